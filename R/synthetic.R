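# Seed-deterministic synthetic EEG-like recordings: band-limited oscillatory
# background + white noise, with planted sharp transients (the annotated
# peaks) and optional "decoy" events (un-annotated biphasic artifacts: a small
# crest between two deep valleys) that mimic true peaks in every
# valley-referenced feature while staying close to the moving-average curve.

#' Configuration for the synthetic recording generator
#'
#' Defaults emulate a 40-second single-channel recording at 256 Hz carrying
#' 40 annotated sharp transients: 10240 samples, transient amplitudes 20–32
#' uV with per-side half-widths drawn log-uniformly from 4–20 samples
#' (16–80 ms; left and right half-widths are independent, so morphologies
#' range from narrow-symmetric to broad-asymmetric), a <= 3 uV oscillatory
#' background below 8 Hz plus 0.3 uV white noise, and 24 decoy artifacts.
#'
#' @param n_samples Total length in samples.
#' @param fs Sampling frequency (Hz).
#' @param n_peaks Number of annotated transients.
#' @param peak_amp Length-2 amplitude range (uV) for the transients.
#' @param peak_halfwidth Length-2 half-width-at-half-maximum range (samples).
#' @param min_separation Minimum spacing between event apices (samples),
#'   shared by peaks and decoys.
#' @param background_amp Total oscillation amplitude bound (uV).
#' @param background_band Length-2 frequency band (Hz) of the oscillation.
#' @param noise_sd White-noise standard deviation (uV).
#' @param n_decoys Number of decoy events (0 disables them).
#' @param decoy_amp Crest amplitude range (uV) of the decoys — kept small so
#'   decoys stay near the moving-average curve.
#' @param decoy_depth Depth range (uV) of the decoys' flanking valleys —
#'   deep, so their valley-referenced amplitudes rival the true peaks'.
#' @param decoy_halfwidth Crest-to-valley distance range (samples) of the
#'   decoy complex.
#' @param snr_knob If not `NULL`, transient amplitudes are rescaled so the
#'   smallest equals `snr_knob` times the 99th percentile of the
#'   background-only candidates' moving-average prominence (feature f5).
#'   Values below about 1 leave the planted peaks indistinguishable from
#'   background fluctuations.
#' @param edge_margin Apex-free zone at each end of the signal (samples).
#' @param mac_window Moving-average window used for the `snr_knob`
#'   calibration.
#' @param seed Integer seed for full determinism; `NULL` uses the current
#'   RNG state.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 10240L, fs = 256, n_peaks = 40L,
                         peak_amp = c(20, 32), peak_halfwidth = c(4, 20),
                         min_separation = 120L, background_amp = 3,
                         background_band = c(0.5, 8), noise_sd = 0.3,
                         n_decoys = 24L, decoy_amp = c(1, 2.5),
                         decoy_depth = c(20, 30), decoy_halfwidth = c(12, 18),
                         snr_knob = NULL, edge_margin = 320L,
                         mac_window = 257L, seed = NULL) {
  stopifnot(n_samples >= 1L, fs > 0, n_peaks >= 0L, n_decoys >= 0L,
            length(peak_amp) == 2L, peak_amp[1L] <= peak_amp[2L],
            length(peak_halfwidth) == 2L,
            peak_halfwidth[1L] <= peak_halfwidth[2L],
            min_separation >= 1L, noise_sd >= 0, background_amp >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Uniform placement of n apices in [margin, span-margin] with pairwise
# spacing >= minsep, via the spacing construction (exact, no rejection).
place_apices <- function(n, n_samples, minsep, margin) {
  if (n == 0L) return(integer(0))
  span <- n_samples - 2L * margin
  slack <- span - (n - 1L) * minsep
  if (slack < 0) {
    stop(sprintf(
      "cannot place %d events >= %d samples apart in %d usable samples",
      n, minsep, span), call. = FALSE)
  }
  u <- sort(stats::runif(n, 0, slack))
  as.integer(round(margin + u + (seq_len(n) - 1L) * minsep))
}

# Sharp transient, apex value = amp at offset 0; gaussian or triangular,
# parameterized by half-width at half maximum.
transient_shape <- function(amp, hw_l, hw_r = hw_l,
                            shape = c("gaussian", "triangle")) {
  shape <- match.arg(shape)
  if (shape == "gaussian") {
    sl <- hw_l / sqrt(2 * log(2)); sr <- hw_r / sqrt(2 * log(2))
    half <- ceiling(4 * max(sl, sr))
    d <- (-half):half
    s <- ifelse(d < 0, sl, sr)
    amp * exp(-0.5 * (d / s)^2)
  } else {
    bl <- 2 * hw_l; br <- 2 * hw_r       # zero at -2*hw_l / +2*hw_r
    half <- as.integer(ceiling(max(bl, br)))
    d <- (-half):half
    amp * pmax(0, 1 - abs(d) / ifelse(d < 0, bl, br))
  }
}

# Decoy event: a biphasic "M"-shaped artifact — a small crest (amplitude a)
# between two deep valleys (depth dep) at +/- off samples, all piecewise
# linear. The crest stays near the moving-average curve (so f5 is small)
# while its flanking valleys are deep (so the valley-referenced amplitudes,
# widths and slopes rival a true peak's). Every segment is straight and
# steep ((a + dep) / off per sample, several times the noise scale), so
# white noise cannot carve intervening micro-valleys: the crest's nearest
# strict minima are the deep vertices themselves.
decoy_shape <- function(a, dep, off) {
  off <- as.integer(round(off))
  d <- (-2L * off):(2L * off)
  stats::approx(x = c(-2L * off, -off, 0L, off, 2L * off),
                y = c(0, -dep, a, -dep, 0), xout = d)$y
}

add_event <- function(x, center, wave) {
  half <- (length(wave) - 1L) %/% 2L
  pos <- (center - half):(center + half)     # 0-based
  keep <- pos >= 0L & pos < length(x)
  x[pos[keep] + 1L] <- x[pos[keep] + 1L] + wave[keep]
  x
}

# Noise damping profile: white noise is attenuated inside a transient's
# footprint (down to 10% at the apex), emulating a high local
# signal-to-noise event. Without this, noise occasionally carves a
# spurious local maximum into a transient's shoulder whose prominence
# rivals the apex itself.
damp_event <- function(damp, center, wave, amp) {
  half <- (length(wave) - 1L) %/% 2L
  pos <- (center - half):(center + half)
  keep <- pos >= 0L & pos < length(damp)
  i <- pos[keep] + 1L
  damp[i] <- pmin(damp[i], 1 - 0.9 * wave[keep] / amp)
  damp
}

background_signal <- function(cfg, n_osc = 8L) {
  t <- (seq_len(cfg$n_samples) - 1L) / cfg$fs
  freqs <- stats::runif(n_osc, cfg$background_band[1L], cfg$background_band[2L])
  phases <- stats::runif(n_osc, 0, 2 * pi)
  w <- stats::runif(n_osc)
  amps <- cfg$background_amp * w / sum(w)
  osc <- rep(0, cfg$n_samples)
  for (j in seq_len(n_osc)) {
    osc <- osc + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
  }
  osc
}

# 99th percentile of candidate f5 prominence on a background-only signal,
# used by the snr_knob calibration.
background_prominence_q99 <- function(bg, cfg) {
  sig <- eeg_signal(bg, cfg$fs)
  cand <- detect_candidates(sig)
  if (nrow(cand) == 0L) return(cfg$noise_sd)
  mac <- mac_curve(sig, cfg$mac_window)
  stats::quantile(abs(cand$amp - mac[cand$pp + 1L]), 0.99, names = FALSE)
}

#' Generate a synthetic annotated recording
#'
#' Draws the oscillatory + white-noise background, places transients and
#' decoys with the configured minimum separation, and guarantees every
#' annotation is a strict three-point local maximum of the final signal (so
#' [detect_candidates()] recovers it exactly): where noise breaks strictness
#' the noise around that apex is locally redrawn, with the apex sample given
#' a positive offset.
#'
#' @param cfg A [synth_config()].
#' @return A list with `signal` (an [eeg_signal()]), `annotations` (an
#'   [annotation_set()] of the transient apices) and `decoys` (integer apex
#'   positions of the decoy events, not annotated).
#' @examples
#' rec <- generate_recording(synth_config(n_samples = 2048, n_peaks = 8,
#'                                        n_decoys = 4, seed = 1))
#' length(rec$annotations)
#' @export
generate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(as.integer(cfg$seed))
  }

  osc <- background_signal(cfg)
  noise <- stats::rnorm(cfg$n_samples, 0, cfg$noise_sd)
  bg <- osc + noise

  n_events <- cfg$n_peaks + cfg$n_decoys
  apices <- place_apices(n_events, cfg$n_samples, cfg$min_separation,
                         cfg$edge_margin)
  which_peak <- sort(sample.int(n_events, cfg$n_peaks))
  peak_pos <- apices[which_peak]
  decoy_pos <- apices[setdiff(seq_len(n_events), which_peak)]

  amps <- stats::runif(cfg$n_peaks, cfg$peak_amp[1L], cfg$peak_amp[2L])
  if (!is.null(cfg$snr_knob) && cfg$n_peaks > 0L) {
    q99 <- background_prominence_q99(bg, cfg)
    target_min <- cfg$snr_knob * q99
    amps <- amps / cfg$peak_amp[1L] * target_min
  }
  # per-side half-widths, log-uniform so narrow-sharp and broad-asymmetric
  # morphologies are both well represented
  lhw <- log(cfg$peak_halfwidth)
  hw_l <- exp(stats::runif(cfg$n_peaks, lhw[1L], lhw[2L]))
  hw_r <- exp(stats::runif(cfg$n_peaks, lhw[1L], lhw[2L]))
  shapes <- sample(c("gaussian", "triangle"), cfg$n_peaks, replace = TRUE)

  events <- rep(0, cfg$n_samples)
  damp <- rep(1, cfg$n_samples)
  for (j in seq_len(cfg$n_peaks)) {
    wave <- transient_shape(amps[j], hw_l[j], hw_r[j], shape = shapes[j])
    events <- add_event(events, peak_pos[j], wave)
    damp <- damp_event(damp, peak_pos[j], wave, amps[j])
  }
  x <- osc + noise * damp + events
  for (j in seq_len(cfg$n_decoys)) {
    x <- add_event(x, decoy_pos[j],
                   decoy_shape(stats::runif(1L, cfg$decoy_amp[1L],
                                            cfg$decoy_amp[2L]),
                               stats::runif(1L, cfg$decoy_depth[1L],
                                            cfg$decoy_depth[2L]),
                               stats::runif(1L, cfg$decoy_halfwidth[1L],
                                            cfg$decoy_halfwidth[2L])))
  }

  # enforce apex strictness: broad transients are nearly flat at the top, so
  # residual noise can leave the annotated sample a non-maximum. Regenerate
  # the apex jitter as a small strictly positive kick that lifts the apex
  # just above its neighbours — never touching the neighbours themselves, so
  # no spurious high-prominence candidates are carved into the flanks.
  for (p in peak_pos) {
    i <- p + 1L   # 1-based
    need <- max(x[i - 1L], x[i + 1L]) - x[i]
    if (need >= 0) {
      x[i] <- x[i] + need + 0.05 + abs(stats::rnorm(1L, 0, cfg$noise_sd / 4))
    }
  }

  list(signal = eeg_signal(x, cfg$fs),
       annotations = annotation_set(peak_pos, cfg$n_samples),
       decoys = as.integer(decoy_pos))
}

#' Build a separable parameter-recovery fixture
#'
#' Generates a recording, runs the full candidate-detection /
#' feature-extraction / labelling pipeline on both halves, and verifies that
#' a single planted rule — feature f5 (peak amplitude above the
#' moving-average curve) against one threshold `theta` — separates the
#' classes perfectly, while the decoy events deny every f5-free conjunction a
#' perfect score: the builder requires, in each partition, at least one
#' negative candidate that dominates the positives' componentwise feature
#' minima on all thirteen other features. Any perfect conjunctive rule on
#' this fixture must therefore select f5. `theta` is placed midway between
#' the largest negative and smallest positive f5.
#'
#' The construction is checked, not assumed: if separability (min positive f5
#' must exceed the max negative f5) or decoy domination fails, the recording
#' is regenerated with a derived seed, up to `max_attempts` times, then the
#' builder refuses with an error. With `snr_knob` below about 1 the f5
#' distributions overlap and the builder always refuses.
#'
#' @param seed Integer master seed.
#' @param cfg A [synth_config()]; its `seed` is overridden per attempt.
#' @param boundary Train/test split index (default: half the recording).
#' @param tolerance Annotation matching tolerance in samples.
#' @param mac_window Moving-average window (samples).
#' @param max_attempts Regeneration budget before refusing.
#' @return A list with `train` and `test` (each holding `candidates`,
#'   `features`, `labels`), the planted `model` (a [rule_model()] with mask
#'   \{f5\}), `theta`, the `recording`, and the realized class margins.
#' @export
make_separable_fixture <- function(seed, cfg = synth_config(snr_knob = 8),
                                   boundary = NULL, tolerance = 0L,
                                   mac_window = 257L, max_attempts = 10L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(boundary)) boundary <- cfg$n_samples %/% 2L

  prep <- function(part) {
    cand <- detect_candidates(part$signal)
    list(candidates = cand,
         features = peak_features(part$signal, cand, mac_window),
         labels = label_candidates(cand, part$annotations, tolerance))
  }
  dominated <- function(feats, labels) {
    # some negative row >= componentwise positive minima on all f != f5
    pos_min <- apply(feats[labels, -5L, drop = FALSE], 2L, min)
    neg <- feats[!labels, -5L, drop = FALSE]
    any(rowSums(neg >= rep(pos_min, each = nrow(neg))) == 13L)
  }

  for (attempt in seq_len(max_attempts)) {
    cfg$seed <- (as.integer(seed) + 7919L * (attempt - 1L)) %% 2147483647L
    rec <- generate_recording(cfg)
    halves <- split_recording(rec$signal, rec$annotations, boundary)
    tr <- prep(halves$train)
    te <- prep(halves$test)
    if (sum(tr$labels) == 0L || sum(te$labels) == 0L) next

    f5 <- c(tr$features[, 5L], te$features[, 5L])
    lab <- c(tr$labels, te$labels)
    min_pos <- min(f5[lab]); max_neg <- max(f5[!lab])
    if (min_pos <= max_neg) next
    if (!dominated(tr$features, tr$labels) ||
        !dominated(te$features, te$labels)) next

    theta <- (min_pos + max_neg) / 2
    model <- rule_model(seq_len(14L) == 5L,
                        replace(rep(0, 14L), 5L, theta))
    # construction gate: the planted rule must be perfect on the training half
    g <- gmean(confusion(classify(tr$features, model), tr$labels))
    if (g < 1) next
    return(list(train = tr, test = te, model = model, theta = theta,
                recording = rec, boundary = boundary,
                margin = c(max_negative_f5 = max_neg,
                           min_positive_f5 = min_pos),
                seed_used = cfg$seed, attempts = attempt))
  }
  stop(sprintf(paste0(
    "could not build a separable fixture in %d attempts ",
    "(f5 class distributions overlap or decoy domination failed); ",
    "is snr_knob large enough?"), max_attempts), call. = FALSE)
}
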