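# Model-based landmarks (valley, turning, half points, moving-average curve)
# and the fourteen time-domain peak features.

FEATURE_NAMES <- paste0("f", 1:14)
AMPLITUDE_FEATURES <- 1:5
WIDTH_FEATURES <- 6:10
SLOPE_FEATURES <- 11:14

#' Centered moving-average value at one sample
#'
#' Arithmetic mean of the samples in a centered window of odd length; the
#' window is truncated (not padded) at the signal boundaries. The moving
#' average plays the role of a floating mean / baseline: feature f5 is the
#' peak amplitude measured against it.
#'
#' @param signal An [eeg_signal()].
#' @param center 0-based sample index.
#' @param window Odd window length in samples (default 257, about one second
#'   at 256 Hz).
#' @return The window mean.
#' @export
moving_average_value <- function(signal, center, window = 257L) {
  stopifnot(inherits(signal, "eeg_signal"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("'window' must be odd and >= 1", call. = FALSE)
  }
  n <- signal_length(signal)
  center <- as.integer(center)
  if (center < 0L || center >= n) {
    stop(sprintf("center %d outside [0, %d)", center, n), call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  lo <- max(0L, center - h)
  hi <- min(n - 1L, center + h)
  mean(signal$samples[(lo + 1L):(hi + 1L)])
}

# Moving-average curve over the whole signal, boundary-truncated, via
# cumulative sums: O(L) for any window.
mac_curve <- function(signal, window = 257L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("'window' must be odd and >= 1", call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(x)   # exact: avoids cumsum round-off at window 1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the turning point between a peak and one of its valleys
#'
#' Walking from the peak toward the valley one sample at a time gives
#' one-sample slope magnitudes `s1, s2, ...`. The turning point is the
#' endpoint of the first segment `k >= 2` whose slope drops by more than 50%
#' relative to the preceding segment (`s_k < 0.5 * s_{k-1}`, strict). When no
#' segment qualifies before the valley is reached — including the case of a
#' valley adjacent to the peak — the valley index itself is returned as a
#' fallback, which keeps all turning-point features defined.
#'
#' @param signal An [eeg_signal()].
#' @param pp 0-based peak index.
#' @param vp 0-based index of the flanking valley on either side.
#' @return A 0-based sample index between `pp` and `vp` (exclusive of `pp`).
#' @export
find_turning_point <- function(signal, pp, vp) {
  stopifnot(inherits(signal, "eeg_signal"))
  pp <- as.integer(pp); vp <- as.integer(vp)
  if (vp == pp) stop("valley index equals peak index", call. = FALSE)
  step <- if (vp > pp) 1L else -1L
  m <- abs(vp - pp)
  if (m >= 2L) {
    idx <- pp + step * (0:m)
    s <- abs(diff(xval(signal, idx)))
    for (k in 2:m) {
      if (s[k] < 0.5 * s[k - 1L]) return(pp + step * k)
    }
  }
  vp
}

#' Locate the half point between a peak and one of its valleys
#'
#' With half level `h = (x(pp) + x(vp)) / 2`, returns the first sample walking
#' from the peak toward the valley whose value is at or below `h`. Since
#' `x(vp) <= h`, the walk always terminates; no sub-sample interpolation is
#' performed, so widths stay integer sample counts.
#'
#' @inheritParams find_turning_point
#' @return A 0-based sample index in `(pp, vp]`.
#' @export
find_half_point <- function(signal, pp, vp) {
  stopifnot(inherits(signal, "eeg_signal"))
  pp <- as.integer(pp); vp <- as.integer(vp)
  if (vp == pp) stop("valley index equals peak index", call. = FALSE)
  step <- if (vp > pp) 1L else -1L
  h <- (xval(signal, pp) + xval(signal, vp)) / 2
  i <- pp
  repeat {
    i <- i + step
    if (xval(signal, i) <= h || i == vp) return(i)
  }
}

#' Eight model-based landmark parameters for one candidate
#'
#' @param signal An [eeg_signal()].
#' @param pp,vp1,vp2 0-based indices of the candidate peak and its flanking
#'   valleys (`vp1 < pp < vp2`), as returned by [detect_candidates()].
#' @param mac_window Odd moving-average window length in samples.
#' @param mac Optional precomputed moving-average value at `pp` (used
#'   internally to amortize the curve over many candidates).
#' @return A list with indices `pp`, `vp1`, `vp2`, `tp1`, `tp2`, `hp1`, `hp2`
#'   and the amplitude `mac`.
#' @export
model_params <- function(signal, pp, vp1, vp2, mac_window = 257L, mac = NULL) {
  if (!(vp1 < pp && pp < vp2)) {
    stop("need vp1 < pp < vp2", call. = FALSE)
  }
  if (is.null(mac)) mac <- moving_average_value(signal, pp, mac_window)
  list(pp = as.integer(pp), vp1 = as.integer(vp1), vp2 = as.integer(vp2),
       tp1 = find_turning_point(signal, pp, vp1),
       tp2 = find_turning_point(signal, pp, vp2),
       hp1 = find_half_point(signal, pp, vp1),
       hp2 = find_half_point(signal, pp, vp2),
       mac = mac)
}

#' Compute the fourteen peak features for one candidate
#'
#' Five amplitudes (f1–f5, signal units), five widths (f6–f10, samples) and
#' four slopes (f11–f14, units per sample), all absolute values:
#' \describe{
#'   \item{f1, f2}{peak amplitude above the first / second valley}
#'   \item{f3, f4}{peak amplitude above the first / second turning point}
#'   \item{f5}{peak amplitude above the moving-average curve}
#'   \item{f6}{valley-to-valley width; f7, f8 peak-to-valley widths}
#'   \item{f9}{turning-point width; f10 half-point width}
#'   \item{f11, f12}{peak-to-valley slopes of the first / second half wave}
#'   \item{f13, f14}{peak-to-turning-point slopes}
#' }
#' The second valley slope f12 uses denominator `|pp - vp2|`; set
#' `literal_f12 = TRUE` to reproduce the historically printed (but
#' description-contradicting) denominator `|pp - vp1|`. Slope denominators
#' that would be zero yield a feature value of 0.
#'
#' @inheritParams model_params
#' @param literal_f12 Use the printed f12 denominator instead of the
#'   corrected one.
#' @return Named numeric vector `f1..f14`; all entries finite and >= 0.
#' @examples
#' s <- eeg_signal(c(5, 1, 4, 2, 6, 3, 7, 0), fs = 256)
#' extract_features(s, pp = 4, vp1 = 3, vp2 = 5, mac_window = 1)
#' @export
extract_features <- function(signal, pp, vp1, vp2, mac_window = 257L,
                             literal_f12 = FALSE, mac = NULL) {
  p <- model_params(signal, pp, vp1, vp2, mac_window, mac = mac)
  xpp <- xval(signal, p$pp)
  slope <- function(num, den) if (den == 0) 0 else abs(num / den)
  f <- c(
    abs(xpp - xval(signal, p$vp1)),
    abs(xpp - xval(signal, p$vp2)),
    abs(xpp - xval(signal, p$tp1)),
    abs(xpp - xval(signal, p$tp2)),
    abs(xpp - p$mac),
    abs(p$vp1 - p$vp2),
    abs(p$pp - p$vp1),
    abs(p$pp - p$vp2),
    abs(p$tp1 - p$tp2),
    abs(p$hp1 - p$hp2),
    slope(xpp - xval(signal, p$vp1), p$pp - p$vp1),
    slope(xpp - xval(signal, p$vp2),
          if (literal_f12) p$pp - p$vp1 else p$pp - p$vp2),
    slope(xpp - xval(signal, p$tp1), p$pp - p$tp1),
    slope(xpp - xval(signal, p$tp2), p$pp - p$tp2)
  )
  names(f) <- FEATURE_NAMES
  f
}

#' Feature matrix for a table of candidates
#'
#' Vectorized driver around [extract_features()]; the moving-average curve is
#' computed once for the whole signal.
#'
#' @param signal An [eeg_signal()].
#' @param candidates Data frame from [detect_candidates()].
#' @inheritParams extract_features
#' @return Numeric matrix, one row per candidate, columns `f1..f14`.
#' @export
peak_features <- function(signal, candidates, mac_window = 257L,
                          literal_f12 = FALSE) {
  n <- nrow(candidates)
  out <- matrix(0, n, 14L, dimnames = list(NULL, FEATURE_NAMES))
  if (n == 0L) return(out)
  mac <- mac_curve(signal, mac_window)
  for (i in seq_len(n)) {
    out[i, ] <- extract_features(signal, candidates$pp[i], candidates$vp1[i],
                                 candidates$vp2[i], mac_window, literal_f12,
                                 mac = mac[candidates$pp[i] + 1L])
  }
  out
}

#' Named peak-model feature subsets
#'
#' The four classical time-domain peak models, as fixed feature masks:
#' `dumpala` \{f1, f6, f11, f12\}, `acir` \{f1, f2, f7, f8, f13, f14\},
#' `liu` \{f1, f2, f3, f4, f6, f9, f10, f11, f12, f13, f14\} and
#' `dingle` \{f5, f6, f11, f12\}.
#'
#' @return Named list of integer feature-index vectors.
#' @export
peak_model_catalog <- function() {
  list(
    dumpala = c(1L, 6L, 11L, 12L),
    acir = c(1L, 2L, 7L, 8L, 13L, 14L),
    liu = c(1L, 2L, 3L, 4L, 6L, 9L, 10L, 11L, 12L, 13L, 14L),
    dingle = c(5L, 6L, 11L, 12L)
  )
}

#' Feature indices of one named peak model
#' @param name One of `"dumpala"`, `"acir"`, `"liu"`, `"dingle"`.
#' @return Integer vector of feature indices (into f1..f14).
#' @export
model_subset <- function(name) {
  cat_ <- peak_model_catalog()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(cat_))) {
    stop("unknown peak model ", sQuote(name), "; valid names: ",
         paste(names(cat_), collapse = ", "), call. = FALSE)
  }
  cat_[[name]]
}
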