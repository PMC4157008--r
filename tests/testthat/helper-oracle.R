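# Brute-force candidate oracle: tests every interior index against the
# three-point strict max/min definitions and pairs each maximum with the
# nearest interior valley on each side. Deliberately naive and independent
# of detect_candidates().
brute_force_candidates <- function(x) {
  n <- length(x)
  out <- data.frame(pp = integer(0), vp1 = integer(0), vp2 = integer(0))
  if (n < 3L) return(out)
  is_max <- logical(n); is_min <- logical(n)
  for (i in 2:(n - 1L)) {
    is_max[i] <- x[i - 1L] < x[i] && x[i] > x[i + 1L]
    is_min[i] <- x[i - 1L] > x[i] && x[i] < x[i + 1L]
  }
  for (i in which(is_max)) {
    v1 <- NA_integer_; v2 <- NA_integer_
    for (j in (i - 1L):1L) if (is_min[j]) { v1 <- j; break }
    for (j in (i + 1L):n) if (is_min[j]) { v2 <- j; break }
    if (!is.na(v1) && !is.na(v2)) {
      out <- rbind(out, data.frame(pp = i - 1L, vp1 = v1 - 1L, vp2 = v2 - 1L))
    }
  }
  out
}

# Random test signals mixing smooth oscillation, white noise and integer
# quantization (the latter exercises plateaus / tied samples).
random_test_signal <- function(n) {
  kind <- sample(3L, 1L)
  x <- switch(kind,
              stats::rnorm(n),
              sin(seq(0, stats::runif(1, 1, 8) * pi, length.out = n)) +
                stats::rnorm(n, 0, 0.3),
              as.numeric(sample.int(6L, n, replace = TRUE)))
  x
}

# Tiny labelled training set built from a small synthetic recording; cached
# per session because several test files want one.
small_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_samples = 2048L, n_peaks = 8L, n_decoys = 4L,
                          min_separation = 100L, edge_margin = 150L,
                          seed = 42L)
      rec <- generate_recording(cfg)
      cand <- detect_candidates(rec$signal)
      cache <<- list(
        recording = rec,
        candidates = cand,
        features = peak_features(rec$signal, cand),
        labels = label_candidates(cand, rec$annotations))
    }
    cache
  }
})
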