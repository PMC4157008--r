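# Three-point sliding-window candidate detection.

#' Detect candidate peaks with the three-point sliding window
#'
#' A candidate peak point `pp` is a strict three-point local maximum,
#' `x(pp-1) < x(pp) > x(pp+1)`, taken together with its flanking valley points
#' `vp1 < pp < vp2`, each a strict three-point local minimum. The nearest
#' valley on each side is used; local maxima lacking an interior valley on
#' either side (e.g. near the signal boundaries) are discarded.
#'
#' All inequalities are strict, so plateaus (equal adjacent samples) never
#' produce candidates or valleys. If a signal with tied samples must be
#' processed, break the ties upstream (`jitter` argument) — the detector
#' itself never reinterprets ties.
#'
#' @param signal An [eeg_signal()].
#' @param jitter If `TRUE`, a tie-breaking pre-pass adds an infinitesimal
#'   index-ordered ramp (`i * eps`) to the samples before scanning, so plateau
#'   maxima resolve to their last sample. Off by default.
#' @return A data.frame with one row per candidate, ordered by `pp`, columns
#'   `pp`, `vp1`, `vp2` (0-based sample indices) and `amp` (`x(pp)`).
#'   Signals too short to admit a candidate (length < 5) give zero rows.
#' @examples
#' s <- eeg_signal(c(5, 1, 4, 2, 6, 3, 7, 0), fs = 256)
#' detect_candidates(s)  # pp 2 and 4; the maximum at 6 has no right valley
#' @export
detect_candidates <- function(signal, jitter = FALSE) {
  stopifnot(inherits(signal, "eeg_signal"))
  x <- signal$samples
  n <- length(x)
  empty <- data.frame(pp = integer(0), vp1 = integer(0), vp2 = integer(0),
                      amp = numeric(0))
  if (n < 5L) return(empty)
  if (jitter) x <- x + seq_len(n) * (max(abs(x), 1) * 1e-12)

  mid <- 2:(n - 1L)                       # 1-based interior positions
  is_max <- x[mid - 1L] < x[mid] & x[mid] > x[mid + 1L]
  is_min <- x[mid - 1L] > x[mid] & x[mid] < x[mid + 1L]
  maxima <- mid[is_max]
  minima <- mid[is_min]
  if (length(maxima) == 0L || length(minima) < 2L) return(empty)

  # nearest strict minimum to the left / right of each maximum
  left <- findInterval(maxima, minima)           # minima[left] < maxima
  right <- left + 1L
  ok <- left >= 1L & right <= length(minima)
  maxima <- maxima[ok]
  if (length(maxima) == 0L) return(empty)
  vp1 <- minima[left[ok]]
  vp2 <- minima[right[ok]]
  data.frame(pp = maxima - 1L, vp1 = vp1 - 1L, vp2 = vp2 - 1L,
             amp = signal$samples[maxima])
}
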