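# Conjunctive threshold rule classifier, candidate labelling and the
# geometric-mean score.

#' Construct a rule model (feature mask + decision thresholds)
#'
#' A rule model is the decoded form of one swarm particle: a 14-bit feature
#' mask and fourteen per-feature decision thresholds, of which only the masked
#' entries take part in classification. A candidate is called a peak iff
#' `f_i >= th_i` for every selected feature `i`; an empty mask is a vacuous
#' conjunction, so everything is called a peak (during training that model
#' self-penalizes through its zero true-non-peak rate).
#'
#' @param mask Logical (or 0/1) vector of length 14.
#' @param thresholds Numeric vector of length 14; unmasked entries are kept
#'   but ignored.
#' @return An object of class `rule_model`.
#' @export
rule_model <- function(mask, thresholds = rep(0, 14L)) {
  mask <- as.logical(mask)
  thresholds <- as.numeric(thresholds)
  if (length(mask) != 14L || anyNA(mask)) {
    stop("'mask' must be 14 booleans", call. = FALSE)
  }
  if (length(thresholds) != 14L || !all(is.finite(thresholds))) {
    stop("'thresholds' must be 14 finite numbers", call. = FALSE)
  }
  names(thresholds) <- FEATURE_NAMES
  structure(list(mask = mask, thresholds = thresholds), class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  sel <- which(x$mask)
  if (length(sel) == 0L) {
    cat("<rule_model> empty mask (vacuous rule: everything is a peak)\n")
  } else {
    cat("<rule_model>",
        paste(sprintf("%s>=%.4g", FEATURE_NAMES[sel], x$thresholds[sel]),
              collapse = " & "), "\n")
  }
  invisible(x)
}

#' Classify feature vectors with a rule model
#'
#' @param features Numeric matrix with 14 columns (one row per candidate), or
#'   a single length-14 vector.
#' @param model A [rule_model()].
#' @return Logical vector, `TRUE` = predicted peak.
#' @export
classify <- function(features, model) {
  stopifnot(inherits(model, "rule_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  stopifnot(ncol(features) == 14L)
  sel <- which(model$mask)
  if (length(sel) == 0L) return(rep(TRUE, nrow(features)))
  th <- model$thresholds[sel]
  # recycle th down the rows of the transposed block: one pass, no sweep()
  colSums(t(features[, sel, drop = FALSE]) >= th) == length(sel)
}

#' Label candidates against ground-truth annotations
#'
#' A candidate is labelled positive iff it consumes an annotation within
#' `tolerance` samples of its peak index. Each annotation is consumed by at
#' most one candidate: the nearest peak index wins, with the earlier index
#' breaking distance ties. With the default `tolerance = 0` this reduces to
#' exact index matching.
#'
#' @param candidates Data frame from [detect_candidates()].
#' @param annotations An [annotation_set()] (or integer vector of 0-based
#'   indices).
#' @param tolerance Non-negative matching tolerance in samples.
#' @return Logical vector along the candidate rows.
#' @export
label_candidates <- function(candidates, annotations, tolerance = 0L) {
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  pp <- as.integer(candidates$pp)
  pos <- logical(length(pp))
  for (a in as.integer(annotations)) {
    d <- abs(pp - a)
    elig <- which(d <= tolerance)
    if (length(elig) > 0L) {
      win <- elig[order(d[elig], pp[elig])][1L]
      pos[win] <- TRUE
    }
  }
  pos
}

#' Tally a 2x2 confusion from predictions and labels
#'
#' @param predictions,labels Logical vectors of equal length (`TRUE` = peak).
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion <- function(predictions, labels) {
  predictions <- as.logical(predictions)
  labels <- as.logical(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  structure(list(tp = sum(predictions & labels),
                 tn = sum(!predictions & !labels),
                 fp = sum(predictions & !labels),
                 fn = sum(!predictions & labels)),
            class = "confusion_counts")
}

#' Geometric mean of true-peak and true-non-peak rates
#'
#' `TPR = tp / (tp + fn)` and `TNR = tn / (tn + fp)`, each defined as 0 when
#' its denominator is 0, combined as `sqrt(TPR * TNR)`. The score is 0
#' whenever no true peak is recovered, however many non-peaks are classified
#' correctly — which is what makes it a usable fitness on heavily imbalanced
#' candidate sets. `literal = TRUE` returns the plain product `TPR * TNR`
#' instead of its square root (a monotone-equivalent fitness).
#'
#' @param counts A `confusion_counts` object, or anything list-like with
#'   elements `tp`, `tn`, `fp`, `fn`.
#' @param literal Use the plain product instead of the geometric mean.
#' @return A number in \[0, 1\].
#' @export
gmean <- function(counts, literal = FALSE) {
  tpr <- if (counts$tp + counts$fn == 0L) 0 else
    counts$tp / (counts$tp + counts$fn)
  tnr <- if (counts$tn + counts$fp == 0L) 0 else
    counts$tn / (counts$tn + counts$fp)
  if (literal) tpr * tnr else sqrt(tpr * tnr)
}

#' Write a rule model (plus configuration echo) as JSON
#'
#' @param model A [rule_model()].
#' @param path Output path.
#' @param config Optional named list echoed verbatim into the file (e.g.
#'   moving-average window, matching tolerance, score variant).
#' @return `path`, invisibly.
#' @export
write_rule_model <- function(model, path, config = list()) {
  stopifnot(inherits(model, "rule_model"))
  obj <- list(mask = as.integer(model$mask),
              thresholds = unname(model$thresholds),
              features = FEATURE_NAMES[model$mask],
              config = config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a rule model written by [write_rule_model()]
#' @param path Path to the JSON file.
#' @return A [rule_model()]; the configuration echo is attached as attribute
#'   `config`.
#' @export
read_rule_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- rule_model(obj$mask, obj$thresholds)
  attr(m, "config") <- obj$config
  m
}
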