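# Expression/DE call aggregation, analytic chance expectations,
# cross-quantity sensitivity/FDR, rank correlations, and power-by-fold-
# change binning.

#' Aggregate per-section detection into expression calls
#'
#' A bead-type is "detected" on a section when its detection p-value falls
#' below `alpha`.  Per bead-type the call summary reports detection in at
#' least one section, in both pure sources (at least one UHRR-pure
#' `c = 1` section and at least one Brain-pure `c = 0` section), in every
#' section on which it was measured, and the number of detecting sections.
#'
#' @param detection_p Matrix of detection p-values (bead-types x sections).
#' @param design Design rows covering the matrix columns.
#' @param alpha Detection significance level (default 0.01).
#' @return data.frame with columns `bead_type_id`, `detected_any`,
#'   `detected_both_pure`, `detected_all`, `n_sections_detected`.  The
#'   mean number of detecting sections is attached twice, as attributes
#'   `mean_sections_all` (denominator: all bead-types) and
#'   `mean_sections_detected` (denominator: bead-types detected at least
#'   once).
#' @export
expression_calls <- function(detection_p, design, alpha = 0.01) {
  stopifnot(is.matrix(detection_p))
  sections <- colnames(detection_p)
  if (!all(sections %in% design$section_id))
    stop("design does not cover all matrix sections", call. = FALSE)
  cc <- design$c_uhrr[match(sections, design$section_id)]
  det <- !is.na(detection_p) & detection_p < alpha
  measured <- !is.na(detection_p)

  uhrr_cols <- which(cc == 1)
  brain_cols <- which(cc == 0)
  both_pure <- if (length(uhrr_cols) && length(brain_cols)) {
    rowSums(det[, uhrr_cols, drop = FALSE]) >= 1 &
      rowSums(det[, brain_cols, drop = FALSE]) >= 1
  } else {
    warning("no pure sections of both sources; detected_both_pure undefined")
    rep(NA, nrow(det))
  }
  n_det <- rowSums(det)
  out <- data.frame(
    bead_type_id = rownames(detection_p),
    detected_any = n_det >= 1,
    detected_both_pure = both_pure,
    detected_all = rowSums(measured) > 0 & n_det == rowSums(measured),
    n_sections_detected = n_det,
    stringsAsFactors = FALSE)
  attr(out, "mean_sections_all") <- mean(n_det)
  attr(out, "mean_sections_detected") <-
    if (any(out$detected_any)) mean(n_det[out$detected_any]) else NA_real_
  out
}

#' Expected detections under the no-expression null
#'
#' If no bead-type were truly expressed, detection p-values would be
#' uniform, so among `n_types` bead-types one expects
#' `n_types * (1 - (1 - alpha)^n_sections)` to be detected in at least one
#' of `n_sections` sections, and
#' `n_types * (1 - (1 - alpha)^n_pure)^2` to be detected in both pure
#' sources when each source contributes `n_pure` pure sections.
#'
#' @param n_types Number of bead-types.
#' @param n_sections Number of sections (mode `"any"`).
#' @param alpha Detection level.
#' @param mode `"any"` or `"both_pure"`.
#' @param n_pure Pure sections per source (mode `"both_pure"`), default 2.
#' @return Expected count (real, not rounded).
#' @export
expected_chance_detections <- function(n_types, n_sections = NULL,
                                       alpha = 0.01,
                                       mode = c("any", "both_pure"),
                                       n_pure = 2L) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (mode == "any") {
    if (is.null(n_sections)) stop("n_sections required for mode 'any'",
                                  call. = FALSE)
    n_types * (1 - (1 - alpha)^n_sections)
  } else {
    n_types * (1 - (1 - alpha)^n_pure)^2
  }
}

#' Concordance of calls between a test and a reference experiment
#'
#' Sensitivity is the fraction of the reference experiment's calls that
#' the test experiment reproduces; the false discovery rate is the
#' fraction of the test experiment's calls absent from the reference.
#'
#' @param test_calls,ref_calls Character vectors of called bead-type ids
#'   drawn from a common universe.
#' @return List of class `"concordance_result"`: `sensitivity`, `fdr`,
#'   `n_ref`, `n_test`, `n_overlap`.  Undefined ratios (empty reference or
#'   empty test set) are `NA`.
#' @export
consistency <- function(test_calls, ref_calls) {
  test_calls <- unique(test_calls)
  ref_calls <- unique(ref_calls)
  n_overlap <- length(intersect(test_calls, ref_calls))
  n_ref <- length(ref_calls)
  n_test <- length(test_calls)
  structure(list(
    sensitivity = if (n_ref) n_overlap / n_ref else NA_real_,
    fdr = if (n_test) (n_test - n_overlap) / n_test else NA_real_,
    n_ref = n_ref, n_test = n_test, n_overlap = n_overlap),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance: sensitivity %.3f, FDR %.3f (ref %d, test %d, overlap %d)\n",
              x$sensitivity, x$fdr, x$n_ref, x$n_test, x$n_overlap))
  invisible(x)
}

#' Squared Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs dropped,
#'   at least 3 complete pairs required.  Ties take midranks.
#' @return Squared rank correlation in `[0, 1]`; `NA` (with a warning)
#'   when either vector is constant.
#' @export
rank_correlation_sq <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    warning("constant vector; rank correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok], method = "spearman")^2
}

#' Proportion of bead-types called, by fold-change bin
#'
#' Bins bead-types into `n_bins` equal-count bins of the reference log2
#' fold change (by absolute value unless `signed`) and reports, per bin,
#' the fold-change range, the proportion called and a Wilson 95%
#' confidence interval for that proportion.
#'
#' @param ref_logfc Reference log2 fold changes, one per bead-type.
#' @param de_called Logical vector aligned with `ref_logfc`.
#' @param n_bins Number of equal-count bins (default 50).
#' @param signed Bin on the signed fold change instead of its magnitude.
#' @param conf_level Confidence level of the Wilson interval.
#' @return data.frame with one row per bin: `bin`, `lfc_lo`, `lfc_hi`,
#'   `n`, `proportion`, `ci_low`, `ci_high`.
#' @export
power_by_foldchange <- function(ref_logfc, de_called, n_bins = 50L,
                                signed = FALSE, conf_level = 0.95) {
  if (length(ref_logfc) != length(de_called))
    stop("length mismatch", call. = FALSE)
  ok <- is.finite(ref_logfc) & !is.na(de_called)
  lfc <- ref_logfc[ok]; called <- de_called[ok]
  n <- length(lfc)
  if (n < n_bins) stop("fewer bead-types than bins", call. = FALSE)
  key <- if (signed) lfc else abs(lfc)
  bin <- ceiling(rank(key, ties.method = "first") * n_bins / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  res <- lapply(seq_len(n_bins), function(b) {
    i <- bin == b
    k <- sum(called[i]); m <- sum(i)
    phat <- k / m
    centre <- (phat + z^2 / (2 * m)) / (1 + z^2 / m)
    half <- z * sqrt(phat * (1 - phat) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
    data.frame(bin = b, lfc_lo = min(key[i]), lfc_hi = max(key[i]), n = m,
               proportion = phat,
               ci_low = max(0, centre - half), ci_high = min(1, centre + half))
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1) via [stats::p.adjust()],
#' with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}
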