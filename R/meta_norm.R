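# Cross-quantity normalisation strategies: transforming a section run at a
# low starting quantity so that it is comparable with sections run at a
# higher one, either by matching distributions (quantile mapping) or by
# learning the quantity bias from a sample hybridised at both quantities
# (locally smooth regression), plus squared-error evaluation against a
# reference section.

#' Quantile-style mapping of one vector onto another's distribution
#'
#' Replaces the value at rank k of `source` by the interpolated rank-k
#' quantile of `target`.  Ranks (hence orderings) of `source` are
#' preserved; when the two vectors have equal length the output's sorted
#' values equal `target`'s exactly.
#'
#' @param source Numeric vector to transform (`NA`s pass through).
#' @param target Non-empty numeric vector supplying the target
#'   distribution (`NA`s dropped).
#' @return Transformed vector aligned with `source`.
#' @export
quantile_map <- function(source, target) {
  target <- target[is.finite(target)]
  if (!length(target)) stop("empty target", call. = FALSE)
  out <- rep(NA_real_, length(source))
  ok <- is.finite(source)
  n <- sum(ok)
  if (!n) return(out)
  if (n == 1) {
    out[ok] <- median(target)
    return(out)
  }
  probs <- (rank(source[ok], ties.method = "average") - 1) / (n - 1)
  out[ok] <- quantile(target, probs, names = FALSE, type = 7)
  out
}

#' Bias correction across starting quantities via local regression
#'
#' Learns the starting-quantity bias from one sample hybridised at both
#' quantities: a robust locally-weighted linear regression (lowess) of
#' `paired_high` on `paired_low`, aligned by bead-type, is fitted and then
#' used to project `source_section` (another sample measured at the low
#' quantity) onto the high-quantity scale.  Outside the fitted range the
#' boundary trend is extended linearly; extrapolated entries are flagged
#' in the `"extrapolated"` attribute.
#'
#' @param source_section Log2 values of the section to project.
#' @param paired_low,paired_high Log2 values of the same sample at the low
#'   and high quantity, aligned by bead-type with `source_section`'s
#'   universe; at least 50 complete pairs required.
#' @param span Lowess span (fraction of points per local fit).
#' @param iter Robustness iterations.
#' @return Predicted high-quantity log2 values aligned with
#'   `source_section`.
#' @export
smooth_bias_correct <- function(source_section, paired_low, paired_high,
                                span = 0.3, iter = 3L) {
  if (length(paired_low) != length(paired_high))
    stop("paired vectors must be aligned", call. = FALSE)
  ok <- is.finite(paired_low) & is.finite(paired_high)
  if (sum(ok) < 50)
    stop("need at least 50 complete pairs to fit the smoother, got ",
         sum(ok), call. = FALSE)
  fit <- lowess(paired_low[ok], paired_high[ok], f = span, iter = iter)
  # collapse duplicate abscissae so interpolation is well defined
  fx <- tapply(fit$y, fit$x, mean)
  xs <- as.numeric(names(fx)); ys <- as.numeric(fx)
  if (length(xs) < 2) stop("degenerate paired data", call. = FALSE)

  n_edge <- max(2L, ceiling(0.05 * length(xs)))
  slope_at <- function(idx) {
    xi <- xs[idx]; yi <- ys[idx]
    sum((xi - mean(xi)) * (yi - mean(yi))) / sum((xi - mean(xi))^2)
  }
  lo_slope <- slope_at(seq_len(n_edge))
  hi_slope <- slope_at(seq(length(xs) - n_edge + 1L, length(xs)))

  out <- rep(NA_real_, length(source_section))
  src_ok <- is.finite(source_section)
  v <- source_section[src_ok]
  pred <- approx(xs, ys, xout = v, rule = 1)$y
  below <- v < xs[1]; above <- v > xs[length(xs)]
  pred[below] <- ys[1] + lo_slope * (v[below] - xs[1])
  pred[above] <- ys[length(xs)] + hi_slope * (v[above] - xs[length(xs)])
  out[src_ok] <- pred
  extrap <- rep(FALSE, length(source_section))
  extrap[src_ok] <- below | above
  attr(out, "extrapolated") <- extrap
  out
}

#' Evaluate a cross-quantity prediction against a reference section
#'
#' Per bead-type squared differences between the predicted and the
#' reference log2 intensities, their empirical cumulative distribution and
#' the median — the same summary used to compare normalisation strategies
#' against the replicate-section gold standard.
#'
#' @param prediction,reference Aligned numeric vectors (same bead-type
#'   universe); incomplete pairs are dropped.
#' @return List of class `"normalization_eval"`: `squared_errors`, `cdf`
#'   (an [stats::ecdf()]), `median_se`, `n`.
#' @export
evaluate_normalization <- function(prediction, reference) {
  if (length(prediction) != length(reference))
    stop("prediction and reference must be aligned", call. = FALSE)
  ok <- is.finite(prediction) & is.finite(reference)
  if (!any(ok)) stop("no complete pairs", call. = FALSE)
  se <- (prediction[ok] - reference[ok])^2
  structure(list(squared_errors = se, cdf = stats::ecdf(se),
                 median_se = median(se), n = length(se)),
            class = "normalization_eval")
}

#' @export
print.normalization_eval <- function(x, ...) {
  cat(sprintf("Normalisation evaluation on %d bead-types: median squared error %.4g\n",
              x$n, x$median_se))
  invisible(x)
}
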