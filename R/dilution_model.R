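# Weighted non-linear dilution model, fitted per bead-type across the
# mixture series of one starting quantity:
#
#   y_i = log2(c_i * Delta + B) + eps_i,   Delta = U - B,
#
# with y the summarised (normalised) log2 intensity, c the UHRR proportion
# of the mixture, weights the bead counts behind each summary, and the
# constraints B > 0, B + Delta > 0 keeping the model mean positive over the
# whole titration range.  The Wald test of Delta = 0 is the quick test of
# differential expression between the two sources.

#' Fit the dilution model to one bead-type
#'
#' Minimises `sum(w_i * (y_i - log2(c_i * Delta + B))^2)` over
#' `(Delta, B)` by damped Gauss-Newton with projection onto the feasible
#' region and up to three starts.  Initialisation follows the titration
#' end-points: `B0 = 2^(weighted mean y at the smallest c)`,
#' `U0 = 2^(weighted mean y at the largest c)`, `Delta0 = U0 - B0`.  The
#' standard error of `Delta` comes from the first-order (Jacobian)
#' covariance at the optimum with residual variance on `n - 2` degrees of
#' freedom, matching standard non-linear least-squares summaries.
#'
#' @param y Numeric vector of log2 intensities (>= 3 values).
#' @param c_uhrr Mixture proportions in `[0, 1]`, at least two distinct.
#' @param w Positive weights (bead counts); equal weights by default.
#' @param bead_type_id Optional id carried into the result.
#' @param tol Convergence tolerance on the relative objective decrease.
#' @param max_iter Iteration cap per start.
#' @return One-row data.frame of class `"dilution_fit"`: `bead_type_id`,
#'   `delta_hat`, `b_hat`, `se_delta`, `t_stat`, `p_value`, `df`,
#'   `converged`, `n_obs`, `objective`.
#' @examples
#' cc <- rep(c(1, .75, .5, .25, 0), each = 2)
#' y <- log2(cc * 900 + 100)
#' fit_dilution(y, cc)
#' @export
fit_dilution <- function(y, c_uhrr, w = NULL, bead_type_id = NA_character_,
                         tol = 1e-8, max_iter = 200L) {
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(c_uhrr) != n) stop("length mismatch y / c_uhrr", call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(w <= 0))
    stop("weights must be positive and match y", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(c_uhrr)))
    stop("y and c_uhrr must be finite", call. = FALSE)
  if (any(c_uhrr < 0 | c_uhrr > 1))
    stop("c_uhrr must lie in [0, 1]", call. = FALSE)
  if (length(unique(c_uhrr)) < 2)
    stop("Delta is unidentifiable with a single mixture level", call. = FALSE)
  .fit_dilution_core(y, c_uhrr, w, bead_type_id, tol, max_iter)
}

# Validation-free core used by fit_all().
.fit_dilution_core <- function(y, cc, w, bead_type_id = NA_character_,
                               tol = 1e-8, max_iter = 200L) {
  n <- length(y)
  floor_b <- max(1e-12, 2^min(y) * 1e-9)
  wmean <- function(v, wt) sum(wt * v) / sum(wt)
  lo <- cc == min(cc); hi <- cc == max(cc)
  b0 <- 2^wmean(y[lo], w[lo])
  u0 <- 2^wmean(y[hi], w[hi])
  starts <- list(c(u0 - b0, b0),
                 c(0, 2^wmean(y, w)),
                 c(2 * (u0 - b0), b0 / 2))
  best <- NULL
  for (s in starts) {
    res <- .gauss_newton(y, cc, w, s[1], s[2], floor_b, tol, max_iter)
    if (is.null(best) || res$f < best$f ||
        (res$converged && !best$converged && res$f <= best$f * (1 + 1e-6)))
      best <- res
    if (best$converged) break
  }
  .fit_record(best, y, cc, w, n, bead_type_id)
}

.gauss_newton <- function(y, cc, w, d, b, floor_b, tol, max_iter) {
  ln2 <- log(2)
  if (b < floor_b) b <- floor_b
  if (b + d < floor_b) d <- floor_b - b
  mu <- cc * d + b
  f <- sum(w * (y - log2(mu))^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - log2(mu)
    jd <- cc / (mu * ln2)
    jb <- 1 / (mu * ln2)
    a11 <- sum(w * jd * jd); a12 <- sum(w * jd * jb); a22 <- sum(w * jb * jb)
    g1 <- sum(w * jd * r); g2 <- sum(w * jb * r)
    scale_g <- max(abs(g1), abs(g2))
    if (scale_g < 1e-12 * max(1, f)) { converged <- TRUE; break }
    improved <- FALSE
    for (k in 1:40) {
      A11 <- a11 * (1 + lambda); A22 <- a22 * (1 + lambda)
      det <- A11 * A22 - a12 * a12
      if (det <= 0 || !is.finite(det)) { lambda <- lambda * 10; next }
      sd_ <- (g1 * A22 - g2 * a12) / det
      sb_ <- (g2 * A11 - g1 * a12) / det
      d_new <- d + sd_; b_new <- b + sb_
      if (b_new < floor_b) b_new <- floor_b
      if (b_new + d_new < floor_b) d_new <- floor_b - b_new
      mu_new <- cc * d_new + b_new
      f_new <- sum(w * (y - log2(mu_new))^2)
      if (is.finite(f_new) && f_new <= f) {
        rel <- (f - f_new) / max(f, .Machine$double.xmin)
        d <- d_new; b <- b_new; mu <- mu_new; f <- f_new
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (converged) break
    if (!improved) {
      # step rejected at maximal damping: stationary up to numerics
      converged <- scale_g < 1e-6 * max(1, f)
      break
    }
  }
  list(delta = d, b = b, f = f, converged = converged)
}

.fit_record <- function(res, y, cc, w, n, bead_type_id) {
  ln2 <- log(2)
  mu <- cc * res$delta + res$b
  jd <- cc / (mu * ln2); jb <- 1 / (mu * ln2)
  a11 <- sum(w * jd * jd); a12 <- sum(w * jd * jb); a22 <- sum(w * jb * jb)
  det <- a11 * a22 - a12 * a12
  df <- n - 2L
  sigma2 <- res$f / df
  se_delta <- if (det > 0) sqrt(sigma2 * a22 / det) else NA_real_
  t_stat <- if (!is.na(se_delta) && se_delta > 0) res$delta / se_delta
            else if (res$delta == 0) 0 else NA_real_
  p_value <- if (is.na(t_stat)) NA_real_ else 2 * pt(-abs(t_stat), df)
  out <- data.frame(bead_type_id = bead_type_id, delta_hat = res$delta,
                    b_hat = res$b, se_delta = se_delta, t_stat = t_stat,
                    p_value = p_value, df = df, converged = res$converged,
                    n_obs = n, objective = res$f, stringsAsFactors = FALSE)
  class(out) <- c("dilution_fit", class(out))
  out
}

#' Wald test of no difference between the sources
#'
#' Two-sided p-value for `Delta = 0` from `t = delta_hat / se_delta` on
#' `n_obs - 2` degrees of freedom.  A zero standard error is degenerate:
#' the p-value is returned as 0 with attribute `degenerate = TRUE`.
#'
#' @param fit A `"dilution_fit"` row from [fit_dilution()].
#' @return The p-value (scalar).
#' @export
test_delta <- function(fit) {
  stopifnot(inherits(fit, "dilution_fit"))
  if (!isTRUE(fit$converged))
    warning("testing a non-converged fit")
  if (is.na(fit$se_delta) || fit$se_delta == 0) {
    if (fit$delta_hat == 0) return(1)
    return(structure(0, degenerate = TRUE))
  }
  2 * pt(-abs(fit$delta_hat / fit$se_delta), fit$df)
}

#' Fit the dilution model to every bead-type of one quantity
#'
#' Extracts, for each bead-type in `group`, the summarised log2 values of
#' the sections run at `quantity` (normalised within that quantity),
#' weights them by bead counts, and fits the dilution model.  Bead-types
#' missing from some sections are fitted on the remaining observations;
#' per-bead-type failures are recorded, not fatal.
#'
#' @param em A [bead_expression()], quantile-normalised within quantity.
#' @param design Design data.frame covering `em`'s sections.
#' @param quantity The starting quantity (ng) whose sections to use.
#' @param group Character vector of bead-type ids (the analysis-group).
#' @return data.frame of class `"dilution_fits"`, one row per bead-type.
#' @export
fit_all <- function(em, design, quantity, group) {
  stopifnot(inherits(em, "bead_expression"))
  sections <- design$section_id[design$quantity_ng == quantity]
  if (!length(sections))
    stop("no sections at quantity ", quantity, call. = FALSE)
  if (!all(sections %in% colnames(em$log2_mean)))
    stop("design sections missing from the expression matrices", call. = FALSE)
  cc_all <- design$c_uhrr[match(sections, design$section_id)]
  ym <- em$log2_mean[, sections, drop = FALSE]
  wm <- em$n_beads[, sections, drop = FALSE]
  group <- intersect(group, rownames(ym))
  rows <- vector("list", length(group))
  for (i in seq_along(group)) {
    p <- group[i]
    y <- ym[p, ]; w <- wm[p, ]
    ok <- !is.na(y) & w > 0
    if (sum(ok) < 3 || length(unique(cc_all[ok])) < 2) {
      rows[[i]] <- data.frame(bead_type_id = p, delta_hat = NA_real_,
                              b_hat = NA_real_, se_delta = NA_real_,
                              t_stat = NA_real_, p_value = NA_real_,
                              df = as.integer(sum(ok)) - 2L,
                              converged = FALSE,
                              n_obs = as.integer(sum(ok)),
                              objective = NA_real_, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- .fit_dilution_core(y[ok], cc_all[ok], w[ok],
                                      bead_type_id = p)
    }
  }
  out <- data.table::rbindlist(rows)
  out <- as.data.frame(out)
  class(out) <- c("dilution_fits", class(out))
  out
}

#' Median signal-to-noise ratio of dilution fits
#'
#' The per-bead-type noise-to-signal measure is `se_delta / |delta_hat|`
#' (smaller is better).  Fits with `delta_hat` numerically zero (below
#' `1e-9 * b_hat`) are excluded and counted separately, as the ratio is
#' undefined there.
#'
#' @param fits A `"dilution_fits"` table.
#' @return List with `median_ratio`, `n_used`, `n_excluded`.
#' @export
snr_summary <- function(fits) {
  if (!nrow(fits)) stop("empty fit table", call. = FALSE)
  ok <- !is.na(fits$delta_hat) & !is.na(fits$se_delta) &
    abs(fits$delta_hat) >= 1e-9 * pmax(fits$b_hat, .Machine$double.xmin)
  if (!any(ok)) {
    warning("all fits excluded; median ratio undefined")
    return(list(median_ratio = NA_real_, n_used = 0L,
                n_excluded = nrow(fits)))
  }
  ratio <- fits$se_delta[ok] / abs(fits$delta_hat[ok])
  list(median_ratio = median(ratio), n_used = sum(ok),
       n_excluded = sum(!ok))
}

#' Sample-size inflation to match a reference signal-to-noise
#'
#' Standard errors scale with `1/sqrt(n)`, so matching a reference
#' experiment's noise-to-signal ratio requires inflating the sample size by
#' the squared ratio of the two median `se/|Delta|` summaries.  A test/ref
#' ratio of 1.12 gives ~1.25 ("at least 1.2"); 1.76 gives ~3.1 (about
#' three times as many samples).
#'
#' @param snr_test,snr_ref Median `se/|Delta|` ratios, both positive;
#'   `snr_test` is the noisier (lower-quantity) experiment.
#' @return The inflation factor `(snr_test / snr_ref)^2`.
#' @export
sample_size_inflation <- function(snr_test, snr_ref) {
  if (!is.finite(snr_test) || !is.finite(snr_ref) ||
      snr_test <= 0 || snr_ref <= 0)
    stop("both ratios must be positive", call. = FALSE)
  (snr_test / snr_ref)^2
}
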