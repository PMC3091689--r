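# Bead-level -> summarised expression: outlier removal on the log2 scale,
# per-section summarisation, empirical detection p-values against the
# negative controls, within-quantity quantile normalisation, and the
# analysis-group filter.

#' Median/MAD outlier mask for bead replicates
#'
#' Keeps observation i iff `|x_i - median(x)| <= 3 * MAD(x)`, where MAD is
#' the plain median absolute deviation (no Gaussian consistency factor).
#' When MAD is zero (at least half the replicates identical) only values
#' equal to the median are kept — an aggressive but deterministic reading
#' of the degenerate case.
#'
#' @param values Numeric vector (log2-scale intensities), length >= 1.
#' @return Logical vector, `TRUE` = keep.
#' @export
mad_outlier_mask <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  med <- median(values)
  dev <- abs(values - med)
  madv <- median(dev)
  if (madv == 0) dev == 0 else dev <= 3 * madv
}

# Shared summarisation core: data.table with columns section_id,
# bead_type_id, lg (log2 intensity).  Entirely grouped-aggregate based so
# data.table's optimised group code carries million-bead experiments.
.summarize_core <- function(dt) {
  lg <- med <- dev <- madv <- keep <- n_total <- n_used <- NULL  # NSE notes
  dt[, med := median(lg), by = list(section_id, bead_type_id)]
  dt[, dev := abs(lg - med)]
  dt[, madv := median(dev), by = list(section_id, bead_type_id)]
  # 3-MAD keep rule; degenerate MAD = 0 keeps only values at the median
  dt[, keep := (madv > 0 & dev <= 3 * madv) | (madv == 0 & dev == 0)]
  tot <- dt[, list(n_total = .N), by = list(section_id, bead_type_id)]
  out <- dt[keep == TRUE,
            list(log2_mean = mean(lg), log2_sd = sd(lg), n_used = .N),
            by = list(section_id, bead_type_id)]
  out <- out[tot, on = c("section_id", "bead_type_id")]
  out[is.na(n_used), n_used := 0L]
  out[, n_removed := n_total - n_used]
  out[, c("section_id", "bead_type_id", "log2_mean", "log2_sd",
          "n_used", "n_removed"), with = FALSE]
}

#' Summarise one section's beads per bead-type
#'
#' Log2-transforms raw bead intensities, removes outliers by the 3-MAD
#' rule within each bead-type, and reports mean, SD and counts of the
#' retained beads.  Bead-types with no beads on the section are simply
#' absent from the summary.
#'
#' @param section A [bead_section()].
#' @return data.frame of class `"section_summary"` with columns
#'   `bead_type_id`, `log2_mean`, `log2_sd`, `n_used`, `n_removed`; the
#'   section's design row is attached as attribute `"meta"`.
#' @export
summarize_section <- function(section) {
  stopifnot(inherits(section, "bead_section"))
  if (!nrow(section$beads)) {
    out <- data.frame(bead_type_id = character(0), log2_mean = numeric(0),
                      log2_sd = numeric(0), n_used = integer(0),
                      n_removed = integer(0), stringsAsFactors = FALSE)
  } else {
    dt <- data.table::data.table(
      section_id = section$meta$section_id,
      bead_type_id = section$beads$bead_type_id,
      lg = log2(section$beads$intensity))
    out <- as.data.frame(.summarize_core(dt))
    out$section_id <- NULL
    out <- out[order(out$bead_type_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "meta") <- section$meta
  class(out) <- c("section_summary", class(out))
  out
}

#' Empirical detection p-values from negative controls
#'
#' The detection score of bead-type p on a section is the empirical upper
#' tail probability of its summarised log2 intensity among the negative
#' controls:
#' `p = (1 + #{negatives q != p with mean_q > mean_p}) / (N + 1)` with `N`
#' the number of other summarised negatives.  With this convention p is
#' always positive and the negatives' own detection p-values are exactly
#' uniform on \{1/N, ..., 1\}, so a fraction alpha of them "detect"
#' expression by construction.
#'
#' @param summary A `"section_summary"` from [summarize_section()].
#' @param annotation Annotation table (see [read_annotation()]).
#' @return The summary with a `detection_p` column appended.
#' @export
detection_pvalues <- function(summary, annotation) {
  cat_of <- annotation$category[match(summary$bead_type_id,
                                      annotation$bead_type_id)]
  is_neg <- !is.na(cat_of) & cat_of == "negative" & summary$n_used >= 1
  n_neg <- sum(is_neg)
  if (n_neg < 2)
    stop("need at least two summarised negative controls, got ", n_neg,
         call. = FALSE)
  neg_sorted <- sort(summary$log2_mean[is_neg])
  n_greater <- n_neg - findInterval(summary$log2_mean, neg_sorted)
  denom <- ifelse(is_neg, n_neg, n_neg + 1)  # self excluded for negatives
  summary$detection_p <- (1 + n_greater) / denom
  summary$detection_p[summary$n_used < 1] <- NA_real_
  summary
}

#' Summarise a whole experiment into expression matrices
#'
#' Runs [summarize_section()] logic and [detection_pvalues()] for every
#' section in one grouped pass and assembles the three aligned matrices
#' (mean log2, bead counts, detection p).  Rows cover the union of the
#' annotation's bead-types and any observed ones, columns follow the input
#' section order.
#'
#' @param sections Named list of [bead_section()]s.
#' @param annotation Annotation table.
#' @return A [bead_expression()].
#' @export
preprocess_experiment <- function(sections, annotation) {
  stopifnot(length(sections) > 0)
  section_ids <- vapply(sections, function(s) s$meta$section_id, character(1))
  dt <- data.table::rbindlist(lapply(sections, function(s)
    data.table::data.table(section_id = s$meta$section_id,
                           bead_type_id = s$beads$bead_type_id,
                           lg = log2(s$beads$intensity))))
  summ <- .summarize_core(dt)

  ids <- union(annotation$bead_type_id, unique(summ$bead_type_id))
  shape <- function(value_col, fill = NA_real_) {
    m <- matrix(fill, nrow = length(ids), ncol = length(section_ids),
                dimnames = list(ids, section_ids))
    m[cbind(match(summ$bead_type_id, ids),
            match(summ$section_id, section_ids))] <- summ[[value_col]]
    m
  }
  log2_mean <- shape("log2_mean")
  n_beads <- shape("n_used", fill = 0)
  mode(n_beads) <- "integer"

  is_neg <- ids %in% annotation$bead_type_id[annotation$category == "negative"]
  detection <- matrix(NA_real_, length(ids), length(section_ids),
                      dimnames = list(ids, section_ids))
  for (j in seq_along(section_ids)) {
    x <- log2_mean[, j]
    ok <- !is.na(x)
    negs <- sort(x[ok & is_neg])
    n_neg <- length(negs)
    if (n_neg < 2)
      stop("section ", section_ids[j], " has fewer than two summarised ",
           "negative controls", call. = FALSE)
    n_greater <- n_neg - findInterval(x[ok], negs)
    denom <- ifelse(is_neg[ok], n_neg, n_neg + 1)
    detection[ok, j] <- (1 + n_greater) / denom
  }
  bead_expression(log2_mean, n_beads, detection)
}

#' Within-group quantile normalisation
#'
#' Quantile-normalises the summarised log2 means across the sections of
#' each group (in the canonical design, each starting quantity), replacing
#' every section's sorted values by the mean sorted profile of its group.
#' Ties share the mean of the reference values of the tied block and
#' missing entries are tolerated.  Bead counts and detection p-values are
#' untouched: detection is computed per section from ranks, which
#' normalisation preserves.
#'
#' @param em A [bead_expression()].
#' @param groups Named character/numeric vector mapping section id to
#'   group label (e.g. the starting quantity).
#' @return A new [bead_expression()] with normalised `log2_mean`.
#' @export
quantile_normalize <- function(em, groups) {
  stopifnot(inherits(em, "bead_expression"))
  sections <- colnames(em$log2_mean)
  if (!all(sections %in% names(groups)))
    stop("'groups' must name every section", call. = FALSE)
  m <- em$log2_mean
  for (g in unique(groups[sections])) {
    cols <- sections[groups[sections] == g]
    if (length(cols) < 2) {
      warning("group '", g, "' has a single section; left unchanged")
      next
    }
    m[, cols] <- limma::normalizeQuantiles(m[, cols, drop = FALSE],
                                           ties = TRUE)
  }
  bead_expression(m, em$n_beads, em$detection_p)
}

#' Restrict to the analysis-group of bead-types
#'
#' A bead-type enters the analysis-group iff its annotation is reliable
#' (`is_perfect`), its probe GC content lies in the hybridisation-friendly
#' 20-35 base range, and it is represented by at least `min_beads` beads
#' on every section under analysis.
#'
#' @param annotation Annotation table.
#' @param counts Bead-count matrix (bead-types x sections), e.g.
#'   `em$n_beads`.
#' @param gc_range Inclusive GC bounds, default `c(20, 35)`.
#' @param min_beads Minimum beads per section, default 6.
#' @return Character vector of retained bead-type ids.
#' @export
analysis_group_filter <- function(annotation, counts,
                                  gc_range = c(20L, 35L), min_beads = 6L) {
  idx <- match(annotation$bead_type_id, rownames(counts))
  min_count <- rep(0L, nrow(annotation))
  has <- !is.na(idx)
  if (any(has))
    min_count[has] <- apply(counts[idx[has], , drop = FALSE], 1, min)
  keep <- annotation$is_perfect &
    annotation$gc_count >= gc_range[1] & annotation$gc_count <= gc_range[2] &
    min_count >= min_beads
  annotation$bead_type_id[keep]
}
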