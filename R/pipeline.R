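# End-to-end orchestration: the canned synthetic replica of the titration
# study (simulate -> preprocess -> filter -> detect -> fit -> concordance
# -> cross-quantity normalisation) and the analytic chance-expectation
# report.

#' Configuration for a replica run
#'
#' @param generator A [generator_config()]; its seed is overridden by
#'   `seed`.
#' @param detection_alpha Per-section detection level (default 0.01).
#' @param de_alpha Differential-expression level for the dilution-model
#'   Wald test (default 0.001).
#' @param fit_models Whether to fit the dilution model per quantity
#'   (the slow stage); detection analyses run regardless.
#' @param metanorm_low Low starting quantity used in the cross-quantity
#'   normalisation demonstration (the reference is the highest quantity).
#' @param seed Master seed for the whole run.
#' @return List of class `"replica_config"`.
#' @export
replica_config <- function(generator = generator_config(),
                           detection_alpha = 0.01,
                           de_alpha = 0.001,
                           fit_models = TRUE,
                           metanorm_low = 50,
                           seed = 1L) {
  if (detection_alpha <= 0 || detection_alpha >= 1)
    stop("detection_alpha must lie in (0, 1)", call. = FALSE)
  if (de_alpha <= 0 || de_alpha >= 1)
    stop("de_alpha must lie in (0, 1)", call. = FALSE)
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, detection_alpha = detection_alpha,
                 de_alpha = de_alpha, fit_models = fit_models,
                 metanorm_low = metanorm_low, seed = as.integer(seed)),
            class = "replica_config")
}

.msg <- function(verbose, ...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the synthetic titration replica end to end
#'
#' Simulates a ground-truthed experiment, preprocesses it to summarised
#' matrices, quantile-normalises within each starting quantity, restricts
#' to the analysis-group, derives expression calls and their concordance
#' against the highest quantity, optionally fits the dilution model per
#' quantity (DE calls, DE concordance, signal-to-noise and sample-size
#' inflation), and evaluates cross-quantity normalisation strategies
#' against a replicate-section gold standard.
#'
#' @param config A [replica_config()].
#' @param out_dir Optional directory; when given, tabular results and a
#'   run manifest are written there as TSV/JSON.
#' @param verbose Emit progress messages to stderr.
#' @return List with elements `design`, `truth`, `annotation`,
#'   `expression` (normalised [bead_expression()]), `analysis_group`,
#'   `detection_summary`, `detection_concordance`, `calls` (per-quantity
#'   call tables), and when `fit_models`: `fits`, `de_summary`,
#'   `de_concordance`, `snr`; plus `metanorm` and `manifest`.
#' @export
run_replica <- function(config = replica_config(), out_dir = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "replica_config"))
  gen <- config$generator
  quantities <- sort(unique(gen$quantities), decreasing = TRUE)
  ref_q <- quantities[1]

  .msg(verbose, "simulating ", gen$n_bead_types, " bead-types x ",
       length(gen$quantities) * length(gen$mixtures) * 2, " sections")
  sim <- simulate_experiment(gen)
  design <- sim$design

  .msg(verbose, "summarising bead-level data")
  em <- preprocess_experiment(sim$sections, sim$annotation)
  groups <- setNames(design$quantity_ng, design$section_id)
  emn <- quantile_normalize(em, groups)
  group <- analysis_group_filter(sim$annotation,
                                 em$n_beads[, design$section_id])
  .msg(verbose, length(group), " bead-types in the analysis-group")

  # Detection calls per quantity and concordance vs the reference quantity
  calls <- list()
  det_rows <- list()
  for (q in quantities) {
    cols <- design$section_id[design$quantity_ng == q]
    cl <- expression_calls(em$detection_p[group, cols, drop = FALSE],
                           design, alpha = config$detection_alpha)
    calls[[as.character(q)]] <- cl
    det_rows[[as.character(q)]] <- data.frame(
      quantity_ng = q,
      detected_any = sum(cl$detected_any),
      detected_both_pure = sum(cl$detected_both_pure),
      detected_all = sum(cl$detected_all),
      mean_sections_all = attr(cl, "mean_sections_all"),
      mean_sections_detected = attr(cl, "mean_sections_detected"))
  }
  detection_summary <- do.call(rbind, det_rows)
  rownames(detection_summary) <- NULL

  both_pure_set <- function(q) {
    cl <- calls[[as.character(q)]]
    cl$bead_type_id[cl$detected_both_pure]
  }
  detection_concordance <- do.call(rbind, lapply(
    quantities[-1], function(q) {
      r <- consistency(both_pure_set(q), both_pure_set(ref_q))
      data.frame(test_quantity_ng = q, reference_quantity_ng = ref_q,
                 sensitivity = r$sensitivity, fdr = r$fdr,
                 n_ref = r$n_ref, n_test = r$n_test,
                 n_overlap = r$n_overlap)
    }))

  out <- list(design = design, truth = sim$truth,
              annotation = sim$annotation, expression = emn,
              analysis_group = group,
              detection_summary = detection_summary,
              detection_concordance = detection_concordance,
              calls = calls)

  if (config$fit_models) {
    fits <- list()
    de_sets <- list()
    snr_rows <- list()
    for (q in quantities) {
      .msg(verbose, "fitting dilution model at ", q, " ng")
      f <- fit_all(emn, design, q, group)
      fits[[as.character(q)]] <- f
      de_sets[[as.character(q)]] <-
        f$bead_type_id[!is.na(f$p_value) & f$p_value < config$de_alpha]
      s <- snr_summary(f)
      snr_rows[[as.character(q)]] <- data.frame(
        quantity_ng = q, median_se_over_delta = s$median_ratio,
        n_used = s$n_used, n_excluded = s$n_excluded)
    }
    snr <- do.call(rbind, snr_rows)
    rownames(snr) <- NULL
    ref_snr <- snr$median_se_over_delta[snr$quantity_ng == ref_q]
    snr$snr_ratio_vs_ref <- snr$median_se_over_delta / ref_snr
    snr$sample_size_inflation <- vapply(
      snr$median_se_over_delta, sample_size_inflation, numeric(1),
      snr_ref = ref_snr)

    de_summary <- data.frame(
      quantity_ng = quantities,
      n_de = vapply(as.character(quantities),
                    function(q) length(de_sets[[q]]), integer(1)),
      n_group = length(group))
    de_concordance <- do.call(rbind, lapply(quantities[-1], function(q) {
      r <- consistency(de_sets[[as.character(q)]],
                       de_sets[[as.character(ref_q)]])
      data.frame(test_quantity_ng = q, reference_quantity_ng = ref_q,
                 sensitivity = r$sensitivity, fdr = r$fdr,
                 n_ref = r$n_ref, n_test = r$n_test, n_overlap = r$n_overlap)
    }))
    out$fits <- fits
    out$de_summary <- de_summary
    out$de_concordance <- de_concordance
    out$snr <- snr
  }

  out$metanorm <- .metanorm_eval(emn, design, group,
                                 low_q = config$metanorm_low,
                                 high_q = ref_q)

  manifest <- list(package = "beadtitration",
                   version = as.character(utils::packageVersion("beadtitration")),
                   seed = config$seed,
                   n_bead_types = gen$n_bead_types,
                   quantities = quantities,
                   detection_alpha = config$detection_alpha,
                   de_alpha = config$de_alpha,
                   config_hash = .config_hash(config))
  out$manifest <- manifest

  if (!is.null(out_dir)) .write_replica(out, out_dir, config)
  out
}

# Stable content hash (polynomial rolling hash mod a Mersenne prime) of the
# configuration's deparsed form, so a manifest pins the exact settings.
.config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% m
  sprintf("%08x", as.integer(h))
}

# Pick pure sections for the cross-quantity normalisation comparison:
# project a Brain-pure low-quantity section onto the high-quantity scale
# and score it against a Brain-pure high-quantity reference section, with
# the second high-quantity Brain replicate as the gold standard.
.metanorm_eval <- function(em, design, group, low_q, high_q) {
  pick <- function(q, c_val) {
    ids <- design$section_id[design$quantity_ng == q & design$c_uhrr == c_val]
    if (length(ids) < 1) stop("no pure section at ", q, " ng", call. = FALSE)
    ids
  }
  brain_low <- pick(low_q, 0)[1]
  uhrr_low <- pick(low_q, 1)[1]
  uhrr_high <- pick(high_q, 1)[1]
  brain_high <- pick(high_q, 0)
  if (length(brain_high) < 2)
    stop("need two high-quantity Brain-pure sections", call. = FALSE)
  m <- em$log2_mean[group, , drop = FALSE]
  src <- m[, brain_low]
  ref <- m[, brain_high[1]]

  pred_quantile <- quantile_map(src, m[, uhrr_high])
  pred_bias <- smooth_bias_correct(src, m[, uhrr_low], m[, uhrr_high])
  strategies <- list(replicate = m[, brain_high[2]],
                     bias_corrected = pred_bias,
                     quantile_mapped = pred_quantile,
                     raw = src)
  evals <- lapply(strategies, evaluate_normalization, reference = ref)
  data.frame(strategy = names(evals),
             median_squared_error = vapply(evals, `[[`, numeric(1),
                                           "median_se"),
             n = vapply(evals, `[[`, integer(1), "n"),
             source_section = brain_low,
             reference_section = brain_high[1],
             row.names = NULL)
}

.write_replica <- function(out, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name)
    data.table::fwrite(x, file.path(out_dir, name), sep = "\t", na = "")
  wr(out$detection_summary, "detection_summary.tsv")
  wr(out$detection_concordance, "detection_concordance.tsv")
  if (!is.null(out$de_summary)) {
    wr(out$de_summary, "de_summary.tsv")
    wr(out$de_concordance, "de_concordance.tsv")
    wr(out$snr, "snr_summary.tsv")
    for (q in names(out$fits))
      wr(out$fits[[q]], sprintf("fits_%sng.tsv", q))
  }
  wr(out$metanorm, "metanorm_evaluation.tsv")
  wr(out$design, "design.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(out$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    writeLines(paste(names(out$manifest),
                     vapply(out$manifest, function(v)
                       paste(format(v), collapse = ","), character(1)),
                     sep = ": "), manifest_path)
  }
  invisible(out_dir)
}

#' Analytic chance-expectation report for a detection design
#'
#' Expected numbers of bead-types detected by chance alone (uniform
#' detection p-values): in at least one of the design's sections, in both
#' pure sources, and among the negative controls of a single section.
#'
#' @param n_types Analysis-group size (canonical: 21627).
#' @param n_sections Sections per quantity (canonical: 18).
#' @param alpha Detection level.
#' @param n_negative Negative-control bead-types (canonical: 759).
#' @param n_pure Pure sections per source (canonical: 2).
#' @return List with `any_section`, `both_pure`,
#'   `negatives_per_section`.
#' @export
run_chance_expectations <- function(n_types = 21627, n_sections = 18,
                                    alpha = 0.01, n_negative = 759,
                                    n_pure = 2L) {
  list(
    any_section = expected_chance_detections(n_types, n_sections, alpha,
                                             mode = "any"),
    both_pure = expected_chance_detections(n_types, alpha = alpha,
                                           mode = "both_pure",
                                           n_pure = n_pure),
    negatives_per_section = n_negative * alpha)
}
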