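# Ground-truthed simulator for two-source titration BeadArray experiments.
#
# Forward model per bead of type p in section (mixture c, quantity r):
#   intensity = (b_r * base_p + a_r * (c * U_p + (1 - c) * B_p)) * 2^eps,
#   eps ~ N(0, sigma)  (variance-inflated with probability outlier_rate)
# U_p / B_p are the raw-scale source-specific signals at the reference
# quantity; a_r attenuates specific signal as starting RNA drops while the
# additive background b_r stays roughly level, which is the pattern seen in
# control probes when the amount of hybridised cRNA is held constant.
# base_p is a reproducible probe-specific non-specific-binding factor
# (lognormal, median 1) shared by all sections: without it every
# unexpressed probe would sit at an exchangeable background level, whereas
# real negative controls show probe-specific spread and a persistent
# detected tail far above the ~1% expected by chance.

#' Configuration for the synthetic bead-level generator
#'
#' Defaults emulate the canonical experiment: ~20 bead replicates per type,
#' 759 negative-control and 7 housekeeping bead-types, four starting
#' quantities (250/100/50/10 ng) with attenuation and background calibrated
#' to the observed control-probe medians (negative-control medians near
#' log2 = 5.8 at all quantities; housekeeping medians falling from 13.46 at
#' 250 ng to 11.32 at 10 ng), and the nine-level mixture series.
#'
#' @param n_bead_types Number of regular (non-control) bead-types.
#' @param frac_expressed Named fractions (`neither`, `brain_only`,
#'   `uhrr_only`, `both`) of regular bead-types expressed in each source;
#'   must sum to 1.
#' @param n_negative,n_housekeeping Control bead-type counts.
#' @param expr_log2_mean,expr_log2_sd Normal parameters (log2 raw scale) of
#'   the shared expression level of bead-types expressed in both sources.
#' @param lfc_sd SD of the true log2 fold change (UHRR vs Brain) for
#'   bead-types expressed in both sources.
#' @param single_log2_mean,single_log2_sd Parameters for bead-types
#'   expressed in exactly one source.
#' @param baseline_log2_sd SD (log2) of the reproducible probe-specific
#'   non-specific-binding factor multiplying the background; shared across
#'   sections and quantities, median 1.  Set to 0 for an exchangeable
#'   background.
#' @param hk_uhrr_log2,hk_brain_log2,hk_log2_sd,hk_floor Housekeeping
#'   signal medians per source (log2 raw), spread, and a raw-scale floor.
#' @param gc_size,gc_prob,gc_range Probe GC counts are Binomial(`gc_size`,
#'   `gc_prob`) clamped to `gc_range` (bases of the 50-mer).
#' @param p_perfect Probability that a regular bead-type carries a reliable
#'   ("perfect") annotation; controls are never flagged perfect.
#' @param quantities Starting quantities (ng) of the design.
#' @param mixtures UHRR proportions of the titration series.
#' @param attenuation Named (by quantity) multiplicative attenuation `a_r`
#'   of specific signal, 1 at the reference quantity.
#' @param background Named (by quantity) raw-scale additive background
#'   `b_r`.
#' @param bead_noise_sd Per-bead log2 noise SD used for quantities without
#'   an entry in `sigma_by_quantity`.
#' @param sigma_by_quantity Named per-quantity noise SDs.  The defaults
#'   rise as starting RNA falls and are calibrated so that the pipeline's
#'   median standard-error-to-estimate ratios from the dilution fits land
#'   near the observed ladder (about 0.23, 0.28, 0.31 and 0.52 for 250,
#'   100, 50 and 10 ng): signal attenuation alone reproduces only part of
#'   the signal-to-noise loss at low starting quantities.
#' @param outlier_rate Probability a bead's noise SD is inflated.
#' @param outlier_sd_multiplier Inflation factor (> 1) for outlier beads.
#' @param replicate_mean Mean of the (zero-truncated Poisson) bead
#'   replicate count per bead-type and section.
#' @param decode_loss Probability each bead is lost to decoding.
#' @param artifact_patches Number of rectangular high-intensity spatial
#'   patches injected per section (0 disables).
#' @param artifact_side,artifact_multiplier Patch side length (fraction of
#'   the coordinate range) and intensity multiplier.
#' @param seed Master seed.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_bead_types = 5000,
                             frac_expressed = c(neither = 0.22,
                                                brain_only = 0.08,
                                                uhrr_only = 0.08,
                                                both = 0.62),
                             n_negative = 759,
                             n_housekeeping = 7,
                             expr_log2_mean = 7.8,
                             expr_log2_sd = 2.0,
                             lfc_sd = 1.2,
                             single_log2_mean = 7.0,
                             single_log2_sd = 1.8,
                             baseline_log2_sd = 0.3,
                             hk_uhrr_log2 = 13.46,
                             hk_brain_log2 = 12.47,
                             hk_log2_sd = 0.25,
                             hk_floor = 2^10,
                             gc_size = 50,
                             gc_prob = 0.55,
                             gc_range = c(10L, 45L),
                             p_perfect = 0.9,
                             quantities = c(250, 100, 50, 10),
                             mixtures = c(1, 0.99, 0.95, 0.90, 0.75,
                                          0.50, 0.25, 0.10, 0),
                             attenuation = c(`250` = 1,
                                             `100` = 2^(13.14 - 13.46),
                                             `50` = 2^(13.09 - 13.46),
                                             `10` = 2^(11.32 - 13.46)),
                             background = c(`250` = 2^5.78,
                                            `100` = 2^5.79,
                                            `50` = 2^5.73,
                                            `10` = 2^5.58),
                             bead_noise_sd = 0.7,
                             sigma_by_quantity = c(`250` = 0.58,
                                                   `100` = 0.68,
                                                   `50` = 0.74,
                                                   `10` = 0.80),
                             outlier_rate = 0.02,
                             outlier_sd_multiplier = 5,
                             replicate_mean = 20,
                             decode_loss = 0.03,
                             artifact_patches = 0L,
                             artifact_side = 0.05,
                             artifact_multiplier = 4,
                             seed = 1L) {
  cfg <- as.list(environment())
  needed <- c("neither", "brain_only", "uhrr_only", "both")
  if (!all(needed %in% names(frac_expressed)))
    stop("frac_expressed must be named: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (abs(sum(frac_expressed) - 1) > 1e-8)
    stop("frac_expressed must sum to 1 (got ", sum(frac_expressed), ")",
         call. = FALSE)
  if (any(frac_expressed < 0))
    stop("frac_expressed must be non-negative", call. = FALSE)
  for (nm in c("outlier_rate", "decode_loss"))
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1)
      stop(nm, " must lie in [0, 1)", call. = FALSE)
  if (outlier_sd_multiplier <= 1)
    stop("outlier_sd_multiplier must exceed 1", call. = FALSE)
  if (bead_noise_sd < 0) stop("bead_noise_sd must be >= 0", call. = FALSE)
  if (replicate_mean <= 0) stop("replicate_mean must be > 0", call. = FALSE)
  qn <- as.character(quantities)
  if (!all(qn %in% names(attenuation)))
    stop("attenuation must be named for every quantity", call. = FALSE)
  if (!all(qn %in% names(background)))
    stop("background must be named for every quantity", call. = FALSE)
  if (any(attenuation <= 0 | attenuation > 1))
    stop("attenuation values must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "generator_config")
}

.noise_sd_for <- function(config, quantity) {
  s <- config$sigma_by_quantity
  if (!is.null(s) && as.character(quantity) %in% names(s))
    unname(s[[as.character(quantity)]])
  else config$bead_noise_sd
}

# Stable per-section seed: polynomial rolling hash of the section id folded
# into the master seed, kept below 2^31 so it is a valid R integer seed.
.derive_seed <- function(master, section_id) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(section_id)) h <- (h * 31 + code) %% m
  as.integer((h + (as.numeric(master) %% m) * 92821) %% m)
}

#' Generate the chip-pairing titration design
#'
#' Lays out `|quantities| * |mixtures|` samples (each occupying two
#' array-sections) across `choose(|quantities|, 2)` chips so that every
#' chip hosts exactly two starting quantities, every unordered pair of
#' quantities shares exactly one chip, and each quantity-by-mixture
#' combination occurs exactly once.  Which mixtures of a quantity land on
#' which of its chips is randomised by `seed`.
#'
#' @param quantities Distinct starting quantities (ng); the canonical
#'   design uses four.
#' @param mixtures UHRR proportions; their number must be divisible by
#'   `length(quantities) - 1`.
#' @param seed Integer seed for the mixture-to-chip assignment.
#' @return A design data.frame (see [read_design()] for columns) that
#'   passes [validate_design()].
#' @export
generate_design <- function(quantities = c(250, 100, 50, 10),
                            mixtures = c(1, 0.99, 0.95, 0.90, 0.75,
                                         0.50, 0.25, 0.10, 0),
                            seed = 1L) {
  quantities <- sort(unique(quantities), decreasing = TRUE)
  nq <- length(quantities)
  nm <- length(mixtures)
  if (nq < 2) stop("need at least two quantities", call. = FALSE)
  if (anyDuplicated(mixtures)) stop("mixtures must be distinct", call. = FALSE)
  if (nm %% (nq - 1) != 0)
    stop("number of mixtures (", nm, ") must be divisible by ",
         nq - 1, " for a balanced pairing", call. = FALSE)
  per_chip <- nm / (nq - 1)

  pairs <- utils::combn(quantities, 2)
  n_chips <- ncol(pairs)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  # For each quantity, randomly partition its mixtures across its chips.
  alloc <- list()
  for (q in quantities) {
    shuffled <- mixtures[sample.int(nm)]
    chips_of_q <- which(pairs[1, ] == q | pairs[2, ] == q)
    for (i in seq_along(chips_of_q)) {
      key <- paste0(chips_of_q[i], "|", q)
      alloc[[key]] <- shuffled[((i - 1) * per_chip + 1):(i * per_chip)]
    }
  }

  rows <- list()
  for (chip in seq_len(n_chips)) {
    chip_id <- sprintf("chip%02d", chip)
    samples <- list()
    for (q in pairs[, chip]) {
      for (m in alloc[[paste0(chip, "|", q)]])
        samples[[length(samples) + 1L]] <- list(q = q, m = m)
    }
    ord <- sample(length(samples))  # interleave quantities along the chip
    pos <- 0L
    for (s in samples[ord]) {
      sample_id <- sprintf("q%s_m%04d", format(s$q, trim = TRUE),
                           as.integer(round(1000 * s$m)))
      for (k in 1:2) {
        pos <- pos + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          section_id = sprintf("%s_s%d", sample_id, k),
          chip_id = chip_id, sample_id = sample_id,
          c_uhrr = s$m, quantity_ng = s$q, position = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Draw the ground-truth signal table and annotation
#'
#' Samples raw-scale source-specific signals `U_p` (UHRR) and `B_p`
#' (Brain) for every bead-type at the reference quantity, plus the
#' annotation consumed downstream.  Negative controls carry zero specific
#' signal in both sources; housekeeping controls sit at a high floor in
#' both.  Regular bead-types fall into four expression classes (neither /
#' Brain only / UHRR only / both) with configured fractions.
#'
#' @param config A [generator_config()].
#' @return List with elements `truth` (data.frame: `bead_type_id`,
#'   `u_raw`, `b_raw`, `base_raw` — the probe-specific background factor —
#'   `category`, `gc_count`, `is_perfect`) and `annotation` (the same
#'   minus the signal columns).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(config$seed))

  n <- config$n_bead_types
  classes <- sample(names(config$frac_expressed), n, replace = TRUE,
                    prob = config$frac_expressed)
  u <- b <- numeric(n)
  i_both <- classes == "both"
  n_both <- sum(i_both)
  base <- rnorm(n_both, config$expr_log2_mean, config$expr_log2_sd)
  lfc <- rnorm(n_both, 0, config$lfc_sd)
  u[i_both] <- 2^(base + lfc / 2)
  b[i_both] <- 2^(base - lfc / 2)
  i_u <- classes == "uhrr_only"
  u[i_u] <- 2^rnorm(sum(i_u), config$single_log2_mean, config$single_log2_sd)
  i_b <- classes == "brain_only"
  b[i_b] <- 2^rnorm(sum(i_b), config$single_log2_mean, config$single_log2_sd)

  nn <- config$n_negative
  nh <- config$n_housekeeping
  hk_u <- pmax(2^rnorm(nh, config$hk_uhrr_log2, config$hk_log2_sd),
               config$hk_floor)
  hk_b <- pmax(2^rnorm(nh, config$hk_brain_log2, config$hk_log2_sd),
               config$hk_floor)

  ids <- c(sprintf("bt_%06d", seq_len(n)),
           if (nn) sprintf("neg_%04d", seq_len(nn)),
           if (nh) sprintf("hk_%02d", seq_len(nh)))
  n_all <- n + nn + nh
  base_fac <- if (config$baseline_log2_sd > 0)
    2^rnorm(n_all, 0, config$baseline_log2_sd) else rep(1, n_all)
  truth <- data.frame(
    bead_type_id = ids,
    u_raw = c(u, rep(0, nn), hk_u),
    b_raw = c(b, rep(0, nn), hk_b),
    base_raw = base_fac,
    category = c(rep("regular", n), rep("negative", nn),
                 rep("housekeeping", nh)),
    gc_count = pmin(pmax(rbinom(n + nn + nh, config$gc_size,
                                config$gc_prob),
                         config$gc_range[1]), config$gc_range[2]),
    is_perfect = c(runif(n) < config$p_perfect, rep(FALSE, nn + nh)),
    stringsAsFactors = FALSE)
  list(truth = truth,
       annotation = truth[, c("bead_type_id", "category", "gc_count",
                              "is_perfect")])
}

# Zero-truncated Poisson replicate counts.
.rtpois <- function(k, lambda) {
  x <- rpois(k, lambda)
  while (any(zero <- x == 0L)) x[zero] <- rpois(sum(zero), lambda)
  x
}

#' Simulate one bead-level array-section
#'
#' Applies the forward model to every bead-type of the truth table at this
#' section's mixture proportion and starting quantity: replicate counts are
#' zero-truncated Poisson thinned by decode loss, expected raw intensity is
#' `b_r + a_r (c U + (1-c) B)`, and multiplicative log-normal noise is
#' added per bead (variance-inflated for a small outlier fraction).
#' Optional rectangular high-intensity spatial patches can be injected;
#' affected beads are flagged in an `artifact` attribute (patch correction
#' itself is out of scope here).
#'
#' @param truth Truth data.frame from [simulate_truth()].
#' @param meta One design row for the section.
#' @param config A [generator_config()].
#' @param seed Integer seed for this section.
#' @return A [bead_section()].
#' @export
simulate_section <- function(truth, meta, config, seed) {
  stopifnot(inherits(config, "generator_config"))
  meta <- as.data.frame(meta)
  .check_meta_row(meta)
  q <- as.character(meta$quantity_ng)
  if (!q %in% names(config$attenuation))
    stop("no attenuation configured for quantity ", q, call. = FALSE)
  a_r <- unname(config$attenuation[[q]])
  b_r <- unname(config$background[[q]])
  sigma <- .noise_sd_for(config, q)
  cc <- meta$c_uhrr

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  n_types <- nrow(truth)
  counts <- .rtpois(n_types, config$replicate_mean)
  if (config$decode_loss > 0)
    counts <- rbinom(n_types, counts, 1 - config$decode_loss)
  keep <- counts > 0L
  idx <- rep(which(keep), counts[keep])
  n_beads <- length(idx)

  base_fac <- if ("base_raw" %in% names(truth)) truth$base_raw else 1
  mu <- b_r * base_fac + a_r * (cc * truth$u_raw + (1 - cc) * truth$b_raw)
  sd_bead <- rep(sigma, n_beads)
  if (config$outlier_rate > 0 && sigma > 0) {
    infl <- runif(n_beads) < config$outlier_rate
    sd_bead[infl] <- sigma * config$outlier_sd_multiplier
  }
  eps <- if (sigma > 0) rnorm(n_beads, 0, sd_bead) else numeric(n_beads)
  intensity <- mu[idx] * 2^eps
  x <- runif(n_beads, 0, 1000)
  y <- runif(n_beads, 0, 1000)

  artifact <- rep(FALSE, n_beads)
  if (config$artifact_patches > 0) {
    side <- config$artifact_side * 1000
    for (p in seq_len(config$artifact_patches)) {
      x0 <- runif(1, 0, 1000 - side); y0 <- runif(1, 0, 1000 - side)
      hit <- x >= x0 & x <= x0 + side & y >= y0 & y <= y0 + side
      intensity[hit] <- intensity[hit] * config$artifact_multiplier
      artifact <- artifact | hit
    }
  }

  section <- bead_section(meta, data.frame(
    bead_type_id = truth$bead_type_id[idx],
    intensity = intensity, x = x, y = y, stringsAsFactors = FALSE))
  if (any(artifact)) attr(section, "artifact") <- artifact
  section
}

#' Simulate a whole titration experiment
#'
#' Draws one truth table and one bead-level section per design row.
#' Section seeds are derived deterministically from the master seed and the
#' section id, so adding sections never perturbs existing ones and
#' identical seeds give byte-identical output.
#'
#' @param config A [generator_config()].
#' @param design Optional design data.frame; by default the canonical
#'   layout is generated from the config's quantities and mixtures.
#' @return List with `truth`, `annotation`, `design` and `sections` (a
#'   named list of [bead_section()]s).
#' @export
simulate_experiment <- function(config, design = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(design))
    design <- generate_design(config$quantities, config$mixtures,
                              seed = config$seed)
  tr <- simulate_truth(config)
  sections <- vector("list", nrow(design))
  names(sections) <- design$section_id
  for (i in seq_len(nrow(design))) {
    s <- .derive_seed(config$seed, design$section_id[i])
    sections[[i]] <- simulate_section(tr$truth, design[i, , drop = FALSE],
                                      config, seed = s)
  }
  list(truth = tr$truth, annotation = tr$annotation,
       design = design, sections = sections)
}
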