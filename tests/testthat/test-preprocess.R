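test_that("the 3-MAD outlier rule matches hand evaluation", {
  expect_equal(mad_outlier_mask(rep(10, 5)), rep(TRUE, 5))
  # median 3, MAD 1: keep 1..4, drop 100
  expect_equal(mad_outlier_mask(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # degenerate MAD = 0: keep only values at the median
  expect_equal(mad_outlier_mask(c(5, 5, 5, 9)), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(mad_outlier_mask(numeric(0)), "empty")

  # invariance under shift and positive scaling
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    expect_identical(mad_outlier_mask(a * x + b), mad_outlier_mask(x))
  }
})

test_that("section summarisation applies log2, MAD filtering and counts", {
  s1 <- toy_section(c(4, 4, 4))
  sm1 <- summarize_section(s1)
  expect_equal(sm1$log2_mean, 2)
  expect_equal(sm1$n_used, 3L)
  expect_equal(sm1$n_removed, 0L)

  # log2 = [1,2,3,2,12]; median 2, MAD 1 -> drop 12; mean(1,2,3,2) = 2
  s2 <- toy_section(c(2, 4, 8, 4, 4096))
  sm2 <- summarize_section(s2)
  expect_equal(sm2$log2_mean, 2)
  expect_equal(sm2$n_removed, 1L)

  empty <- toy_section(numeric(0), ids = character(0))
  expect_equal(nrow(summarize_section(empty)), 0L)

  # several bead-types, one per group accounting
  s3 <- toy_section(c(8, 8, 2, 2, 2), ids = c("a", "a", "b", "b", "b"))
  sm3 <- summarize_section(s3)
  expect_equal(sm3$bead_type_id, c("a", "b"))
  expect_equal(sm3$log2_mean, c(3, 1))
})

test_that("detection p-values rank against the negative controls", {
  n_neg <- 100
  ids <- c("target_hi", "target_lo", sprintf("neg_%03d", 1:n_neg))
  ann <- data.frame(bead_type_id = ids,
                    category = c("regular", "regular", rep("negative", n_neg)),
                    gc_count = 25L, is_perfect = TRUE,
                    stringsAsFactors = FALSE)
  sm <- data.frame(bead_type_id = ids,
                   log2_mean = c(20, 1, seq(5, 8, length.out = n_neg)),
                   log2_sd = 0.1, n_used = 10L, n_removed = 0L,
                   stringsAsFactors = FALSE)
  class(sm) <- c("section_summary", class(sm))
  out <- detection_pvalues(sm, ann)
  expect_equal(out$detection_p[out$bead_type_id == "target_hi"], 1 / 101)
  expect_equal(out$detection_p[out$bead_type_id == "target_lo"], 1)
  # negatives' own p-values are exactly uniform on {1/100, ..., 1}
  pn <- sort(out$detection_p[grepl("^neg", out$bead_type_id)])
  expect_equal(pn, (1:100) / 100)

  expect_error(detection_pvalues(sm[1:2, ], ann), "negative controls")
})

test_that("unexpressed bead-types have uniform detection p-values", {
  # regular bead-types with no specific signal are exchangeable with the
  # negatives, so their detection scores should be uniform
  cfg <- generator_config(n_bead_types = 500, n_negative = 400,
                          frac_expressed = c(neither = 1, brain_only = 0,
                                             uhrr_only = 0, both = 0),
                          seed = 5)
  tr <- simulate_truth(cfg)
  metas <- lapply(1:4, function(i)
    toy_meta(section_id = paste0("s", i), c_uhrr = c(1, 1, 0, 0)[i]))
  sections <- lapply(seq_along(metas), function(i)
    simulate_section(tr$truth, metas[[i]], cfg, seed = 100 + i))
  names(sections) <- paste0("s", 1:4)
  em <- preprocess_experiment(sections, tr$annotation)
  reg <- tr$annotation$bead_type_id[tr$annotation$category == "regular"]
  p <- as.vector(em$detection_p[reg, ])
  p <- p[!is.na(p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # per section, exactly the top 1% of negatives "detect" expression
  neg <- tr$annotation$bead_type_id[tr$annotation$category == "negative"]
  for (j in 1:4)
    expect_equal(sum(em$detection_p[neg, j] < 0.01, na.rm = TRUE), 3L)
})

test_that("quantile normalisation matches the mean-sorted reference", {
  ids <- c("a", "b", "c")
  m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  rownames(m) <- ids
  em <- bead_expression(m, matrix(5L, 3, 2, dimnames = dimnames(m)),
                        matrix(0.5, 3, 2, dimnames = dimnames(m)))
  g <- c(s1 = "q", s2 = "q")
  out <- quantile_normalize(em, g)
  expect_equal(unname(out$log2_mean[, "s1"]), c(1.5, 3, 4.5))
  expect_equal(unname(out$log2_mean[, "s2"]), c(1.5, 3, 4.5))

  # identical sections are a fixed point; the map is idempotent
  m2 <- cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3))
  rownames(m2) <- ids
  em2 <- bead_expression(m2, matrix(5L, 3, 2, dimnames = dimnames(m2)),
                         matrix(0.5, 3, 2, dimnames = dimnames(m2)))
  out2 <- quantile_normalize(em2, g)
  expect_equal(out2$log2_mean, m2)
  once <- quantile_normalize(em, g)
  twice <- quantile_normalize(once, g)
  expect_equal(twice$log2_mean, once$log2_mean, tolerance = 1e-12)

  # sorted values agree across sections of a group afterwards
  set.seed(2)
  m3 <- matrix(rnorm(40), 10, 4,
               dimnames = list(sprintf("b%02d", 1:10), paste0("s", 1:4)))
  em3 <- bead_expression(m3, matrix(5L, 10, 4, dimnames = dimnames(m3)),
                         matrix(0.5, 10, 4, dimnames = dimnames(m3)))
  g3 <- setNames(c("x", "x", "y", "y"), paste0("s", 1:4))
  out3 <- quantile_normalize(em3, g3)
  expect_equal(sort(out3$log2_mean[, 1]), sort(out3$log2_mean[, 2]),
               ignore_attr = TRUE)
  expect_equal(sort(out3$log2_mean[, 3]), sort(out3$log2_mean[, 4]),
               ignore_attr = TRUE)

  # a single-section group is left unchanged with a warning
  m4 <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(7, 8, 9))
  rownames(m4) <- ids
  em4 <- bead_expression(m4, matrix(5L, 3, 3, dimnames = dimnames(m4)),
                         matrix(0.5, 3, 3, dimnames = dimnames(m4)))
  expect_warning(
    out4 <- quantile_normalize(em4, c(s1 = "q", s2 = "q", s3 = "solo")),
    "single")
  expect_equal(out4$log2_mean[, "s3"], m4[, "s3"])
})

test_that("the analysis-group filter applies all three criteria", {
  ann <- data.frame(
    bead_type_id = c("keep", "gc_hi", "gc_lo", "imperfect", "sparse"),
    category = "regular",
    gc_count = c(27L, 36L, 19L, 27L, 30L),
    is_perfect = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  counts <- matrix(10L, 5, 3,
                   dimnames = list(ann$bead_type_id, paste0("s", 1:3)))
  counts["sparse", 2] <- 5L
  expect_equal(analysis_group_filter(ann, counts), "keep")
  # boundary GC values are inclusive
  ann2 <- ann; ann2$gc_count <- c(20L, 35L, 19L, 27L, 30L)
  expect_equal(analysis_group_filter(ann2, counts), c("keep", "gc_hi"))
  # a bead-type absent from the count matrix cannot be kept
  ann3 <- rbind(ann, data.frame(bead_type_id = "ghost", category = "regular",
                                gc_count = 25L, is_perfect = TRUE))
  expect_equal(analysis_group_filter(ann3, counts), "keep")
})
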