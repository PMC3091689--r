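test_that("the canonical design lays out 36 samples over six paired chips", {
  d <- generate_design(c(250, 100, 50, 10), canonical_cc()[seq(1, 18, 2)],
                       seed = 11)
  expect_equal(length(unique(d$chip_id)), 6L)
  expect_equal(length(unique(d$sample_id)), 36L)
  expect_equal(nrow(d), 72L)
  expect_length(validate_design(d), 0L)

  # every quantity appears on 3 chips with 3 samples each
  tab <- table(unique(d[, c("chip_id", "sample_id", "quantity_ng")])$quantity_ng)
  expect_true(all(tab == 9L))
})

test_that("general designs pair quantities feasibly and reproducibly", {
  d <- generate_design(c(100, 50), c(1, 0.5, 0), seed = 3)
  expect_equal(length(unique(d$chip_id)), 1L)
  expect_equal(sort(unique(d$quantity_ng)), c(50, 100))
  expect_length(validate_design(d), 0L)

  expect_identical(generate_design(seed = 9), generate_design(seed = 9))
  expect_false(identical(generate_design(seed = 9), generate_design(seed = 10)))
  expect_error(generate_design(c(250, 100, 50), c(1, 0.5, 0)), "divisible")

  # property: many seeds all validate
  for (s in 1:5)
    expect_length(validate_design(generate_design(seed = s)), 0L)
})

test_that("truth tables respect category structure and configuration", {
  cfg <- small_config(n_bead_types = 400, seed = 21)
  tr <- simulate_truth(cfg)
  expect_equal(sum(tr$truth$category == "negative"), 120L)
  expect_equal(sum(tr$truth$category == "housekeeping"), 7L)
  expect_true(all(tr$truth$u_raw[tr$truth$category == "negative"] == 0))
  expect_true(all(tr$truth$b_raw[tr$truth$category == "negative"] == 0))
  hk <- tr$truth[tr$truth$category == "housekeeping", ]
  expect_true(all(hk$u_raw >= cfg$hk_floor & hk$b_raw >= cfg$hk_floor))
  expect_true(all(tr$truth$gc_count >= 10 & tr$truth$gc_count <= 45))
  expect_false(any(tr$annotation$is_perfect[tr$annotation$category != "regular"]))

  # all-unexpressed configuration zeroes every regular signal
  cfg0 <- small_config(frac_expressed = c(neither = 1, brain_only = 0,
                                          uhrr_only = 0, both = 0),
                       seed = 2)
  tr0 <- simulate_truth(cfg0)
  reg <- tr0$truth$category == "regular"
  expect_true(all(tr0$truth$u_raw[reg] == 0) && all(tr0$truth$b_raw[reg] == 0))

  expect_identical(simulate_truth(cfg), simulate_truth(cfg))
  expect_error(generator_config(frac_expressed = c(neither = .5,
                                                   brain_only = .2,
                                                   uhrr_only = .2,
                                                   both = .2)), "sum to 1")
})

test_that("noiseless sections evaluate the forward model exactly", {
  # negative control at 250 ng: every bead exactly at the background level
  cfg <- noiseless_config(n_bead_types = 5, n_negative = 10,
                          n_housekeeping = 2, seed = 4)
  tr <- simulate_truth(cfg)
  sec <- simulate_section(tr$truth, toy_meta(c_uhrr = 1), cfg, seed = 1)
  neg_ids <- tr$truth$bead_type_id[tr$truth$category == "negative"]
  neg_int <- sec$beads$intensity[sec$beads$bead_type_id %in% neg_ids]
  expect_equal(unique(neg_int), 2^5.78, tolerance = 1e-12)

  # hand-computed mixture: c = .5, U = 1000, B = 100, a = 1, b_r = 0
  truth1 <- data.frame(bead_type_id = "p1", u_raw = 1000, b_raw = 100,
                       base_raw = 1, category = "regular", gc_count = 25,
                       is_perfect = TRUE, stringsAsFactors = FALSE)
  cfg1 <- noiseless_config(quantities = 250, attenuation = c(`250` = 1),
                           background = c(`250` = 0))
  sec1 <- simulate_section(truth1, toy_meta(c_uhrr = 0.5), cfg1, seed = 2)
  expect_equal(unique(sec1$beads$intensity), 550, tolerance = 1e-12)
  expect_equal(log2(550), 9.103, tolerance = 1e-3)

  s_a <- simulate_section(tr$truth, toy_meta(), cfg, seed = 99)
  s_b <- simulate_section(tr$truth, toy_meta(), cfg, seed = 99)
  expect_identical(s_a, s_b)
})

test_that("noiseless summarised means equal the forward model for all mixtures", {
  cfg <- noiseless_config(n_bead_types = 40, n_negative = 10,
                          n_housekeeping = 2, seed = 6)
  tr <- simulate_truth(cfg)
  for (cc in c(0, 0.25, 0.9)) {
    sec <- simulate_section(tr$truth, toy_meta(c_uhrr = cc, quantity_ng = 10),
                            cfg, seed = 31)
    sm <- summarize_section(sec)
    i <- match(sm$bead_type_id, tr$truth$bead_type_id)
    a <- cfg$attenuation[["10"]]; b <- cfg$background[["10"]]
    expected <- log2(b + a * (cc * tr$truth$u_raw[i] +
                                (1 - cc) * tr$truth$b_raw[i]))
    expect_equal(sm$log2_mean, expected, tolerance = 1e-12)
    expect_true(all(sm$n_removed == 0))
  }
})

test_that("expected intensity is monotone in the mixture proportion", {
  truth <- data.frame(bead_type_id = c("up", "down"),
                      u_raw = c(1000, 100), b_raw = c(100, 1000),
                      base_raw = 1, category = "regular", gc_count = 25,
                      is_perfect = TRUE, stringsAsFactors = FALSE)
  cfg <- noiseless_config()
  means <- sapply(c(0, .25, .5, .75, 1), function(cc) {
    sec <- simulate_section(truth, toy_meta(c_uhrr = cc), cfg, seed = 8)
    tapply(sec$beads$intensity, sec$beads$bead_type_id, mean)[c("up", "down")]
  })
  expect_true(all(diff(means["up", ]) > 0))
  expect_true(all(diff(means["down", ]) < 0))
})

test_that("control calibration follows the observed quantity pattern", {
  # housekeeping and negative medians: gap shrinks as starting RNA drops
  cfg <- small_config(n_bead_types = 50, seed = 14)
  tr <- simulate_truth(cfg)
  med <- function(q) {
    sec <- simulate_section(tr$truth,
                            toy_meta(c_uhrr = 1, quantity_ng = q),
                            cfg, seed = 40 + q)
    sm <- summarize_section(sec)
    cat_of <- tr$truth$category[match(sm$bead_type_id, tr$truth$bead_type_id)]
    c(hk = median(sm$log2_mean[cat_of == "housekeeping"]),
      neg = median(sm$log2_mean[cat_of == "negative"]))
  }
  m250 <- med(250); m10 <- med(10)
  expect_equal(unname(m250["hk"]), 13.46, tolerance = 0.3)
  expect_equal(unname(m250["neg"]), 5.78, tolerance = 0.15)
  gap250 <- m250["hk"] - m250["neg"]
  gap10 <- m10["hk"] - m10["neg"]
  expect_gt(gap250, gap10)
  expect_equal(unname(gap250), 7.68, tolerance = 0.5)
  expect_equal(unname(gap10), 5.74, tolerance = 0.5)
})

test_that("whole experiments are reproducible and share one truth", {
  cfg <- small_config(n_bead_types = 60, n_negative = 30, seed = 17)
  sim <- simulate_experiment(cfg)
  expect_equal(length(sim$sections), nrow(sim$design))
  expect_identical(names(sim$sections), sim$design$section_id)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim, sim2)
})
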