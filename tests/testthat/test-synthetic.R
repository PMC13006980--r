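test_that("cohort generation is byte-reproducible under a seed", {
  a <- generate_cohort(tiny_sim(), seed = 31)
  b <- generate_cohort(tiny_sim(), seed = 31)
  c <- generate_cohort(tiny_sim(), seed = 32)
  expect_equal(a$features, b$features)
  expect_equal(a$meta, b$meta)
  expect_equal(a$truth, b$truth)
  expect_false(identical(a$meta$time_days, c$meta$time_days))
})

test_that("censoring lands near the tuned target", {
  co <- generate_cohort(tiny_sim(n = 2000), seed = 17)
  # binomial noise at n = 2000: 3 * sqrt(.35*.65/2000) ~ 0.032
  expect_lt(abs(censoring_rate(co) - 0.35), 0.04)
  none <- generate_cohort(tiny_sim(n = 200, censoring_target = 0), seed = 17)
  expect_equal(censoring_rate(none), 0)
  expect_error(sim_config(censoring_target = 1), "\\[0, 1\\)")
})

test_that("true risks follow the planted linear model", {
  scfg <- tiny_sim(n = 100, beta = c(0.5, 1.0, 0.25))
  co <- generate_cohort(scfg, seed = 7)
  manual <- 0.5 * co$truth$f_img + 1.0 * co$truth$f_rna + 0.25 * co$truth$f_txt
  expect_equal(co$truth$risk_true, manual)
  expect_equal(co$truth$lambda, scfg$lambda0 * exp(manual))
})

test_that("a zero-signal cohort has a chance-level oracle ceiling", {
  co <- generate_cohort(tiny_sim(n = 300, beta = c(0, 0, 0)), seed = 5)
  ceil <- oracle_cindex_ceiling(co)
  expect_gte(ceil$overall, 0.45)
  expect_lte(ceil$overall, 0.55)
})

test_that("the dominant planted modality is the most prognostic factor", {
  co <- generate_cohort(tiny_sim(n = 400, beta = c(0, 1.5, 0)), seed = 13)
  ci <- function(v) c_index(v, co$meta$time_days, co$meta$event)
  expect_gt(ci(co$truth$f_rna), ci(co$truth$f_img))
  expect_gt(ci(co$truth$f_rna), 0.6)
})

test_that("oracle ceiling requires ground truth and bounds fitted models", {
  co <- generate_cohort(tiny_sim(n = 100), seed = 3)
  co$truth <- NULL
  expect_error(oracle_cindex_ceiling(co), "ground-truth")
})

test_that("site shifts move feature means between institutions", {
  scfg <- tiny_sim(n = 400, site_sd = 2)
  co <- generate_cohort(scfg, seed = 19)
  by_site <- tapply(co$features$img[, 1], co$meta$institution, mean)
  expect_gt(max(by_site) - min(by_site), 1)
  flat <- generate_cohort(tiny_sim(n = 400, site_sd = 0), seed = 19)
  by_site0 <- tapply(flat$features$img[, 1], flat$meta$institution, mean)
  expect_lt(max(by_site0) - min(by_site0), 1)
})

test_that("raw-level cohorts pool back to the patient feature vectors", {
  scfg <- sim_config(n = 6, n_cancers = 2, institutions_per_cancer = 2,
                     d_img = 12, d_rna = 6, d_txt = 8,
                     n_patch_range = c(4, 6), n_genes = 10,
                     l_txt_range = c(3, 5), raw_noise_sd = 0.1)
  co <- generate_cohort(scfg, seed = 23, level = "raw")
  expect_length(co$raw, 6)
  for (i in 1:6) {
    expect_lt(max(abs(mean_pool(co$raw[[i]]$img) - co$features$img[i, ])), 0.3)
    expect_equal(dim(co$raw[[i]]$rna), c(10, 6))
    expect_true(nrow(co$raw[[i]]$txt) %in% 3:5)
  }
})

test_that("cohort CSV round-trip preserves features, mask and truth", {
  co <- generate_cohort(tiny_sim(n = 20), seed = 29)
  co$mask[4, 2] <- 0L
  dir <- file.path(tempdir(), "cohort-rt")
  write_cohort(co, dir)
  rt <- read_cohort(dir, with_truth = TRUE)
  expect_equal(unname(rt$features$img), unname(co$features$img))
  expect_equal(unname(rt$mask[, 2]), unname(co$mask[, 2]))
  expect_equal(rt$meta$time_days, co$meta$time_days)
  expect_equal(rt$truth$risk_true, co$truth$risk_true)
})
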