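test_that("patient splits are disjoint, complete and stratified", {
  s <- tiny_setup(seed = 1, n = 100)
  sp <- make_split(s$cohort$meta, c(4, 2, 4), "patient", seed = 3)
  ids <- s$cohort$meta$patient_id
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  # stratification: each cancer type within one patient of the target
  for (cc in unique(s$cohort$meta$cancer_type)) {
    sub <- ids[s$cohort$meta$cancer_type == cc]
    n_c <- length(sub)
    expect_lte(abs(sum(sp$train %in% sub) - 0.4 * n_c), 1)
    expect_lte(abs(sum(sp$val %in% sub) - 0.2 * n_c), 1)
  }
  expect_error(make_split(s$cohort$meta, c(5, 2, 4)), "sum to 10")
})

test_that("institution splits never share a site across folds", {
  s <- tiny_setup(seed = 5, n = 120)
  meta <- s$cohort$meta
  sp <- make_split(meta, c(7, 1, 2), "institution", seed = 2)
  site_of <- function(ids) unique(meta$institution[match(ids, meta$patient_id)])
  expect_length(intersect(site_of(sp$train), site_of(sp$val)), 0)
  expect_length(intersect(site_of(sp$train), site_of(sp$test)), 0)
  expect_length(intersect(site_of(sp$val), site_of(sp$test)), 0)
})

test_that("split JSON round-trip preserves membership", {
  s <- tiny_setup(seed = 1, n = 40)
  sp <- make_split(s$cohort$meta, c(4, 2, 4), "patient", seed = 1)
  path <- tempfile(fileext = ".json")
  save_split(sp, path)
  sp2 <- load_split(path)
  expect_equal(sp2$train, sp$train)
  expect_equal(sp2$test, sp$test)
  expect_equal(split_idx(sp2, s$cohort, "val"), split_idx(sp, s$cohort, "val"))
})

test_that("missing-modality protocol masks exactly round(f*n) patients, copy-on-mask", {
  cohort <- generate_cohort(tiny_sim(n = 50), seed = 2)  # fully observed
  idx <- 1:40
  ch <- missing_modality_protocol(cohort, idx, "rna", 0.5, seed = 9)
  expect_equal(sum(ch$mask[idx, 2] == 0), 20)           # floor(0.5*40 + 0.5)
  expect_true(all(cohort$mask[, 2] == 1))               # original untouched
  expect_true(all(ch$mask[, 1] == 1))                   # anchor never masked
  expect_true(all(ch$features$rna[idx, ][ch$mask[idx, 2] == 0, ] == 0))
  expect_equal(missing_modality_protocol(cohort, idx, "rna", 0)$mask,
               cohort$mask)
  full <- missing_modality_protocol(cohort, idx, "txt", 1)
  expect_true(all(full$mask[idx, 3] == 0))
  expect_true(all(full$mask[41:50, 3] == 1))            # outside idx untouched
  expect_error(missing_modality_protocol(cohort, idx, "rna", 1.2), "\\[0, 1\\]")
})

test_that("sg_evaluate reports per-cancer concordance with sd semantics", {
  s <- tiny_setup(seed = 3, n = 60)
  fit <- sg_train(s$cohort, 1:36, 37:48, s$cfg,
                  train_config(epochs = 2, seed = 1))
  ev <- sg_evaluate(fit, s$cohort, 49:60)
  expect_equal(sort(ev$per_cancer$cancer_type), 1:2)
  expect_true(all(ev$per_cancer$cindex >= 0 & ev$per_cancer$cindex <= 1))
  expect_equal(ev$mean, mean(ev$per_cancer$cindex))
  expect_true(ev$sd_defined)
  one <- which(s$cohort$meta$cancer_type[49:60] == 1) + 48
  ev1 <- sg_evaluate(fit, s$cohort, one)
  expect_false(ev1$sd_defined)
  expect_equal(ev1$sd, 0)
})

test_that("sweep_missing starts at the clean-evaluation value", {
  s <- tiny_setup(seed = 4, n = 60)
  fit <- sg_train(s$cohort, 1:36, 37:48, s$cfg,
                  train_config(epochs = 2, seed = 1))
  sw <- sweep_missing(fit, s$cohort, 49:60, "rna", rates = c(0, 0.5, 1))
  expect_equal(sw$rate, c(0, 0.5, 1))
  expect_equal(sw$cindex[1], sg_evaluate(fit, s$cohort, 49:60)$mean)
})

test_that("paired t-tests flag planted differences and degenerate inputs", {
  set.seed(21)
  b <- matrix(rnorm(7 * 5, 0, 0.01), 7, 5)
  a <- b
  a[1, ] <- a[1, ] + 1                      # large planted shift, cancer 1
  tt <- paired_ttest_bonferroni(a, b)
  expect_true(tt$significant[1])
  expect_false(any(tt$significant[-1]))
  expect_equal(tt$threshold[1], 0.05 / 7)
  same <- paired_ttest_bonferroni(b, b)
  expect_true(all(!same$significant))
  expect_true(all(grepl("zero shift", same$flag)))
  shift <- paired_ttest_bonferroni(b + 1, b)
  expect_true(all(shift$significant))
  expect_true(all(grepl("constant shift", shift$flag)))
})

test_that("variance F-test is directional with the documented critical value", {
  a <- c(1, 3, 5, 7, 9)          # var 10
  b <- c(4, 4.5, 5, 5.5, 6)      # var 0.625
  r <- variance_f_test(a, b)
  expect_equal(r$F, var(a) / var(b))
  expect_equal(r$critical, qf(0.95, 4, 4))
  expect_equal(round(r$critical, 2), 6.39)
  expect_true(r$significant)
  expect_false(variance_f_test(b, a)$significant)    # directional
  z <- variance_f_test(a, rep(2, 5))
  expect_equal(z$F, Inf)
  expect_match(z$flag, "zero variance")
})

test_that("multi_seed_experiment aggregates per-seed matrices", {
  scfg <- tiny_sim(n = 60)
  ex <- multi_seed_experiment(scfg, tiny_model(),
                              train_config(epochs = 2, seed = 1),
                              seeds = c(11, 22))
  expect_equal(dim(ex$per_seed), c(2, 2))
  expect_true(all(is.finite(ex$per_seed)))
  expect_equal(ex$overall_mean, mean(colMeans(ex$per_seed)))
  expect_length(ex$fits, 2)
})
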