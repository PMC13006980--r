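test_that("model_config validates its arguments", {
  expect_error(model_config(penalty = -10), "penalty")
  expect_error(model_config(d = 30, n_heads = 4))
  expect_error(model_config(fusion = "late"))
  expect_s3_class(tiny_model(), "sg_config")
})

test_that("init_params has the documented shapes and a bias-free gate", {
  cfg <- tiny_model()
  p <- init_params(cfg, seed = 9)
  expect_equal(dim(p$proj$img$W), c(8, 12))
  expect_equal(dim(p$proj$rna$W), c(8, 6))
  expect_equal(dim(p$proj$txt$W), c(8, 8))
  expect_equal(dim(p$gate$W), c(3, 24))
  expect_named(p$gate, "W")               # the gate carries no bias
  expect_length(p$enc$layers, 2)
  expect_length(p$heads, 2)
  expect_equal(dim(p$heads[[1]]$W), c(4, 8))
  expect_equal(init_params(cfg, seed = 9), p)
  expect_false(identical(init_params(cfg, seed = 10), p))
})

test_that("zero_substitute zeroes masked modalities and protects the anchor", {
  z <- matrix(1, 2, 4)
  mask <- rbind(c(1, 0, 1), c(1, 1, 1))
  out <- zero_substitute(z, z, z, mask)
  expect_equal(out$rna[1, ], rep(0, 4))
  expect_equal(out$rna[2, ], rep(1, 4))
  expect_equal(out$img, z)
  expect_error(zero_substitute(z, z, z, rbind(c(0, 1, 1), c(1, 1, 1))),
               "anchor|image")
  expect_error(zero_substitute(z, z, z, rbind(c(1, 0.5, 1), c(1, 1, 1))),
               "binary")
})

test_that("masked gate weights are exactly zero off-mask and sum to one", {
  set.seed(13)
  L <- matrix(rnorm(6 * 3, sd = 3), 6, 3)
  mask <- cbind(1, rbinom(6, 1, 0.5), rbinom(6, 1, 0.5))
  G <- gate_weights(mask_logits(L, mask))
  expect_true(all(G[mask == 0] == 0))
  expect_equal(rowSums(G), rep(1, 6))
  zi <- matrix(rnorm(6 * 4), 6, 4)
  fused <- fuse_modalities(G, zi, zi, zi)
  expect_equal(fused, zi)                  # convex combination of identical z
  expect_error(fuse_modalities(G * 2, zi, zi, zi), "sum")
})

test_that("encoder with zero output weights is the identity (residual path)", {
  cfg <- tiny_model()
  p <- init_params(cfg, seed = 1)
  for (l in seq_along(p$enc$layers)) {
    p$enc$layers[[l]]$attn$Wo[] <- 0
    p$enc$layers[[l]]$attn$bo[] <- 0
    p$enc$layers[[l]]$ffn$W2[] <- 0
    p$enc$layers[[l]]$ffn$b2[] <- 0
  }
  z <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(shared_encode(z, p, cfg), z)
})

test_that("model_forward produces valid hazards, gates and risks", {
  s <- tiny_setup(seed = 4)
  batch <- make_batch(s$cohort, 1:10, s$disc)
  p <- init_params(s$cfg, seed = 2)
  fwd <- model_forward(p, batch, s$cfg)
  expect_equal(dim(fwd$hazards), c(10, 4))
  expect_true(all(fwd$hazards > 0 & fwd$hazards < 1))
  expect_equal(rowSums(fwd$gates), rep(1, 10))
  expect_equal(fwd$gates[2, 2], 0)         # rna masked for patient 2
  expect_equal(fwd$gates[3, 3], 0)         # txt masked for patient 3
  expect_true(all(diff(t(fwd$surv)) <= 0))
  # eval mode is deterministic
  expect_equal(model_forward(p, batch, s$cfg)$hazards, fwd$hazards)
})

test_that("early fusion forward works and reports no gates", {
  s <- tiny_setup(seed = 4)
  cfg <- tiny_model(fusion = "early")
  batch <- make_batch(s$cohort, 1:6, s$disc)
  p <- init_params(cfg, seed = 2)
  fwd <- model_forward(p, batch, cfg)
  expect_equal(dim(fwd$hazards), c(6, 4))
  expect_true(all(is.na(fwd$gates)))
})

test_that("hazard heads reject unknown cancer ids", {
  s <- tiny_setup()
  p <- init_params(s$cfg)
  b <- make_batch(s$cohort, 1:4, s$disc)
  b$cancer[1] <- 99L
  expect_error(model_forward(p, b, s$cfg), "cancer id")
})

test_that("checkpoint JSON round-trip restores parameters exactly", {
  s <- tiny_setup(seed = 6)
  p <- init_params(s$cfg, seed = 3)
  path <- tempfile(fileext = ".json")
  save_checkpoint(p, s$cfg, path, meta = list(seed = 3))
  ck <- load_checkpoint(path)
  expect_equal(ck$params, p)
  expect_equal(ck$config, s$cfg)
  expect_equal(ck$meta$seed, 3)
  b <- make_batch(s$cohort, 1:5, s$disc)
  expect_equal(model_forward(ck$params, b, ck$config)$hazards,
               model_forward(p, b, s$cfg)$hazards)
})

test_that("gradients check out for gated, early and modality-token variants", {
  s <- tiny_setup(seed = 8)
  batch <- make_batch(s$cohort, 1:6, s$disc)
  for (cfg in list(tiny_model(),
                   tiny_model(fusion = "early"))) {
    p <- init_params(cfg, seed = 5)
    expect_lt(check_gradients(p, batch, cfg, n_per_leaf = 3)$max_rel_err, 1e-4)
  }
  # 3-token variant: checked on an all-available batch. Zero-substituted
  # tokens sit at a non-smooth point of layer norm (variance ~ 0), where
  # finite differences are dominated by truncation error even though the
  # analytic gradient is correct.
  cfg3 <- tiny_model(encoder_tokens = "modality")
  full <- make_batch(s$cohort, 5:10, s$disc)
  p3 <- init_params(cfg3, seed = 5)
  expect_lt(check_gradients(p3, full, cfg3, n_per_leaf = 3)$max_rel_err, 1e-4)
})
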