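test_that("discretizer cuts are event-time quantiles; bins assigned correctly", {
  labels <- data.frame(time_days = 1:100, event = 1L, cancer_type = 1L)
  disc <- fit_discretizer(labels, n_bins = 4)
  expect_equal(disc$cuts[["1"]],
               unname(stats::quantile(1:100, c(0.25, 0.5, 0.75))))
  expect_equal(assign_bins(disc, c(0.5, 30, 60, 99, 5000), 1L),
               c(1L, 2L, 3L, 4L, 4L))
})

test_that("cancer types with < T events fall back to pooled cuts", {
  labels <- data.frame(
    time_days = c(1:40, 5, 17),
    event = c(rep(1L, 40), 1L, 1L),
    cancer_type = c(rep(1L, 40), 2L, 2L))
  disc <- fit_discretizer(labels, n_bins = 4)
  expect_equal(disc$cuts[["2"]], disc$cuts$.pooled)
  expect_false(identical(disc$cuts[["1"]], NULL))
})

test_that("discretizer rejects degenerate inputs", {
  expect_error(fit_discretizer(data.frame(time_days = 1:5, event = 0L,
                                          cancer_type = 1L)),
               "no uncensored events")
  expect_error(fit_discretizer(data.frame(time_days = rep(7, 20), event = 1L,
                                          cancer_type = 1L)),
               "degenerate")
  expect_error(fit_discretizer(data.frame(time_days = c(-1, 2:10), event = 1L,
                                          cancer_type = 1L)),
               "positive")
})

test_that("discretizer JSON round-trip is exact", {
  labels <- data.frame(time_days = rexp(80, 1 / 300) + 1, event = 1L,
                       cancer_type = rep(1:2, 40))
  disc <- fit_discretizer(labels, n_bins = 4)
  path <- tempfile(fileext = ".json")
  save_discretizer(disc, path)
  disc2 <- load_discretizer(path)
  expect_equal(disc2$cuts, disc$cuts)
  expect_equal(disc2$n_bins, disc$n_bins)
})

test_that("nll_loss matches a direct likelihood computation", {
  # event in bin 2 of (0.2, 0.5): -(log(0.8) + log(0.5));
  # censored in bin 1 of (0.4, 0.1): -log(0.6)
  h <- rbind(c(0.2, 0.5), c(0.4, 0.1))
  manual <- (-(log(0.8) + log(0.5)) - log(0.6)) / 2
  expect_equal(nll_loss(h, tau = c(2L, 1L), event = c(1L, 0L)), manual)
  expect_error(nll_loss(h, tau = c(3L, 1L), event = c(1L, 0L)), "out of range")
  expect_error(nll_loss(h * 10, tau = c(2L, 1L), event = c(1L, 0L)),
               "\\[0, 1\\]")
})

test_that("nll gradient w.r.t. logits matches finite differences", {
  set.seed(5)
  z <- matrix(rnorm(3 * 4), 3, 4)
  tau <- c(2L, 4L, 1L)
  event <- c(1L, 0L, 1L)
  loss_z <- function(z) nll_loss(1 / (1 + exp(-z)), tau, event)
  g <- nll_grad_logits(1 / (1 + exp(-z)), tau, event)
  h <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- z[i] + h
    zm <- z; zm[i] <- z[i] - h
    expect_equal(g[i], (loss_z(zp) - loss_z(zm)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("survival curves are cumulative products, monotone, S(0)=1 implied", {
  h <- c(0.1, 0.3, 0.2)
  expect_equal(survival_curve(h), cumprod(1 - h))
  expect_true(all(diff(survival_curve(h)) <= 0))
  m <- rbind(h, c(0.5, 0.5, 0.5))
  expect_equal(unname(survival_curve(m)[2, ]), c(0.5, 0.25, 0.125))
  expect_error(survival_curve(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("risk_score is monotone in each hazard and cumhaz sums hazards", {
  h <- c(0.2, 0.3, 0.1)
  h_up <- c(0.2, 0.6, 0.1)
  expect_gt(risk_score(h_up), risk_score(h))
  expect_equal(risk_score(h, method = "cumhaz"), sum(h))
  expect_equal(risk_score(rbind(h, h_up)), c(risk_score(h), risk_score(h_up)))
})

test_that("c_index handles perfect, reversed, tied and censored cases", {
  times <- c(10, 20, 30, 40)
  ev <- rep(1L, 4)
  expect_equal(c_index(-times, times, ev), 1)
  expect_equal(c_index(times, times, ev), 0)
  expect_equal(c_index(rep(3, 4), times, ev), 0.5)
  # censored patients never anchor a comparable pair
  expect_equal(c_index(c(9, 1, 5), c(1, 2, 3), c(0L, 1L, 1L)),
               c_index_naive(c(9, 1, 5), c(1, 2, 3), c(0L, 1L, 1L)))
  expect_error(c_index(c(1, 2), c(5, 6), c(0L, 0L)), "no comparable")
})
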