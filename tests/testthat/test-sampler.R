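test_that("initialization draws log10-uniform points inside the prior box", {
  prior <- prior_spec(c(kf = "second_order_forward", kc = "catalysis"))
  cfg <- ns_config(n_live = 200, seed = 4)
  st <- withr::with_seed(4, ns_initialize(function(p) 0.5, prior, cfg))
  expect_equal(dim(st$live_u), c(200, 2))
  expect_true(all(st$live_u >= 0 & st$live_u <= 1))
  st2 <- withr::with_seed(4, ns_initialize(function(p) 0.5, prior, cfg))
  expect_identical(st$live_u, st2$live_u)

  # parameters land inside their class ranges on the linear scale
  p <- evnest:::prior_transform(prior, st$live_u[1, ])
  expect_gte(p[["kf"]], 1e-8)
  expect_lte(p[["kf"]], 1e-4)
  expect_gte(p[["kc"]], 1e-1)
  expect_lte(p[["kc"]], 1e3)
})

test_that("marginal draws are uniform in log10 space", {
  prior <- prior_spec(c(k1 = "first_order_forward", k2 = "catalysis"))
  u <- withr::with_seed(11, evnest:::prior_sample_unit(prior, 10000))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(u[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
  # and on the log10 scale of the transformed parameters
  logk <- log10(vapply(seq_len(2000), function(i)
    evnest:::prior_transform(prior, u[i, ])[["k1"]], numeric(1)))
  ks <- suppressWarnings(stats::ks.test(logk, "punif", min = -4, max = 0))
  expect_gt(ks$p.value, 0.01)
})

test_that("initialization aborts when the objective mostly fails", {
  prior <- prior_spec(c(u1 = "unit"))
  flaky <- function(p) stop("boom")
  expect_error(ns_initialize(flaky, prior, ns_config(n_live = 20, seed = 1)),
               "initial draws")
})

test_that("proposals respect the threshold and stay in the prior", {
  prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
  obj <- function(p) log10(as.numeric(p))[1]
  cfg <- ns_config(n_live = 100, seed = 7)
  st <- withr::with_seed(7, ns_initialize(obj, prior, cfg))
  for (thr in c(0.2, 0.5, 0.8)) {
    prop <- propose_live_point(st, thr)
    expect_false(prop$exhausted)
    expect_gte(prop$value, thr)
    expect_true(all(prop$u >= 0 & prop$u <= 1))
  }
})

test_that("below-minimum thresholds yield prior-distributed proposals", {
  prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
  obj <- function(p) 0.5
  cfg <- ns_config(n_live = 50, seed = 3, proposal = "prior_rejection")
  st <- withr::with_seed(3, ns_initialize(obj, prior, cfg))
  draws <- withr::with_seed(9, vapply(1:800, function(i)
    propose_live_point(st, 0)$u[1], numeric(1)))
  ks <- suppressWarnings(stats::ks.test(draws, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate live set falls back to whole-prior sampling", {
  prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
  obj <- function(p) 0.5
  cfg <- ns_config(n_live = 10, seed = 5)
  st <- withr::with_seed(5, ns_initialize(obj, prior, cfg))
  st$live_u <- matrix(0.5, nrow = 10, ncol = 2,
                      dimnames = dimnames(st$live_u))
  prop <- withr::with_seed(6, propose_live_point(st, 0))
  expect_true(all(prop$u >= 0 & prop$u <= 1))
  expect_equal(prop$value, 0.5)
})

test_that("the estimator recovers analytic expected values", {
  # constant objective: Z = c essentially exactly
  fx <- build_fixture("constant")
  est <- ns_run(fx$objective, fx$prior, ns_config(n_live = 150, seed = 1))
  expect_equal(est$value, 0.7, tolerance = 1e-3 / 0.7)
  expect_lt(est$error, 1e-6)

  # mean of a uniform coordinate
  fx <- build_fixture("linear")
  est <- ns_run(fx$objective, fx$prior, ns_config(n_live = 200, seed = 2))
  expect_lt(abs(est$value - 0.5), 3 * est$error)

  # Gaussian bump against the deterministic quadrature oracle
  fx <- build_fixture("gaussian2d")
  truth <- stats::integrate(function(x) exp(-(x - 0.5)^2 / (2 * 0.1^2)),
                            0, 1, rel.tol = 1e-10)$value^2
  est <- ns_run(fx$objective, fx$prior, ns_config(n_live = 200, seed = 3))
  expect_lt(abs(est$value - truth), 3 * est$error)
})

test_that("identical seeds reproduce the estimate bit for bit", {
  fx <- build_fixture("gaussian2d")
  cfg <- ns_config(n_live = 80, seed = 17)
  e1 <- ns_run(fx$objective, fx$prior, cfg)
  e2 <- ns_run(fx$objective, fx$prior, cfg)
  expect_identical(e1$value, e2$value)
  expect_identical(e1$error, e2$error)
  expect_identical(e1$n_evaluations, e2$n_evaluations)
  e3 <- ns_run(fx$objective, fx$prior, ns_config(n_live = 80, seed = 18))
  expect_false(identical(e1$value, e3$value))
})

test_that("prior-mass bookkeeping follows X_i = exp(-i/N) exactly", {
  fx <- build_fixture("linear")
  cfg <- ns_config(n_live = 60, seed = 8)
  est <- ns_run(fx$objective, fx$prior, cfg)
  dp <- est$dead_points
  expect_equal(dp$log_prior_mass, -dp$iteration / 60)
  x <- exp(dp$log_prior_mass)
  w <- c(1, x[-length(x)]) - x
  expect_true(all(w > 0))
  expect_equal(sum(w), 1 - est$X_final, tolerance = 1e-12)
  # dead objectives rise monotonically (threshold is nondecreasing)
  expect_true(all(diff(dp$objective) >= 0))
})

test_that("the error estimate tracks information content and replicate spread", {
  # constant objective carries no information
  fx <- build_fixture("constant")
  est <- ns_run(fx$objective, fx$prior, ns_config(n_live = 100, seed = 1))
  expect_lt(est$error, 1e-6)

  # all-zero objective: error undefined, reported 0 with a warning
  prior <- prior_spec(c(u1 = "unit"))
  expect_warning(
    est0 <- ns_run(function(p) 0, prior, ns_config(n_live = 50, seed = 1)),
    "zero")
  expect_equal(est0$value, 0)
  expect_equal(est0$error, 0)

  # reported error within a factor of 3 of the empirical spread
  fx <- build_fixture("gaussian2d")
  runs <- lapply(1:12, function(s)
    ns_run(fx$objective, fx$prior,
           ns_config(n_live = 100, seed = s, keep_dead = FALSE)))
  zs <- vapply(runs, `[[`, numeric(1), "value")
  errs <- vapply(runs, `[[`, numeric(1), "error")
  ratio <- mean(errs) / stats::sd(zs)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)

  # quadrupling the population roughly halves the reported error
  errs4 <- vapply(1:10, function(s)
    ns_run(fx$objective, fx$prior,
           ns_config(n_live = 400, seed = s, keep_dead = FALSE))$error,
    numeric(1))
  shrink <- mean(errs4) / mean(errs)
  expect_gt(shrink, 0.25)
  expect_lt(shrink, 0.75)
})

test_that("evaluation counts scale roughly linearly with the population", {
  fx <- build_fixture("linear")
  ev <- vapply(c(100, 200, 400), function(n)
    ns_run(fx$objective, fx$prior,
           ns_config(n_live = n, seed = 12, keep_dead = FALSE))$n_evaluations,
    numeric(1))
  r1 <- ev[2] / ev[1]
  r2 <- ev[3] / ev[2]
  expect_gt(min(r1, r2), 1.6)
  expect_lt(max(r1, r2), 2.4)
  expect_true(all(ev >= c(100, 200, 400)))
})

test_that("tidy and glance summarise an estimate", {
  fx <- build_fixture("constant")
  est <- ns_run(fx$objective, fx$prior, ns_config(n_live = 50, seed = 2))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$Z, est$value)
  expect_identical(td, glance(est))
})
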