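test_that("scan grids expand to one record slot per variant and setting", {
  # the published resolution: 0..200,000 in steps of 250 -> 801 points
  spec <- scan_spec(names(subnetwork_variants()), "XIAP",
                    seq(0, 200000, by = 250))
  expect_equal(nrow(spec$grid), 6 * 801)
  expect_equal(sum(spec$grid$variant == "A"), 801)

  spec2 <- scan_spec("A", "XIAP", c(0, 1000))
  expect_equal(spec2$grid$grid_index, c(1, 2))
})

test_that("a singleton scan equals a single estimator run with the derived seed", {
  cfg <- ns_config(n_live = 40, termination_tol = 1e-3, seed = 123,
                   keep_dead = FALSE)
  sim <- sim_settings(t_end = 2000, n_points = 51)
  spec <- scan_spec("A", "XIAP", 0, config = cfg, sim = sim)
  res <- run_scan(spec)
  expect_equal(nrow(res), 1)
  expect_equal(res$status, "ok")

  seed <- evnest:::point_seed(123, "A", 1)
  expect_equal(res$seed, seed)
  net <- set_initial(build_subnetwork("A"), "XIAP", 0)
  cfg2 <- cfg
  cfg2$seed <- seed
  est <- suppressWarnings(
    ns_run(make_objective(net, "parp_cleavage", sim = sim),
           prior_from_network(net), cfg2))
  expect_identical(res$Z, est$value)
  expect_identical(res$error, est$error)
})

test_that("scans are reproducible, resumable, and tolerate per-point failures", {
  cfg <- ns_config(n_live = 30, termination_tol = 1e-3, seed = 5,
                   keep_dead = FALSE)
  sim <- sim_settings(t_end = 1000, n_points = 26)
  spec <- scan_spec("A", "XIAP", c(0, 50000), config = cfg, sim = sim)
  r1 <- run_scan(spec)
  r2 <- run_scan(spec)
  expect_identical(r1$Z, r2$Z)

  csv <- withr::local_tempfile(fileext = ".csv")
  r3 <- run_scan(spec, out_csv = csv)
  expect_identical(r3$Z, r1$Z)
  # resuming reuses persisted rows instead of recomputing
  t0 <- Sys.time()
  r4 <- run_scan(spec, out_csv = csv)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(r4$Z, r1$Z)

  # a bad regulator is recorded, not fatal
  bad <- scan_spec("A", "NotASpecies", 0, config = cfg, sim = sim)
  rbad <- run_scan(bad)
  expect_true(is.na(rbad$Z))
  expect_match(rbad$status, "not present")
})

test_that("expected conversion decreases with inhibitor abundance", {
  # Monte-Carlo prior-integration oracle on the toy inhibitor network,
  # compared with the nested-sampling estimates at three regulator levels
  levels <- c(0, 1e4, 1e6)
  mc_mean <- function(i0, n = 1200) {
    net <- toy_inhibitor_network(i0 = i0)
    prior <- prior_from_network(net)
    obj <- make_objective(net, "parp_cleavage",
                          sim = sim_settings(t_end = 100, n_points = 51),
                          cleaved = "P", moiety = c("S", "E_S", "P"))
    u <- withr::with_seed(31, evnest:::prior_sample_unit(prior, n))
    mean(vapply(seq_len(n), function(i)
      obj(evnest:::prior_transform(prior, u[i, ])), numeric(1)))
  }
  ns_est <- function(i0) {
    net <- toy_inhibitor_network(i0 = i0)
    obj <- make_objective(net, "parp_cleavage",
                          sim = sim_settings(t_end = 100, n_points = 51),
                          cleaved = "P", moiety = c("S", "E_S", "P"))
    ns_run(obj, prior_from_network(net),
           ns_config(n_live = 100, seed = 13, keep_dead = FALSE))
  }
  mc <- vapply(levels, mc_mean, numeric(1))
  expect_true(all(diff(mc) < 0))
  ests <- lapply(levels, ns_est)
  zs <- vapply(ests, `[[`, numeric(1), "value")
  errs <- vapply(ests, `[[`, numeric(1), "error")
  expect_true(all(diff(zs) < 0))
  se <- 0.5 / sqrt(1200)   # conservative MC standard error bound
  expect_true(all(abs(zs - mc) <= 3 * (errs + se)))
})

test_that("expected-value ratios are antisymmetric and zero at equality", {
  expect_equal(evr(0.5, 0.5), 0)
  expect_equal(evr(1.0, 0.5), 1)
  expect_equal(evr(0.5, 1.0), -1)
  withr::with_seed(99, {
    z1 <- stats::runif(10000, 1e-6, 1)
    z2 <- stats::runif(10000, 1e-6, 1)
  })
  expect_equal(evr(z1, z2), -evr(z2, z1), tolerance = 1e-12)
  expect_equal(evr(z1, z1), rep(0, 10000))
  expect_error(evr(0, 0.5), "exceed")
  expect_error(evr(0.5, 1e-15), "exceed")
})

test_that("evr_table pairs variants on the shared grid", {
  scan <- tibble::tibble(
    variant = rep(c("A", "E"), each = 3),
    regulator_name = "XIAP",
    regulator_value = rep(c(0, 1, 2), 2),
    objective = "parp_cleavage",
    Z = c(0.9, 0.5, 0.25, 0.9, 0.75, 0.5),
    error = 0.01, n_evaluations = 10L, seed = 1L, status = "ok")
  tab <- evr_table(scan, "E", "A")
  expect_equal(tab$evr, c(0, 0.5, 1))
  expect_equal(evr_table(scan, "A", "E")$evr, c(0, -0.5, -1))
})

test_that("crossings are located by interpolation on the ordered series", {
  exact <- tibble::tibble(regulator_value = c(10000, 30000, 60000),
                          Z = c(0.9, 0.5, 0.2))
  expect_equal(find_crossing(exact), 30000)

  interp <- tibble::tibble(regulator_value = c(30000, 32000),
                           Z = c(0.6, 0.4))
  expect_equal(find_crossing(interp), 31000)

  none <- tibble::tibble(regulator_value = c(0, 1), Z = c(0.9, 0.8))
  expect_true(is.na(find_crossing(none)))

  noisy <- tibble::tibble(regulator_value = 1:5,
                          Z = c(0.9, 0.4, 0.6, 0.3, 0.2))
  expect_message(xc <- find_crossing(noisy), "2 times")
  expect_equal(xc, 1 + 0.5 / 0.5 * 0.8, tolerance = 1e-12)
})

test_that("peaks are found after smoothing, robustly under noise", {
  tri <- tibble::tibble(regulator_value = seq(0, 100, by = 10),
                        evr = c(0:5, 4:0) / 5)
  expect_equal(find_peak(tri, window = 1), 50)
  expect_equal(find_peak(tri, window = 5), 50)

  flat <- tibble::tibble(regulator_value = 1:5, evr = rep(1, 5))
  expect_warning(p <- find_peak(flat), "constant")
  expect_true(is.na(p))

  # noisy unimodal series: peak recovered within 2 grid steps >= 90% of runs
  x <- seq(0, 200, by = 5)
  truth <- 100
  hit <- withr::with_seed(2024, {
    vapply(1:100, function(i) {
      y <- exp(-(x - truth)^2 / (2 * 40^2)) + stats::rnorm(length(x), 0, 0.01)
      p <- find_peak(tibble::tibble(regulator_value = x, evr = y))
      abs(p - truth) <= 2 * 5
    }, logical(1))
  })
  expect_gte(mean(hit), 0.9)

  # window 1 reproduces the raw argmax
  y <- c(0.1, 0.9, 0.3, 0.8, 0.2)
  d <- tibble::tibble(regulator_value = 1:5, evr = y)
  expect_equal(find_peak(d, window = 1), which.max(y))
})

test_that("precision tables aggregate replicated runs", {
  fx <- build_fixture("linear")
  ps <- precision_study(fx$objective, fx$prior, c(50, 100),
                        replicates = 3, config = ns_config(n_live = 50,
                                                           seed = 6))
  expect_s3_class(ps, "evnest_precision")
  expect_equal(ps$n_live, c(50, 100))
  expect_true(all(ps$mean_evaluations >= ps$n_live))
  expect_true(all(ps$mean_error > 0))
})

test_that("autoplot produces ggplot objects for scans and precision tables", {
  scan <- structure(
    tibble::tibble(variant = "A", regulator_name = "XIAP",
                   regulator_value = c(0, 1), objective = "parp_cleavage",
                   Z = c(0.9, 0.8), error = 0.01, n_evaluations = 10L,
                   seed = 1L, status = "ok"),
    class = c("evnest_scan", class(tibble::tibble())))
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
  prec <- structure(
    tibble::tibble(n_live = c(50, 100), mean_evaluations = c(500, 1000),
                   mean_error = c(0.02, 0.015), mean_Z = 0.5, sd_Z = 0.01,
                   replicates = 3),
    class = c("evnest_precision", class(tibble::tibble())))
  expect_s3_class(ggplot2::autoplot(prec), "ggplot")
})
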