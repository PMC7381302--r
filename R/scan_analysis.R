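# Regulator scans across network variants, expected-value ratios,
# crossing/peak detection, and the precision-versus-cost study. All results
# are tidy tibbles so they compose with dplyr/ggplot2.

#' Specify a regulator scan
#'
#' One nested-sampling estimate is produced per (variant x grid point).
#'
#' @param variants Character vector of subnetwork codes (`"A"`..`"F"`) or
#'   catalogue names (see [subnetwork_variants()]).
#' @param regulator Species whose initial copy number is scanned (e.g.
#'   `"XIAP"`).
#' @param values Ordered numeric grid of regulator settings (molecules per
#'   cell).
#' @param objective Objective selector, as in [make_objective()].
#' @param config An [ns_config()]; its seed is the scan's base seed.
#' @param overrides Named numeric vector of fixed initial-copy overrides
#'   applied to every run (e.g. `c(Bcl2 = 0)`).
#' @param sim A [sim_settings()].
#' @return A `scan_spec` list with the expanded grid tibble under `$grid`.
#' @export
scan_spec <- function(variants, regulator, values,
                      objective = "parp_cleavage",
                      config = ns_config(), overrides = NULL,
                      sim = sim_settings()) {
  stopifnot(length(values) >= 1, is.character(regulator))
  grid <- tibble::tibble(
    variant = rep(variants, each = length(values)),
    regulator_name = regulator,
    regulator_value = rep(as.numeric(values), times = length(variants)))
  grid$grid_index <- stats::ave(seq_len(nrow(grid)), grid$variant,
                                FUN = seq_along)
  structure(list(variants = variants, regulator = regulator,
                 values = as.numeric(values), objective = objective,
                 config = config, overrides = overrides, sim = sim,
                 grid = grid),
            class = "scan_spec")
}

# deterministic per-point seed: independent streams per (variant, grid index)
point_seed <- function(base_seed, variant, grid_index) {
  v <- utf8ToInt(substr(as.character(variant), 1, 1))
  as.integer((as.numeric(base_seed) * 7919 + v * 104729 +
                as.numeric(grid_index) * 131) %% 2147483587 + 1)
}

scan_one <- function(spec, variant, value, grid_index) {
  seed <- point_seed(spec$config$seed, variant, grid_index)
  est <- NULL
  status <- "ok"
  res <- tryCatch({
    net <- build_subnetwork(variant)
    # fixed overrides naming species a variant knocked out are dropped;
    # the scanned regulator itself must exist (error recorded otherwise)
    ov <- spec$overrides[names(spec$overrides) %in% species_names(net)]
    for (nm in names(ov)) net <- set_initial(net, nm, ov[[nm]])
    net <- set_initial(net, spec$regulator, value)
    obj <- make_objective(net, kind = spec$objective, sim = spec$sim)
    cfg <- spec$config
    cfg$seed <- seed
    suppressWarnings(ns_run(obj, prior_from_network(net), cfg))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    status <- conditionMessage(res)
    tibble::tibble(variant = variant, regulator_name = spec$regulator,
                   regulator_value = value, objective = spec$objective,
                   Z = NA_real_, error = NA_real_,
                   n_evaluations = NA_integer_, seed = seed,
                   status = status)
  } else {
    tibble::tibble(variant = variant, regulator_name = spec$regulator,
                   regulator_value = value, objective = spec$objective,
                   Z = res$value, error = res$error,
                   n_evaluations = res$n_evaluations, seed = seed,
                   status = "ok")
  }
}

#' Run a regulator scan
#'
#' Performs one independent nested-sampling run per grid point, with a
#' deterministic per-point seed derived from the base seed, the variant and
#' the grid index. When `out_csv` is given, rows are appended as they
#' complete and an interrupted scan resumes from the rows already on disk.
#' Per-point failures are recorded in `status` and the scan continues.
#'
#' @param spec A [scan_spec()].
#' @param out_csv Optional path for incremental CSV output.
#' @return A tibble of class `evnest_scan` with columns `variant`,
#'   `regulator_name`, `regulator_value`, `objective`, `Z`, `error`,
#'   `n_evaluations`, `seed`, `status`.
#' @export
run_scan <- function(spec, out_csv = NULL) {
  stopifnot(inherits(spec, "scan_spec"))
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- tibble::as_tibble(utils::read.csv(out_csv,
                                              stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    g <- spec$grid[i, ]
    if (!is.null(done) &&
        any(done$variant == g$variant &
              done$regulator_value == g$regulator_value)) {
      rows[[i]] <- done[done$variant == g$variant &
                          done$regulator_value == g$regulator_value, ][1, ]
      next
    }
    rows[[i]] <- scan_one(spec, g$variant, g$regulator_value, g$grid_index)
    if (!is.null(out_csv)) {
      utils::write.table(rows[[i]], out_csv, sep = ",",
                         row.names = FALSE, col.names = !file.exists(out_csv),
                         append = file.exists(out_csv))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evnest_scan", class(out))
  out
}

#' Expected-value ratio (EVR)
#'
#' Signed, continuous and antisymmetric transform of the ratio of two
#' expected values, the model-comparison analogue of a Bayes factor:
#' `-Z2/Z1 + 1` when `Z1 < Z2`, `Z1/Z2 - 1` when `Z1 > Z2`, 0 at equality.
#' Positive values favour the numerator network (`z1`).
#'
#' @param z1,z2 Expected values (bare numbers or `ev_estimate` objects);
#'   both must exceed `eps`.
#' @param eps Guard below which the ratio is undefined.
#' @return Signed dimensionless scalar (vectorised over `z1`, `z2`).
#' @export
evr <- function(z1, z2, eps = 1e-12) {
  if (inherits(z1, "ev_estimate")) z1 <- z1$value
  if (inherits(z2, "ev_estimate")) z2 <- z2$value
  if (any(!is.finite(z1)) || any(!is.finite(z2)) ||
      any(z1 <= eps) || any(z2 <= eps)) {
    stop("expected values must exceed ", eps,
         " for a defined expected-value ratio", call. = FALSE)
  }
  ifelse(z1 < z2, -z2 / z1 + 1, ifelse(z1 > z2, z1 / z2 - 1, 0))
}

#' EVR series between two scanned variants
#'
#' @param scan An `evnest_scan` tibble from [run_scan()].
#' @param numerator,denominator Variant codes compared as
#'   `evr(Z_numerator, Z_denominator)` at every shared regulator value.
#' @inheritParams evr
#' @return Tibble with `regulator_value`, `numerator_variant`,
#'   `denominator_variant`, `evr`.
#' @export
evr_table <- function(scan, numerator, denominator, eps = 1e-12) {
  a <- scan[scan$variant == numerator & scan$status == "ok", ]
  b <- scan[scan$variant == denominator & scan$status == "ok", ]
  j <- dplyr::inner_join(
    dplyr::select(a, "regulator_value", Z1 = "Z"),
    dplyr::select(b, "regulator_value", Z2 = "Z"),
    by = "regulator_value")
  tibble::tibble(regulator_value = j$regulator_value,
                 numerator_variant = numerator,
                 denominator_variant = denominator,
                 evr = evr(j$Z1, j$Z2, eps = eps))
}

#' Locate the first downward level crossing of a scanned trend
#'
#' Scans the series in regulator order and returns the regulator value at
#' which the trend first crosses `level` from above, located by linear
#' interpolation between the bracketing grid points. An exact hit returns
#' the grid point itself. If the noisy series crosses several times, the
#' first crossing is returned and the total count is reported via a
#' message.
#'
#' @param data Data frame ordered by regulator value (e.g. one variant of
#'   an `evnest_scan`).
#' @param level Crossing level (default 0.5).
#' @param value_col,regulator_col Column names.
#' @return The interpolated regulator value, or `NA` if the series never
#'   crosses.
#' @export
find_crossing <- function(data, level = 0.5, value_col = "Z",
                          regulator_col = "regulator_value") {
  x <- data[[regulator_col]]
  y <- data[[value_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  o <- order(x)
  x <- x[o]
  y <- y[o]
  hits <- which(y == level)
  down <- which(y[-length(y)] > level & y[-1] < level)
  n_cross <- length(down) + length(hits)
  if (n_cross > 1) {
    message("series crosses level ", level, " ", n_cross,
            " times; returning the first")
  }
  first_hit <- if (length(hits)) x[hits[1]] else Inf
  first_int <- if (length(down)) {
    i <- down[1]
    x[i] + (y[i] - level) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
  } else Inf
  out <- min(first_hit, first_int)
  if (is.infinite(out)) NA_real_ else out
}

#' Locate the peak of an EVR (or any) series
#'
#' Applies a centered moving average and returns the regulator value of the
#' smoothed maximum; ties resolve to the smallest regulator value. An
#' all-equal series has no peak and returns `NA` with a warning.
#'
#' @param data Data frame with a regulator column and a value column.
#' @param window Odd smoothing window in grid points (default 5; 1 means
#'   raw argmax).
#' @param value_col,regulator_col Column names.
#' @return Regulator value at the smoothed maximum, or `NA`.
#' @export
find_peak <- function(data, window = 5, value_col = "evr",
                      regulator_col = "regulator_value") {
  x <- data[[regulator_col]]
  y <- data[[value_col]]
  o <- order(x)
  x <- x[o]
  y <- y[o]
  if (length(y) < 3) stop("need at least 3 points", call. = FALSE)
  if (all(y == y[1])) {
    warning("series is constant; no peak", call. = FALSE)
    return(NA_real_)
  }
  w <- max(1L, as.integer(window))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  sm <- vapply(seq_along(y), function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(y), i + half)
    mean(y[lo:hi])
  }, numeric(1))
  x[which.max(sm)]
}

#' Precision versus computational cost
#'
#' Replicated nested-sampling runs across live-point population sizes,
#' aggregating evaluation counts and reported errors. Evaluations roughly
#' double per doubling of the population, while errors shrink roughly as
#' `n_live^(-1/2)`.
#'
#' @param objective Objective function, as in [ns_run()].
#' @param prior A [prior_spec()].
#' @param populations Numeric vector of live-point counts (>= 2 values).
#' @param replicates Seeded replicates per population size (>= 3).
#' @param config Base [ns_config()] supplying the seed and termination
#'   settings.
#' @return Tibble of class `evnest_precision` with one row per population:
#'   `n_live`, `mean_evaluations`, `mean_error`, `sd_Z`, `mean_Z`,
#'   `replicates`.
#' @export
precision_study <- function(objective, prior, populations,
                            replicates = 3, config = ns_config()) {
  stopifnot(length(populations) >= 2, replicates >= 3)
  rows <- lapply(as.integer(populations), function(n) {
    runs <- lapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$n_live <- n
      cfg$seed <- point_seed(config$seed, "P", n * 1000 + r)
      cfg$keep_dead <- FALSE
      suppressWarnings(ns_run(objective, prior, cfg))
    })
    tibble::tibble(
      n_live = n,
      mean_evaluations = mean(vapply(runs, `[[`, numeric(1),
                                     "n_evaluations")),
      mean_error = mean(vapply(runs, `[[`, numeric(1), "error")),
      mean_Z = mean(vapply(runs, `[[`, numeric(1), "value")),
      sd_Z = stats::sd(vapply(runs, `[[`, numeric(1), "value")),
      replicates = replicates)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evnest_precision", class(out))
  out
}

#' Plot a scan result
#' @param object An `evnest_scan` tibble.
#' @param ... Unused.
#' @method autoplot evnest_scan
#' @export
autoplot.evnest_scan <- function(object, ...) {
  ggplot2::ggplot(object[object$status == "ok", ],
                  ggplot2::aes(x = .data$regulator_value, y = .data$Z,
                               colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Z - .data$error,
                                        ymax = .data$Z + .data$error),
                           width = 0) +
    ggplot2::labs(x = object$regulator_name[1],
                  y = "expected value",
                  colour = "variant") +
    ggplot2::theme_minimal()
}

#' Plot a precision-study result
#' @param object An `evnest_precision` tibble.
#' @param ... Unused.
#' @method autoplot evnest_precision
#' @export
autoplot.evnest_precision <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_live)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_evaluations)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_evaluations)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "live points", y = "mean objective evaluations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
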