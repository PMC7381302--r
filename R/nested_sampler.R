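# Nested-sampling estimation of prior-averaged expected values.
#
# The estimator follows the classic scheme: N live points drawn from the
# prior, iterative replacement of the worst-scoring point under a rising
# objective threshold, prior-mass shrinkage X_i = exp(-i/N), rectangle-rule
# weights, and a final live-set correction. Proposals are drawn uniformly
# from a single enlarged bounding ellipsoid of the live points intersected
# with the prior box, falling back to whole-prior rejection when the
# ellipsoid is degenerate.

#' Sampler configuration
#'
#' @param n_live Number of live points (production default 16,000; tests
#'   and desk-scale runs use 100-500).
#' @param termination_tol Stop once the presumed remaining contribution
#'   `L_high * X_i` falls below this threshold (default 1e-4).
#' @param seed Integer seed; identical (seed, config, objective) runs are
#'   bit-for-bit reproducible.
#' @param max_evaluations Cap on objective evaluations.
#' @param proposal `"single_ellipsoid"` (default) or `"prior_rejection"`.
#' @param enlargement Factor applied to the squared Mahalanobis radius of
#'   the bounding ellipsoid.
#' @param keep_dead Keep the per-iteration dead-point table on the result.
#' @return An `ns_config` list.
#' @export
ns_config <- function(n_live = 16000, termination_tol = 1e-4, seed = 1L,
                      max_evaluations = 1e6,
                      proposal = c("single_ellipsoid", "prior_rejection"),
                      enlargement = 1.25, keep_dead = TRUE) {
  stopifnot(n_live >= 2, termination_tol > 0, max_evaluations >= n_live)
  list(n_live = as.integer(n_live), termination_tol = termination_tol,
       seed = as.integer(seed), max_evaluations = max_evaluations,
       proposal = match.arg(proposal), enlargement = enlargement,
       keep_dead = isTRUE(keep_dead))
}

score_point <- function(objective, prior, u, state_env) {
  value <- tryCatch(objective(prior_transform(prior, u)),
                    error = function(e) NA_real_)
  state_env$n_eval <- state_env$n_eval + 1L
  if (!is.finite(value)) {
    state_env$n_fail <- state_env$n_fail + 1L
    value <- 0
  }
  value
}

#' Initialize a nested-sampling run
#'
#' Draws `n_live` points independently log10-uniformly within the prior
#' ranges, scores each with the objective, and assembles the initial
#' sampler state. Aborts with a diagnostic if the objective fails (errors
#' or returns non-finite) on more than half of the initial draws.
#'
#' @param objective Function mapping a named rate-constant vector to a
#'   value in `[0, 1]` (see [make_objective()] and [build_fixture()]).
#' @param prior A [prior_spec()].
#' @param config An [ns_config()].
#' @return A `sampler_state` environment holding the live set, prior-mass
#'   bookkeeping and evaluation counters.
#' @export
ns_initialize <- function(objective, prior, config = ns_config()) {
  state <- new.env(parent = emptyenv())
  state$prior <- prior
  state$config <- config
  state$objective <- objective
  state$n_eval <- 0L
  state$n_fail <- 0L
  state$live_u <- prior_sample_unit(prior, config$n_live)
  state$live_f <- vapply(seq_len(config$n_live), function(i)
    score_point(objective, prior, state$live_u[i, ], state), numeric(1))
  if (state$n_fail > config$n_live / 2) {
    stop("objective failed on ", state$n_fail, " of ", config$n_live,
         " initial draws; check the model/simulation settings",
         call. = FALSE)
  }
  state$iteration <- 0L
  state$X <- 1
  state$Z <- 0
  state$dead_f <- numeric(0)
  state$dead_logx <- numeric(0)
  class(state) <- c("sampler_state", class(state))
  state
}

# bounding-ellipsoid factorisation of the live set; NULL when degenerate
live_ellipsoid <- function(live_u, enlargement) {
  center <- colMeans(live_u)
  C <- stats::cov(live_u)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Zc <- sweep(live_u, 2, center)
  d2 <- colSums(backsolve(R, t(Zc), transpose = TRUE)^2)
  f <- max(d2) * enlargement
  if (!is.finite(f) || f <= 0) return(NULL)
  list(center = center, R = R, scale = sqrt(f))
}

sample_in_ellipsoid <- function(ell, d) {
  z <- stats::rnorm(d)
  r <- stats::runif(1)^(1 / d)
  as.numeric(ell$center + ell$scale * r * crossprod(ell$R, z / sqrt(sum(z^2))))
}

# first candidate inside the unit cube from a batch of uniform-in-ellipsoid
# draws, or NULL. Batched for speed: in high dimension most of a bounding
# ellipsoid lies outside the prior box until the live set has contracted.
sample_in_ellipsoid_box <- function(ell, d, batches = 4L, batch_size = 64L) {
  for (b in seq_len(batches)) {
    Zm <- matrix(stats::rnorm(batch_size * d), nrow = d)
    norms <- sqrt(colSums(Zm^2))
    radii <- stats::runif(batch_size)^(1 / d)
    U <- ell$center + ell$scale *
      crossprod(ell$R, sweep(Zm, 2, norms / radii, "/"))
    ok <- which(colSums(U >= 0 & U <= 1) == d)
    if (length(ok)) return(U[, ok[1]])
  }
  NULL
}

#' Propose a replacement live point
#'
#' Samples uniformly from the prior restricted to the current bound (the
#' enlarged bounding ellipsoid of the live points intersected with the
#' prior box) until a point with objective value at or above `threshold`
#' is found. Falls back to whole-prior rejection sampling when the
#' ellipsoid is degenerate or when configured with
#' `proposal = "prior_rejection"`.
#'
#' @param state A `sampler_state` from [ns_initialize()].
#' @param threshold Objective value the proposal must meet or exceed.
#' @return List with `u` (unit coordinates), `value`, and `exhausted`
#'   (TRUE when `max_evaluations` was hit before acceptance).
#' @export
propose_live_point <- function(state, threshold) {
  config <- state$config
  d <- prior_dim(state$prior)
  ell <- if (config$proposal == "single_ellipsoid") {
    live_ellipsoid(state$live_u, config$enlargement)
  } else NULL
  repeat {
    if (state$n_eval >= config$max_evaluations) {
      return(list(u = NULL, value = NA_real_, exhausted = TRUE))
    }
    if (!is.null(ell)) {
      u <- sample_in_ellipsoid_box(ell, d)
      # ellipsoid barely intersects the box (early phase, when it still
      # encloses most of the prior): a whole-prior draw is equivalent there
      if (is.null(u)) u <- as.numeric(prior_sample_unit(state$prior, 1))
    } else {
      u <- as.numeric(prior_sample_unit(state$prior, 1))
    }
    value <- score_point(state$objective, state$prior, u, state)
    if (value >= threshold) {
      return(list(u = u, value = value, exhausted = FALSE))
    }
  }
}

#' Estimate the expected value of an objective over the prior
#'
#' Runs nested sampling: iterative worst-point replacement accumulating
#' `sum L_low,i (X_{i-1} - X_i)` with `X_i = exp(-i / n_live)`, terminating
#' when `L_high * X_i < termination_tol` (or at `max_evaluations`), then
#' adding the final live-set correction `mean(live objective) * X_final`.
#' Ties at the removal threshold are broken by a uniform random choice.
#'
#' @inheritParams ns_initialize
#' @return An `ev_estimate`: `value` (the expected value Z), `error`
#'   (standard-deviation-scale uncertainty, see [estimate_error()]),
#'   `n_evaluations`, `n_iterations`, `n_failures`, `terminated_by`
#'   (`"threshold"` or `"max_evaluations"`), and (when configured) a tidy
#'   `dead_points` tibble with columns `iteration`, `objective`,
#'   `log_prior_mass`.
#' @export
ns_run <- function(objective, prior, config = ns_config()) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)
  state <- ns_initialize(objective, prior, config)
  N <- config$n_live
  terminated_by <- "threshold"
  cap <- as.integer(min(config$max_evaluations, 1e7))
  dead_f <- numeric(cap)
  dead_logx <- numeric(cap)
  n_dead <- 0L
  repeat {
    i <- state$iteration + 1L
    X_i <- exp(-i / N)
    w <- state$X - X_i
    l_low <- min(state$live_f)
    l_high <- max(state$live_f)
    if (l_high * X_i < config$termination_tol) {
      # presumed remaining contribution negligible: stop before replacing
      break
    }
    prop <- propose_live_point(state, l_low)
    if (prop$exhausted) {
      terminated_by <- "max_evaluations"
      break
    }
    ties <- which(state$live_f == l_low)
    drop <- if (length(ties) == 1L) ties else
      ties[sample.int(length(ties), 1L)]
    state$Z <- state$Z + l_low * w
    n_dead <- n_dead + 1L
    dead_f[n_dead] <- l_low
    dead_logx[n_dead] <- -i / N
    state$live_u[drop, ] <- prop$u
    state$live_f[drop] <- prop$value
    state$iteration <- i
    state$X <- X_i
  }
  # final live-set correction: remaining prior mass at the mean live value
  state$Z <- state$Z + mean(state$live_f) * state$X
  state$dead_f <- dead_f[seq_len(n_dead)]
  state$dead_logx <- dead_logx[seq_len(n_dead)]
  err <- estimate_error(state)
  dead <- if (config$keep_dead) {
    tibble::tibble(iteration = seq_len(n_dead),
                   objective = state$dead_f,
                   log_prior_mass = state$dead_logx)
  } else NULL
  structure(list(value = state$Z, error = err,
                 n_evaluations = state$n_eval,
                 n_iterations = state$iteration,
                 n_failures = state$n_fail,
                 terminated_by = terminated_by,
                 n_live = N, seed = config$seed,
                 live_objectives = state$live_f,
                 X_final = state$X,
                 dead_points = dead),
            class = "ev_estimate")
}

#' Uncertainty of a nested-sampling estimate
#'
#' Computes the information `H` of the run (the Kullback-Leibler divergence
#' of the objective-weighted prior from the prior) and returns the
#' `sqrt(H / n_live)`-scale uncertainty on `ln Z` propagated to `Z`, i.e.
#' `Z * sqrt(H / n_live)`. For an all-zero objective (`Z = 0`) the error is
#' reported as 0 with a warning, since the information is undefined.
#'
#' @param state A completed `sampler_state` or an `ev_estimate`.
#' @return Nonnegative scalar uncertainty on the same scale as `Z`.
#' @export
estimate_error <- function(state) {
  if (inherits(state, "ev_estimate")) {
    Z <- state$value
    N <- state$n_live
    dead_f <- state$dead_points$objective
    dead_logx <- state$dead_points$log_prior_mass
    live_f <- state$live_objectives
    X_final <- state$X_final
  } else {
    Z <- state$Z
    N <- state$config$n_live
    dead_f <- state$dead_f
    dead_logx <- state$dead_logx
    live_f <- state$live_f
    X_final <- state$X
  }
  if (!is.finite(Z) || Z <= 0) {
    warning("expected value is zero; error estimate undefined, reported 0",
            call. = FALSE)
    return(0)
  }
  x_prev <- c(1, exp(dead_logx[-length(dead_logx)]))
  w <- if (length(dead_logx)) x_prev - exp(dead_logx) else numeric(0)
  p <- c(w * dead_f, rep(X_final / length(live_f), length(live_f)) * live_f) / Z
  l <- c(dead_f, live_f)
  pos <- p > 0 & l > 0
  H <- sum(p[pos] * log(l[pos] / Z))
  H <- max(H, 0)
  Z * sqrt(H / N)
}

#' @export
print.ev_estimate <- function(x, ...) {
  cat(sprintf("<ev_estimate> Z = %.6g +/- %.2g (%d evaluations, %d live, %s)\n",
              x$value, x$error, x$n_evaluations, x$n_live, x$terminated_by))
  invisible(x)
}

#' @rdname ns_run
#' @param x An `ev_estimate`.
#' @param ... Unused.
#' @method tidy ev_estimate
#' @export
tidy.ev_estimate <- function(x, ...) {
  tibble::tibble(Z = x$value, error = x$error,
                 n_evaluations = x$n_evaluations,
                 n_iterations = x$n_iterations,
                 n_failures = x$n_failures,
                 n_live = x$n_live, seed = x$seed,
                 terminated_by = x$terminated_by)
}

#' @rdname ns_run
#' @method glance ev_estimate
#' @export
glance.ev_estimate <- function(x, ...) tidy(x, ...)
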