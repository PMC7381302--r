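# Independent oracles used across the suite. These deliberately do not
# reuse the package's solver or stoichiometry code paths.

# fixed-step classic Runge-Kutta mass-action integrator (brute force)
rk4_final_state <- function(network, params, t_end, dt = 1e-3) {
  y <- initial_copies(network)
  rhs <- function(y) {
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (r in network$reactions) {
      rate <- as.numeric(params[[r$parameter_id]])
      for (re in r$reactants) rate <- rate * y[[re]]
      for (re in r$reactants) dy[[re]] <- dy[[re]] - rate
      for (pr in r$products) dy[[pr]] <- dy[[pr]] + rate
    }
    dy
  }
  n <- ceiling(t_end / dt)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# nullspace of A x = 0 by plain row reduction (independent of svd)
nullspace_rref <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[p, col]) < tol) next
    A[c(row, p), ] <- A[c(p, row), ]
    A[row, ] <- A[row, ] / A[row, col]
    for (r in setdiff(seq_len(m), row)) {
      A[r, ] <- A[r, ] - A[r, col] * A[row, ]
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  if (!length(free)) return(matrix(0, n, 0))
  basis <- matrix(0, n, length(free))
  for (j in seq_along(free)) {
    basis[free[j], j] <- 1
    for (i in seq_along(pivots)) {
      basis[pivots[i], j] <- -A[i, free[j]]
    }
  }
  basis
}

# left-null-space oracle: conservation vectors v with t(S) v = 0
conservation_oracle <- function(network) {
  nullspace_rref(t(network$stoich))
}

# is v inside the column span of B (numerically)?
in_span <- function(B, v, tol = 1e-8) {
  if (ncol(B) == 0) return(all(abs(v) < tol))
  fit <- qr.fitted(qr(B), v)
  max(abs(v - fit)) < tol * max(1, max(abs(v)))
}

# a random (but seeded) parameter draw for a network
draw_params <- function(network, seed = 1) {
  prior <- prior_from_network(network)
  withr::with_seed(seed, {
    u <- stats::runif(length(prior$parameter_ids))
  })
  stats::setNames(10^(prior$log10_low + u * (prior$log10_high -
                                               prior$log10_low)),
                  prior$parameter_ids)
}

# hand-built trajectory objects for objective tests
synthetic_trajectory <- function(times, cparp, acc_caspase, acc_mito,
                                 tparp = 1) {
  state <- cbind(PARP = tparp - cparp, C3_PARP = 0, cPARP = cparp)
  acc <- cbind(C3_via_caspase = acc_caspase, C3_via_mito = acc_mito)
  structure(list(times = times, state = state, accumulators = acc,
                 initial = c(PARP = tparp, C3_PARP = 0, cPARP = 0),
                 failed = FALSE),
            class = "trajectory")
}

# direct term-by-term evaluation of the discrete pathway-flux sum
flux_oracle <- function(traj, acc_name, tparp) {
  cum_total <- rowSums(traj$accumulators)
  cum_path <- traj$accumulators[, acc_name]
  total <- 0
  cparp <- traj$state[, "cPARP"]
  for (t in 2:length(traj$times)) {
    frac <- if (cum_total[t] > 0) cum_path[t] / cum_total[t] else 0
    total <- total + frac * (cparp[t] - cparp[t - 1])
  }
  total / tparp
}
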