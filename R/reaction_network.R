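#' Construct a chemical species
#'
#' @param name Species identifier, unique within a network.
#' @param initial_copies Initial abundance in molecules per cell (>= 0).
#' @param compartment One of `"cytosol"`, `"mitochondria"`, `"membrane"`,
#'   `"none"`; a bookkeeping tag only, no volume corrections are applied.
#' @return A `species` object (named list).
#' @export
species <- function(name, initial_copies = 0, compartment = "none") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  compartment <- match.arg(compartment,
                           c("cytosol", "mitochondria", "membrane", "none"))
  if (!is.numeric(initial_copies) || length(initial_copies) != 1L ||
      is.na(initial_copies) || initial_copies < 0) {
    stop("initial_copies must be a single nonnegative number for species '",
         name, "'", call. = FALSE)
  }
  structure(list(name = name, compartment = compartment,
                 initial_copies = as.numeric(initial_copies)),
            class = "species")
}

#' Rate classes recognised for mass-action reactions
#'
#' Each elementary reaction carries one of four kinetic classes; the class
#' determines the log10-uniform prior range used by [prior_spec()].
#' @return Character vector of the four class names.
#' @export
rate_classes <- function() {
  c("first_order_forward", "second_order_forward",
    "first_order_reverse", "catalysis")
}

#' Construct an elementary mass-action reaction
#'
#' @param id Reaction identifier, unique within a network.
#' @param reactants Character vector of reactant species names (length 0-2;
#'   a repeated name denotes a homodimerisation step).
#' @param products Character vector of product species names (may be empty).
#' @param rate_class One of [rate_classes()]. Reactions with two reactant
#'   units must be `second_order_forward`; reactions with at most one
#'   reactant unit must carry a first-order or catalysis class.
#' @param parameter_id Rate-constant identifier; defaults to `id` (one
#'   parameter per elementary reaction).
#' @return A `reaction` object.
#' @export
reaction <- function(id, reactants, products, rate_class,
                     parameter_id = id) {
  stopifnot(is.character(id), length(id) == 1L)
  reactants <- as.character(reactants)
  products <- as.character(products)
  rate_class <- match.arg(rate_class, rate_classes())
  if (length(reactants) > 2L) {
    stop("reaction '", id, "': at most two reactant units supported",
         call. = FALSE)
  }
  if (length(reactants) == 2L && rate_class != "second_order_forward") {
    stop("reaction '", id, "': two reactant units require rate_class ",
         "'second_order_forward'", call. = FALSE)
  }
  if (length(reactants) < 2L && rate_class == "second_order_forward") {
    stop("reaction '", id, "': second_order_forward requires two ",
         "reactant units", call. = FALSE)
  }
  structure(list(id = id, reactants = reactants, products = products,
                 rate_class = rate_class, parameter_id = parameter_id),
            class = "reaction")
}

#' Assemble a mass-action reaction network
#'
#' The network is the deterministic-ODE model object used throughout the
#' package: species carry initial copy numbers, reactions carry rate classes
#' and parameter identifiers, and optional accumulators define cumulative
#' reaction-flux outputs that are integrated alongside the state (extra ODE
#' components, so attribution is exact regardless of the output grid).
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param accumulators Named list; each element is a character vector of
#'   reaction ids whose summed instantaneous rates are accumulated.
#' @return A `reaction_network` object with a precomputed stoichiometric
#'   matrix (`$stoich`, species x reactions).
#' @export
reaction_network <- function(species = list(), reactions = list(),
                             accumulators = list()) {
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names)) {
    stop("duplicate species names: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "),
         call. = FALSE)
  }
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rx_ids)) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  par_ids <- vapply(reactions, function(r) r$parameter_id, character(1))
  if (anyDuplicated(par_ids)) {
    stop("duplicate parameter ids", call. = FALSE)
  }
  for (r in reactions) {
    unknown <- setdiff(c(r$reactants, r$products), sp_names)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (length(accumulators)) {
    if (is.null(names(accumulators)) || any(!nzchar(names(accumulators)))) {
      stop("accumulators must be a named list", call. = FALSE)
    }
    for (nm in names(accumulators)) {
      unknown <- setdiff(accumulators[[nm]], rx_ids)
      if (length(unknown)) {
        stop("accumulator '", nm, "' references unknown reactions: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  S <- matrix(0, nrow = length(species), ncol = length(reactions),
              dimnames = list(sp_names, rx_ids))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (sp in r$reactants) S[sp, j] <- S[sp, j] - 1
    for (sp in r$products) S[sp, j] <- S[sp, j] + 1
  }
  structure(list(species = species, reactions = reactions,
                 accumulators = accumulators, stoich = S),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(unique(parameter_ids(x))), " parameters, ",
      length(x$accumulators), " accumulators\n", sep = "")
  invisible(x)
}

#' Species names of a network
#' @param network A [reaction_network()].
#' @return Character vector.
#' @export
species_names <- function(network) {
  vapply(network$species, function(s) s$name, character(1))
}

#' Parameter identifiers of a network, in reaction order
#' @inheritParams species_names
#' @return Character vector, one id per elementary reaction.
#' @export
parameter_ids <- function(network) {
  vapply(network$reactions, function(r) r$parameter_id, character(1))
}

#' Reaction ids of a network
#' @inheritParams species_names
#' @return Character vector.
#' @export
reaction_ids <- function(network) {
  vapply(network$reactions, function(r) r$id, character(1))
}

#' Initial copy numbers of a network
#' @inheritParams species_names
#' @return Named numeric vector (molecules per cell).
#' @export
initial_copies <- function(network) {
  stats::setNames(vapply(network$species, function(s) s$initial_copies,
                         numeric(1)),
                  species_names(network))
}

#' Rate class of every reaction
#' @inheritParams species_names
#' @return Named character vector, parameter id -> rate class.
#' @export
parameter_classes <- function(network) {
  stats::setNames(vapply(network$reactions, function(r) r$rate_class,
                         character(1)),
                  parameter_ids(network))
}

check_params <- function(network, params) {
  need <- parameter_ids(network)
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.numeric(params[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("rate parameters must be strictly positive and finite",
         call. = FALSE)
  }
  stats::setNames(vals, need)
}

reactant_index <- function(network) {
  sp <- species_names(network)
  i1 <- integer(length(network$reactions))
  i2 <- integer(length(network$reactions))
  for (j in seq_along(network$reactions)) {
    re <- network$reactions[[j]]$reactants
    i1[j] <- if (length(re) >= 1L) match(re[1L], sp) else NA_integer_
    i2[j] <- if (length(re) == 2L) match(re[2L], sp) else NA_integer_
  }
  list(i1 = i1, i2 = i2)
}

# stoichiometry extended with one row per accumulator (+1 for each member)
extended_stoich <- function(network) {
  S <- network$stoich
  if (length(network$accumulators)) {
    rx <- reaction_ids(network)
    A <- matrix(0, nrow = length(network$accumulators), ncol = ncol(S),
                dimnames = list(names(network$accumulators), colnames(S)))
    for (nm in names(network$accumulators)) {
      A[nm, match(network$accumulators[[nm]], rx)] <- 1
    }
    S <- rbind(S, A)
  }
  S
}

#' Build the mass-action derivative function of a network
#'
#' Returns the right-hand side of the ODE system: each reaction contributes
#' rate `k * prod(reactant copies)` with the network's stoichiometry;
#' accumulator components receive the summed instantaneous rates of their
#' member reactions.
#'
#' @param network A [reaction_network()].
#' @param params Named numeric vector (or `parameter_vector()`), one strictly
#'   positive rate constant per parameter id. First-order and catalysis
#'   constants are in 1/s; second-order constants in 1/(molecules/cell)/s.
#' @return A function `(t, state) -> derivative` over the extended state
#'   (species then accumulators), suitable for [deSolve::ode()] when wrapped
#'   as `function(t, y, p) list(rhs(t, y))`.
#' @export
build_ode_rhs <- function(network, params) {
  k <- check_params(network, params)
  S <- extended_stoich(network)
  idx <- reactant_index(network)
  i1 <- idx$i1
  i2 <- idx$i2
  has1 <- !is.na(i1)
  has2 <- !is.na(i2)
  nr <- length(network$reactions)
  function(t, state) {
    rates <- k
    if (nr) {
      v <- rep(1, nr)
      v[has1] <- state[i1[has1]]
      w <- rep(1, nr)
      w[has2] <- state[i2[has2]]
      rates <- k * v * w
    }
    as.numeric(S %*% rates)
  }
}

# staging payload for the compiled derivative
compiled_model_payload <- function(network) {
  S <- extended_stoich(network)
  idx <- reactant_index(network)
  nr <- ncol(S)
  off <- integer(nr + 1L)
  st_idx <- integer(0)
  st_val <- numeric(0)
  for (j in seq_len(nr)) {
    nz <- which(S[, j] != 0)
    off[j + 1L] <- off[j] + length(nz)
    st_idx <- c(st_idx, nz - 1L)
    st_val <- c(st_val, S[nz, j])
  }
  list(nstate = as.integer(nrow(S)),
       r1 = as.integer(ifelse(is.na(idx$i1), -1L, idx$i1 - 1L)),
       r2 = as.integer(ifelse(is.na(idx$i2), -1L, idx$i2 - 1L)),
       off = as.integer(off),
       idx = as.integer(st_idx),
       val = as.double(st_val))
}

#' Simulation settings
#'
#' @param t_end End time of the in-silico experiment in seconds. The default
#'   of 20,000 s is the conventional extrinsic-apoptosis horizon used for
#'   end-point objectives.
#' @param n_points Number of uniformly spaced output points including t = 0.
#' @param rtol,atol Solver tolerances (absolute tolerance in molecules).
#' @param compiled Use the compiled mass-action derivative (default) or the
#'   pure-R closure from [build_ode_rhs()].
#' @return A `sim_settings` list.
#' @export
sim_settings <- function(t_end = 20000, n_points = 201,
                         rtol = 1e-6, atol = 1e-6, compiled = TRUE) {
  stopifnot(t_end > 0, n_points >= 2)
  list(t_end = t_end, n_points = as.integer(n_points),
       rtol = rtol, atol = atol, compiled = isTRUE(compiled))
}

solve_once <- function(network, k, times, rtol, atol, compiled) {
  n_acc <- length(network$accumulators)
  y0 <- c(initial_copies(network), rep(0, n_acc))
  names(y0) <- c(species_names(network), names(network$accumulators))
  if (compiled) {
    .Call("ma_set_model", compiled_model_payload(network),
          PACKAGE = "evnest")
    .Call("ma_set_k", as.double(k), PACKAGE = "evnest")
    out <- deSolve::ode(y = y0, times = times, func = "ma_derivs",
                        parms = numeric(0), dllname = "evnest",
                        initfunc = NULL, method = "lsodes",
                        rtol = rtol, atol = atol)
  } else {
    rhs <- build_ode_rhs(network, k)
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, p) list(rhs(t, y)),
                        parms = NULL, method = "lsodes",
                        rtol = rtol, atol = atol)
  }
  out
}

#' Simulate a reaction network as a deterministic ODE system
#'
#' Integrates the mass-action ODEs from the network's initial copy numbers
#' with a stiff-capable sparse-Jacobian solver (lsodes). On solver failure the integration is retried
#' once at 10x tighter tolerances; if that also fails, a flagged trajectory
#' is returned (`$failed = TRUE`, state padded with `NA`) rather than an
#' error, so that prior-wide integrals over degenerate parameter corners
#' remain defined.
#'
#' @inheritParams build_ode_rhs
#' @param sim A [sim_settings()] list.
#' @return A `trajectory` object: `$times` (seconds), `$state` (time x
#'   species matrix of copy numbers), `$accumulators` (time x accumulator
#'   matrix, nondecreasing), `$initial` (named initial copies), `$failed`.
#' @export
simulate_network <- function(network, params, sim = sim_settings()) {
  k <- check_params(network, params)
  times <- seq(0, sim$t_end, length.out = sim$n_points)
  n_sp <- length(network$species)
  n_acc <- length(network$accumulators)

  attempt <- function(rtol, atol) {
    out <- tryCatch(
      suppressWarnings(solve_once(network, k, times, rtol, atol,
                                  sim$compiled)),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    m <- as.matrix(out)
    if (nrow(m) != length(times) || any(!is.finite(m))) return(NULL)
    m
  }

  m <- attempt(sim$rtol, sim$atol)
  if (is.null(m)) m <- attempt(sim$rtol / 10, sim$atol / 10)
  failed <- is.null(m)
  if (failed) {
    m <- matrix(NA_real_, nrow = length(times), ncol = 1 + n_sp + n_acc)
    m[, 1] <- times
  }
  state <- m[, 1 + seq_len(n_sp), drop = FALSE]
  colnames(state) <- species_names(network)
  acc <- m[, 1 + n_sp + seq_len(n_acc), drop = FALSE]
  colnames(acc) <- names(network$accumulators)
  if (!failed && n_acc) {
    # guard against sub-atol solver wiggle; accumulators are nondecreasing
    acc <- apply(acc, 2, cummax)
    if (is.null(dim(acc))) acc <- matrix(acc, nrow = length(times))
    colnames(acc) <- names(network$accumulators)
  }
  structure(list(times = times, state = state, accumulators = acc,
                 initial = initial_copies(network), failed = failed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [0, ",
      max(x$times), "] s, ", ncol(x$state), " species",
      if (x$failed) " [FAILED]" else "", "\n", sep = "")
  invisible(x)
}

#' Coerce a trajectory to a tidy tibble
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `copies`.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) {
  m <- cbind(x$state, x$accumulators)
  tibble::tibble(
    time = rep(x$times, times = ncol(m)),
    species = rep(colnames(m), each = length(x$times)),
    copies = as.numeric(m))
}

#' Conserved moieties of a reaction network
#'
#' Computes an orthonormal basis of the left null space of the
#' stoichiometric matrix; each basis vector defines a weighted species total
#' that is invariant under the network dynamics.
#'
#' @inheritParams species_names
#' @param tol Singular-value threshold relative to the largest singular
#'   value.
#' @return A matrix with one named row per species and one column per
#'   conserved moiety (possibly zero columns).
#' @export
conserved_moieties <- function(network, tol = 1e-10) {
  S <- network$stoich
  if (nrow(S) == 0L) {
    return(matrix(0, 0, 0))
  }
  if (ncol(S) == 0L) {
    basis <- diag(nrow(S))
    rownames(basis) <- species_names(network)
    return(basis)
  }
  sv <- svd(S, nu = nrow(S), nv = 0)
  d <- c(sv$d, rep(0, nrow(S) - length(sv$d)))
  keep <- d <= tol * max(sv$d, 1)
  basis <- sv$u[, keep, drop = FALSE]
  rownames(basis) <- species_names(network)
  basis
}
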