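# Objective functions integrated by the nested sampler. Both are
# dimensionless fractions in [0, 1]: the end-point PARP-cleavage fraction
# and the per-pathway share of the cleavage signal (discrete flux sum).

#' End-point PARP-cleavage fraction
#'
#' Fraction of the conserved PARP moiety that is cleaved at the final time
#' point: `cPARP(T) / tPARP`, where `tPARP` is the initial total of the
#' moiety (uncleaved + enzyme-bound + cleaved).
#'
#' @param traj A `trajectory` from [simulate_network()].
#' @param cleaved Name of the cleaved-product species.
#' @param moiety Character vector of species forming the conserved PARP
#'   moiety; its total at t = 0 defines the denominator.
#' @return A single number in `[0, 1]`; `NA` for a failed trajectory.
#' @export
parp_cleavage <- function(traj, cleaved = "cPARP",
                          moiety = c("PARP", "C3_PARP", "cPARP")) {
  missing <- setdiff(c(cleaved, moiety), colnames(traj$state))
  if (length(missing)) {
    stop("trajectory lacks species required by the PARP-cleavage ",
         "objective: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (isTRUE(traj$failed)) return(NA_real_)
  total <- sum(traj$initial[moiety])
  if (total <= 0) stop("PARP moiety total is zero", call. = FALSE)
  value <- traj$state[nrow(traj$state), cleaved] / total
  unname(min(max(value, 0), 1))
}

#' Per-pathway signal flux
#'
#' Attributes PARP cleavage to one Caspase-3-activation pathway by the
#' discrete flux sum
#' `sum_t [cumC3_pathway(t) / cumC3_total(t)] * (cPARP(t) - cPARP(t-1)) / tPARP`,
#' where the cumulative C3-activation series are the trajectory's flux
#' accumulators. Terms with `cumC3_total(t) = 0` contribute 0 (before any
#' Caspase-3 is active no cleavage can have occurred). The division by the
#' conserved PARP total makes the fluxes fractions commensurate with
#' [parp_cleavage()]: over the same grid,
#' `flux(caspase) + flux(mitochondrial) = parp_cleavage`.
#'
#' @param traj A `trajectory` carrying the pathway accumulators, ideally on
#'   a fine uniform grid (1-s spacing for production runs).
#' @param pathway `"caspase"` or `"mitochondrial"`.
#' @param accumulator_map Named character vector mapping pathway tags to
#'   accumulator names.
#' @inheritParams parp_cleavage
#' @return A single number in `[0, 1]`; `NA` for a failed trajectory.
#' @export
pathway_flux <- function(traj, pathway = c("caspase", "mitochondrial"),
                         accumulator_map = c(caspase = "C3_via_caspase",
                                             mitochondrial = "C3_via_mito"),
                         cleaved = "cPARP",
                         moiety = c("PARP", "C3_PARP", "cPARP")) {
  pathway <- match.arg(pathway)
  acc_name <- accumulator_map[[pathway]]
  if (!acc_name %in% colnames(traj$accumulators)) {
    stop("trajectory carries no accumulator '", acc_name,
         "' for pathway '", pathway, "'", call. = FALSE)
  }
  need <- intersect(unname(accumulator_map), colnames(traj$accumulators))
  if (isTRUE(traj$failed)) return(NA_real_)
  total <- sum(traj$initial[moiety])
  if (total <= 0) stop("PARP moiety total is zero", call. = FALSE)
  cum_path <- traj$accumulators[, acc_name]
  cum_total <- rowSums(traj$accumulators[, need, drop = FALSE])
  frac <- ifelse(cum_total > 0, cum_path / cum_total, 0)
  d_cparp <- diff(traj$state[, cleaved])
  value <- sum(frac[-1] * d_cparp) / total
  unname(min(max(value, 0), 1))
}

#' Compose a simulation objective over parameter space
#'
#' Binds a network, an objective kind and simulation settings into a single
#' function of the rate-parameter vector, the integrand handed to
#' [ns_run()]. Failed simulations score 0 (with a warning) so the integral
#' stays defined over the whole prior.
#'
#' @param network A [reaction_network()].
#' @param kind One of `"parp_cleavage"`, `"flux_caspase"`,
#'   `"flux_mitochondrial"`, `"flux_total"`.
#' @param sim A [sim_settings()] list. Flux objectives should use a fine
#'   uniform grid (`n_points` large relative to `t_end`).
#' @param ... Passed on to [parp_cleavage()] / [pathway_flux()] (e.g.
#'   `cleaved`, `moiety` for toy networks).
#' @return A function `params -> value in [0, 1]`.
#' @export
make_objective <- function(network, kind = c("parp_cleavage", "flux_caspase",
                                             "flux_mitochondrial",
                                             "flux_total"),
                           sim = sim_settings(), ...) {
  kind <- match.arg(kind)
  extra <- list(...)
  if (kind != "parp_cleavage") {
    map <- extra$accumulator_map %||%
      c(caspase = "C3_via_caspase", mitochondrial = "C3_via_mito")
    need <- switch(kind,
                   flux_caspase = map[["caspase"]],
                   flux_mitochondrial = map[["mitochondrial"]],
                   flux_total = unname(map))
    missing <- setdiff(need, names(network$accumulators))
    if (length(missing)) {
      stop("objective '", kind, "' needs accumulator(s) ",
           paste(missing, collapse = ", "),
           " which this network does not register", call. = FALSE)
    }
  }
  evaluate <- function(traj) {
    switch(kind,
           parp_cleavage = do.call(parp_cleavage, c(list(traj), extra)),
           flux_caspase = do.call(pathway_flux,
                                  c(list(traj, pathway = "caspase"), extra)),
           flux_mitochondrial = do.call(pathway_flux,
                                        c(list(traj,
                                               pathway = "mitochondrial"),
                                          extra)),
           flux_total = do.call(pathway_flux,
                                c(list(traj, pathway = "caspase"), extra)) +
             do.call(pathway_flux,
                     c(list(traj, pathway = "mitochondrial"), extra)))
  }
  function(params) {
    traj <- simulate_network(network, params, sim = sim)
    if (isTRUE(traj$failed)) {
      warning("simulation failed; objective scored 0", call. = FALSE)
      return(0)
    }
    value <- evaluate(traj)
    if (!is.finite(value)) {
      warning("objective evaluated non-finite; scored 0", call. = FALSE)
      return(0)
    }
    min(max(value, 0), 1)
  }
}
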