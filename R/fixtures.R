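# Named test fixtures with executable ground truth. Analytic fixtures use
# the `unit` prior class ([0, 1] in log10 space), so the unit-cube
# coordinate of a parameter is simply log10 of its linear value.

unit_coords <- function(params) log10(as.numeric(params))

#' Build a named fixture
#'
#' Fixtures pair an objective (analytic or simulation-backed) with a prior
#' and an executable ground-truth recipe, and are used to validate the
#' sampler against quantities known exactly or computable by deterministic
#' quadrature.
#'
#' * `constant`: objective identically `c = 0.7`; truth 0.7.
#' * `linear`: objective equals the first unit-cube coordinate; truth 0.5.
#' * `gaussian2d`: isotropic Gaussian bump (sd 0.1, centre 0.5) on a 2-D
#'   box; truth by adaptive quadrature.
#' * `chain3`: two-step conversion network A -> B -> C; the objective
#'   `C(T)/A0` has a closed form.
#' * `toy_inhibitor`: catalyst E converts S -> P; inhibitor I sequesters E.
#'   The expected conversion is non-increasing in the initial copies of I.
#'
#' @param name One of `"constant"`, `"linear"`, `"gaussian2d"`, `"chain3"`,
#'   `"toy_inhibitor"`.
#' @param t_end Simulation horizon for the network fixtures (seconds).
#' @return A `fixture` list: `name`, `objective` (params -> value),
#'   `prior`, `truth` (a function returning the ground-truth expected
#'   value, or `NA` when no closed/quadrature truth applies), and for
#'   network fixtures the `network`.
#' @export
build_fixture <- function(name = c("constant", "linear", "gaussian2d",
                                   "chain3", "toy_inhibitor"),
                          t_end = 100) {
  name <- match.arg(name)
  fx <- switch(
    name,
    constant = {
      prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
      list(objective = function(params) 0.7,
           prior = prior,
           truth = function() 0.7)
    },
    linear = {
      prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
      list(objective = function(params) unit_coords(params)[1],
           prior = prior,
           truth = function() 0.5)
    },
    gaussian2d = {
      prior <- prior_spec(c(u1 = "unit", u2 = "unit"))
      s <- 0.1
      obj <- function(params) {
        u <- unit_coords(params)
        exp(-((u[1] - 0.5)^2 + (u[2] - 0.5)^2) / (2 * s^2))
      }
      list(objective = obj,
           prior = prior,
           truth = function() {
             one <- stats::integrate(function(x)
               exp(-(x - 0.5)^2 / (2 * s^2)), 0, 1,
               rel.tol = 1e-10)$value
             one^2
           })
    },
    chain3 = {
      net <- chain3_network()
      prior <- prior_from_network(net)
      obj <- make_objective(net, "parp_cleavage",
                            sim = sim_settings(t_end = t_end,
                                               n_points = 101),
                            cleaved = "C", moiety = c("A", "B", "C"))
      list(objective = obj, prior = prior, network = net,
           truth = function(k1, k2, t = t_end) {
             # closed-form two-step conversion fraction C(t)/A0
             if (abs(k1 - k2) < 1e-12) {
               1 - exp(-k1 * t) * (1 + k1 * t)
             } else {
               1 + (k2 * exp(-k1 * t) - k1 * exp(-k2 * t)) / (k1 - k2)
             }
           })
    },
    toy_inhibitor = {
      net <- toy_inhibitor_network()
      prior <- prior_from_network(net)
      obj <- make_objective(net, "parp_cleavage",
                            sim = sim_settings(t_end = t_end,
                                               n_points = 101),
                            cleaved = "P", moiety = c("S", "E_S", "P"))
      list(objective = obj, prior = prior, network = net,
           truth = function() NA_real_)
    })
  structure(c(list(name = name), fx), class = "fixture")
}

#' Toy two-step conversion network A -> B -> C
#' @param a0 Initial copies of A.
#' @return A [reaction_network()].
#' @export
chain3_network <- function(a0 = 1000) {
  reaction_network(
    species = list(species("A", a0), species("B"), species("C")),
    reactions = list(
      reaction("conv_A_B", "A", "B", "first_order_forward"),
      reaction("conv_B_C", "B", "C", "first_order_forward")))
}

#' Toy catalysis-with-inhibitor network
#'
#' Catalyst E converts substrate S to product P through an enzyme-substrate
#' complex; inhibitor I reversibly sequesters E. The initial copies of I
#' act as the regulator.
#'
#' @param e0,s0,i0 Initial copies of catalyst, substrate and inhibitor.
#' @return A [reaction_network()].
#' @export
toy_inhibitor_network <- function(e0 = 100, s0 = 1000, i0 = 0) {
  reaction_network(
    species = list(species("E", e0), species("S", s0), species("I", i0),
                   species("E_S"), species("E_I"), species("P")),
    reactions = list(
      reaction("bind_E_S", c("E", "S"), "E_S", "second_order_forward"),
      reaction("unbind_E_S", "E_S", c("E", "S"), "first_order_reverse"),
      reaction("cat_E_P", "E_S", c("E", "P"), "catalysis"),
      reaction("bind_E_I", c("E", "I"), "E_I", "second_order_forward"),
      reaction("unbind_E_I", "E_I", c("E", "I"), "first_order_reverse")))
}
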