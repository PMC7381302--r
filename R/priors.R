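# Log10-uniform priors over kinetic rate constants, organised by reaction
# class. Internally the sampler works on the unit hypercube; the prior maps
# unit coordinates to rate constants.

#' Default per-class log10 prior ranges
#'
#' Ranges span four orders of magnitude around generic plausible reaction
#' rates and are specific to the reaction class.
#' @return Named list of `c(log10 low, log10 high)` pairs.
#' @export
default_class_ranges <- function() {
  list(first_order_forward = c(-4, 0),
       second_order_forward = c(-8, -4),
       first_order_reverse = c(-4, 0),
       catalysis = c(-1, 3))
}

#' Construct a prior specification
#'
#' @param classes Named character vector mapping each parameter id to its
#'   rate class. The order of `names(classes)` fixes the coordinate order.
#' @param class_ranges Named list of `c(log10 low, log10 high)` ranges, one
#'   per class appearing in `classes`; defaults to
#'   [default_class_ranges()] plus a `unit` class `[0, 1]` used by analytic
#'   test fixtures.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(classes, class_ranges = NULL) {
  ranges <- default_class_ranges()
  ranges$unit <- c(0, 1)
  if (!is.null(class_ranges)) ranges[names(class_ranges)] <- class_ranges
  stopifnot(is.character(classes), !is.null(names(classes)))
  unknown <- setdiff(unique(classes), names(ranges))
  if (length(unknown)) {
    stop("no prior range for class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (cl in unique(classes)) {
    rg <- ranges[[cl]]
    if (length(rg) != 2 || rg[1] >= rg[2]) {
      stop("class '", cl, "' range must be c(low, high) with low < high",
           call. = FALSE)
    }
  }
  lo <- vapply(unname(classes), function(cl) ranges[[cl]][1], numeric(1))
  hi <- vapply(unname(classes), function(cl) ranges[[cl]][2], numeric(1))
  structure(list(parameter_ids = names(classes),
                 classes = classes,
                 class_ranges = ranges[unique(classes)],
                 log10_low = stats::setNames(lo, names(classes)),
                 log10_high = stats::setNames(hi, names(classes))),
            class = "prior_spec")
}

#' Prior specification of a reaction network
#'
#' One log10-uniform coordinate per rate parameter, ranged by the
#' reaction's class. Parameters shared between the full model and a
#' subnetwork therefore carry identical priors.
#'
#' @param network A [reaction_network()].
#' @param class_ranges Optional range overrides, as in [prior_spec()].
#' @return A `prior_spec`.
#' @export
prior_from_network <- function(network, class_ranges = NULL) {
  prior_spec(parameter_classes(network), class_ranges = class_ranges)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", length(x$parameter_ids),
      " parameters, classes: ",
      paste(names(x$class_ranges), collapse = ", "), "\n", sep = "")
  invisible(x)
}

prior_dim <- function(prior) length(prior$parameter_ids)

# unit-cube coordinates -> named rate-constant vector (linear scale)
prior_transform <- function(prior, u) {
  stats::setNames(10^(prior$log10_low + u * (prior$log10_high -
                                               prior$log10_low)),
                  prior$parameter_ids)
}

# n draws, rows = points, on the unit cube
prior_sample_unit <- function(prior, n) {
  matrix(stats::runif(n * prior_dim(prior)), nrow = n,
         dimnames = list(NULL, prior$parameter_ids))
}
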