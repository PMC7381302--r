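# Network serialization: a native structured-text (YAML) format and a
# minimal SBML Level 3 dialect restricted to mass-action kinetic laws.
# Both round-trip species order, stoichiometry, rate classes, parameter
# ids, initial copies and accumulators (in SBML via annotations).

network_to_list <- function(network) {
  list(
    species = lapply(network$species, function(s)
      list(name = s$name, compartment = s$compartment,
           initial_copies = s$initial_copies)),
    reactions = lapply(network$reactions, function(r)
      list(id = r$id, reactants = as.list(r$reactants),
           products = as.list(r$products), rate_class = r$rate_class,
           parameter_id = r$parameter_id)),
    accumulators = lapply(network$accumulators, as.list))
}

network_from_list <- function(x) {
  reaction_network(
    species = lapply(x$species, function(s)
      species(s$name, s$initial_copies, s$compartment)),
    reactions = lapply(x$reactions, function(r)
      reaction(r$id, unlist(r$reactants) %||% character(0),
               unlist(r$products) %||% character(0),
               r$rate_class, r$parameter_id)),
    accumulators = lapply(x$accumulators %||% list(), unlist))
}

#' Write a reaction network to disk
#'
#' @param network A [reaction_network()].
#' @param path Output file.
#' @param format `"yaml"` (native structured text) or `"sbml"` (SBML Level
#'   3 with mass-action kinetic laws; rate classes and accumulators are
#'   carried in annotations). Inferred from the file extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
serialize_network <- function(network, path, format = NULL) {
  format <- format %||%
    switch(tolower(tools::file_ext(path)), xml = , sbml = "sbml", "yaml")
  format <- match.arg(format, c("yaml", "sbml"))
  if (format == "yaml") {
    yaml::write_yaml(network_to_list(network), path)
  } else {
    write_sbml(network, path)
  }
  invisible(path)
}

#' Read a reaction network from disk
#'
#' @param path File written by [serialize_network()] (or SBML produced
#'   elsewhere, provided every kinetic law is elementary mass action).
#' @param format As in [serialize_network()].
#' @return A [reaction_network()].
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||%
    switch(tolower(tools::file_ext(path)), xml = , sbml = "sbml", "yaml")
  format <- match.arg(format, c("yaml", "sbml"))
  if (format == "yaml") {
    network_from_list(yaml::read_yaml(path))
  } else {
    read_sbml(path)
  }
}

sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
mathml_ns <- "http://www.w3.org/1998/Math/MathML"
evnest_ns <- "https://evnest.invalid/sbml-annotations"

write_sbml <- function(network, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = sbml_ns,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "evnest_model")

  ann <- xml2::xml_add_child(model, "annotation")
  meta <- xml2::xml_add_child(ann, "evnestModel", xmlns = evnest_ns)
  for (nm in names(network$accumulators)) {
    xml2::xml_add_child(meta, "accumulator", name = nm,
                        reactions = paste(network$accumulators[[nm]],
                                          collapse = " "))
  }

  comps <- unique(vapply(network$species, function(s) s$compartment,
                         character(1)))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true",
                        spatialDimensions = "3", size = "1")
  }

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in network$species) {
    xml2::xml_add_child(ls, "species", id = s$name,
                        compartment = s$compartment,
                        initialAmount = format(s$initial_copies,
                                               digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }

  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (r in network$reactions) {
    xml2::xml_add_child(lp, "parameter", id = r$parameter_id, value = "1",
                        constant = "true")
  }

  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = "false")
    rann <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(rann, "evnestReaction", xmlns = evnest_ns,
                        rateClass = r$rate_class)
    add_refs <- function(parent_name, sp_names) {
      if (!length(sp_names)) return(invisible())
      lst <- xml2::xml_add_child(rx, parent_name)
      runs <- rle(sp_names)   # preserve order; merge repeated units
      for (i in seq_along(runs$values)) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = runs$values[i],
                            stoichiometry = as.character(runs$lengths[i]),
                            constant = "true")
      }
    }
    add_refs("listOfReactants", r$reactants)
    add_refs("listOfProducts", r$products)
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = mathml_ns)
    apply_node <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(apply_node, "times")
    xml2::xml_add_child(apply_node, "ci", r$parameter_id)
    for (sp in r$reactants) xml2::xml_add_child(apply_node, "ci", sp)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp <- lapply(sp_nodes, function(n) {
    species(xml2::xml_attr(n, "id"),
            as.numeric(xml2::xml_attr(n, "initialAmount")),
            xml2::xml_attr(n, "compartment") %||% "none")
  })

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx <- lapply(rx_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    refs <- function(sel) {
      nodes <- xml2::xml_find_all(n, sel)
      unlist(lapply(nodes, function(m) {
        st <- as.numeric(xml2::xml_attr(m, "stoichiometry") %||% "1")
        if (is.na(st)) st <- 1
        rep(xml2::xml_attr(m, "species"), st)
      })) %||% character(0)
    }
    reactants <- refs("./listOfReactants/speciesReference")
    products <- refs("./listOfProducts/speciesReference")
    cis <- xml2::xml_text(
      xml2::xml_find_all(n, "./kineticLaw/math/apply/ci"))
    op <- xml2::xml_find_first(n, "./kineticLaw/math/apply/*[1]")
    if (length(cis) < 1 ||
        !(xml2::xml_name(op) %in% c("times", "ci")) ||
        !setequal(cis[-1], reactants)) {
      stop("reaction '", id, "': unsupported kinetic law (only ",
           "elementary mass action k * reactants is readable)",
           call. = FALSE)
    }
    rate_class <- xml2::xml_attr(
      xml2::xml_find_first(n, ".//evnestReaction"), "rateClass")
    if (is.na(rate_class)) {
      rate_class <- if (length(reactants) == 2) "second_order_forward"
      else "first_order_forward"
    }
    reaction(id, reactants, products, rate_class, parameter_id = cis[1])
  })

  acc_nodes <- xml2::xml_find_all(doc, ".//evnestModel/accumulator")
  acc <- stats::setNames(
    lapply(acc_nodes, function(n)
      strsplit(xml2::xml_attr(n, "reactions"), " ")[[1]]),
    vapply(acc_nodes, function(n) xml2::xml_attr(n, "name"), character(1)))

  reaction_network(species = sp, reactions = rx, accumulators = acc)
}
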