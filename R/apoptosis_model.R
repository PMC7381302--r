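# Reduced extrinsic-apoptosis reaction network (EARM lineage) and its six
# in-silico knockout subnetworks.
#
# Motif decomposition used throughout (one rate parameter per elementary
# reaction):
#   reversible binding   A + B <-> A:B              2 reactions
#   catalysis            E + S <-> E:S -> E + P     3 reactions
#   translocation        A <-> A_m                  2 reactions
#   displacement         Bad + tBid_m:Bcl2 -> Bad:Bcl2 + tBid_m   1 reaction
#   degradation          Smac:XIAP -> Smac (XIAP ubiquitination)  1 reaction
# yielding 62 reactions over 50 species, 16 of them with nonzero initial
# copies.

m_bind <- function(a, b, complex, tag = NULL) {
  tag <- tag %||% paste(a, b, sep = "_")
  list(reaction(paste0("bind_", tag), c(a, b), complex,
                "second_order_forward"),
       reaction(paste0("unbind_", tag), complex, c(a, b),
                "first_order_reverse"))
}

m_cat <- function(enzyme, substrate, complex, product, tag = NULL) {
  tag <- tag %||% paste(enzyme, substrate, sep = "_")
  c(m_bind(enzyme, substrate, complex, tag = tag),
    list(reaction(paste0("cat_", tag), complex, c(enzyme, product),
                  "catalysis")))
}

m_transloc <- function(a, b, tag = NULL) {
  tag <- tag %||% paste(a, b, sep = "_to_")
  list(reaction(paste0("to_", tag), a, b, "first_order_forward"),
       reaction(paste0("from_", tag), b, a, "first_order_reverse"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apop_species_table <- function(initial) {
  # 16 species with nonzero initial copies + 34 derived complexes/forms
  zero <- function(name, comp = "cytosol") species(name, 0, comp)
  c(list(
    species("L", initial[["L"]], "cytosol"),
    species("R", initial[["R"]], "membrane"),
    species("FADD", initial[["FADD"]], "cytosol"),
    species("pC8", initial[["pC8"]], "cytosol"),
    species("pC3", initial[["pC3"]], "cytosol"),
    species("pC6", initial[["pC6"]], "cytosol"),
    species("Bid", initial[["Bid"]], "cytosol"),
    species("Bax", initial[["Bax"]], "cytosol"),
    species("Bcl2", initial[["Bcl2"]], "mitochondria"),
    species("Bad", initial[["Bad"]], "cytosol"),
    species("CytoC_m", initial[["CytoC_m"]], "mitochondria"),
    species("Smac_m", initial[["Smac_m"]], "mitochondria"),
    species("Apaf", initial[["Apaf"]], "cytosol"),
    species("pC9", initial[["pC9"]], "cytosol"),
    species("XIAP", initial[["XIAP"]], "cytosol"),
    species("PARP", initial[["PARP"]], "cytosol")),
    list(
      zero("L_R", "membrane"), zero("DISC", "membrane"),
      zero("DISC_pC8", "membrane"), zero("DISC_pC8_pC8", "membrane"),
      zero("C8"), zero("C8_pC3"), zero("C3"), zero("C8_Bid"),
      zero("tBid"), zero("tBid_m", "mitochondria"),
      zero("tBid_m_Bax", "mitochondria"), zero("aBax", "mitochondria"),
      zero("Bax2", "mitochondria"), zero("Bax4", "mitochondria"),
      zero("tBid_m_Bcl2", "mitochondria"), zero("aBax_Bcl2", "mitochondria"),
      zero("Bad_Bcl2", "mitochondria"), zero("Bax4_CytoCm", "mitochondria"),
      zero("CytoC"), zero("Bax4_Smacm", "mitochondria"), zero("Smac"),
      zero("CytoC_Apaf"), zero("Apaf_a"), zero("Apop"), zero("Apop_pC3"),
      zero("Smac_XIAP"), zero("Apop_XIAP"), zero("XIAP_C3"), zero("C3_ub"),
      zero("C3_pC6"), zero("C6"), zero("C6_pC8"), zero("C3_PARP"),
      zero("cPARP")))
}

apop_reaction_table <- function() {
  c(
    # DISC assembly and Caspase-8 activation (dimerisation at the DISC)
    m_bind("L", "R", "L_R"),
    m_bind("L_R", "FADD", "DISC"),
    m_bind("DISC", "pC8", "DISC_pC8"),
    m_bind("DISC_pC8", "pC8", "DISC_pC8_pC8", tag = "DISCpC8_pC8"),
    list(reaction("cat_DISC_C8", "DISC_pC8_pC8", c("DISC", "C8"),
                  "catalysis")),
    # direct caspase cascade: C8 -> C3
    m_cat("C8", "pC3", "C8_pC3", "C3"),
    # mitochondrial arm: C8 -> tBid -> Bax pore
    m_cat("C8", "Bid", "C8_Bid", "tBid"),
    m_transloc("tBid", "tBid_m", tag = "tBid_m"),
    m_cat("tBid_m", "Bax", "tBid_m_Bax", "aBax"),
    m_bind("aBax", "aBax", "Bax2", tag = "aBax_aBax"),
    m_bind("Bax2", "Bax2", "Bax4", tag = "Bax2_Bax2"),
    # Bcl-2 family regulation
    m_bind("tBid_m", "Bcl2", "tBid_m_Bcl2"),
    m_bind("aBax", "Bcl2", "aBax_Bcl2"),
    m_bind("Bad", "Bcl2", "Bad_Bcl2"),
    list(reaction("displace_Bad_tBidmBcl2", c("Bad", "tBid_m_Bcl2"),
                  c("Bad_Bcl2", "tBid_m"), "second_order_forward")),
    # pore-mediated export of Cytochrome c and Smac
    m_cat("Bax4", "CytoC_m", "Bax4_CytoCm", "CytoC"),
    m_cat("Bax4", "Smac_m", "Bax4_Smacm", "Smac"),
    # apoptosome assembly and mitochondrial C3 activation
    m_cat("CytoC", "Apaf", "CytoC_Apaf", "Apaf_a"),
    m_bind("Apaf_a", "pC9", "Apop"),
    m_cat("Apop", "pC3", "Apop_pC3", "C3"),
    # XIAP axis: Smac inhibition/degradation, apoptosome sequestration,
    # Caspase-3 sequestration and ubiquitination
    m_bind("Smac", "XIAP", "Smac_XIAP"),
    list(reaction("deg_Smac_XIAP", "Smac_XIAP", "Smac",
                  "first_order_forward")),
    m_bind("Apop", "XIAP", "Apop_XIAP"),
    m_cat("XIAP", "C3", "XIAP_C3", "C3_ub"),
    # feed-forward loop C3 -> C6 -> C8 and PARP execution
    m_cat("C3", "pC6", "C3_pC6", "C6"),
    m_cat("C6", "pC8", "C6_pC8", "C8"),
    m_cat("C3", "PARP", "C3_PARP", "cPARP"))
}

#' Default initial copy numbers of the apoptosis model
#'
#' Reads the packaged configuration file (`inst/extdata/initial_copies.yaml`).
#' @return Named numeric vector, molecules per cell, for the 16
#'   nonzero-initial species.
#' @export
default_initial_copies <- function() {
  path <- system.file("extdata", "initial_copies.yaml", package = "evnest",
                      mustWork = TRUE)
  unlist(yaml::read_yaml(path))
}

#' Build the reduced extrinsic-apoptosis network
#'
#' Constructs the complete network: DISC assembly and Caspase-8 activation,
#' the direct caspase cascade (C8 -> C3), the mitochondrial arm (tBid, Bax
#' pore, Cytochrome-c/Smac release, apoptosome), Bcl-2-family regulation with
#' a sensitizer, the XIAP axis (C3 sequestration/degradation, apoptosome
#' sequestration, Smac counter-inhibition), the C3 -> C6 -> C8 feed-forward
#' loop, and PARP cleavage. Two flux accumulators are registered: cumulative
#' Caspase-3 activation via the direct C8-catalysed reaction
#' (`C3_via_caspase`) and via the apoptosome-catalysed reaction
#' (`C3_via_mito`).
#'
#' @param initial Optional named numeric vector overriding any of the
#'   default initial copy numbers (see [default_initial_copies()]).
#' @return A [reaction_network()] with 50 species, 62 reactions and 62 rate
#'   parameters, 16 species at nonzero initial copies.
#' @export
build_full_model <- function(initial = NULL) {
  init <- default_initial_copies()
  if (!is.null(initial)) {
    unknown <- setdiff(names(initial), names(init))
    if (length(unknown)) {
      stop("unknown species in initial overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    init[names(initial)] <- initial
  }
  reaction_network(
    species = apop_species_table(init),
    reactions = apop_reaction_table(),
    accumulators = list(C3_via_caspase = "cat_C8_pC3",
                        C3_via_mito = "cat_Apop_pC3"))
}

#' Subnetwork variants of the apoptosis model
#'
#' @return Named character vector mapping variant codes to catalogue names:
#'   A = direct caspase only, B = direct caspase + mitochondrial activation,
#'   C = direct caspase + mitochondrial inhibition of XIAP,
#'   D = mitochondrial activation only, E = complete network,
#'   F = full mitochondrial subnetwork (no direct caspase link).
#' @export
subnetwork_variants <- function() {
  c(A = "caspase", B = "caspase+mito_act", C = "caspase+xiap_inh",
    D = "mito_act", E = "full", F = "mito_full")
}

variant_removed_reactions <- function(code) {
  direct <- c("bind_C8_pC3", "unbind_C8_pC3", "cat_C8_pC3")
  smac_arm <- c("bind_Bax4_Smac_m", "unbind_Bax4_Smac_m", "cat_Bax4_Smac_m",
                "bind_Smac_XIAP", "unbind_Smac_XIAP", "deg_Smac_XIAP")
  apop_arm <- c("bind_Bax4_CytoC_m", "unbind_Bax4_CytoC_m",
                "cat_Bax4_CytoC_m",
                "bind_CytoC_Apaf", "unbind_CytoC_Apaf", "cat_CytoC_Apaf",
                "bind_Apaf_a_pC9", "unbind_Apaf_a_pC9",
                "bind_Apop_pC3", "unbind_Apop_pC3", "cat_Apop_pC3",
                "bind_Apop_XIAP", "unbind_Apop_XIAP")
  mito_all <- c("bind_C8_Bid", "unbind_C8_Bid", "cat_C8_Bid",
                "to_tBid_m", "from_tBid_m",
                "bind_tBid_m_Bax", "unbind_tBid_m_Bax", "cat_tBid_m_Bax",
                "bind_aBax_aBax", "unbind_aBax_aBax",
                "bind_Bax2_Bax2", "unbind_Bax2_Bax2",
                "bind_tBid_m_Bcl2", "unbind_tBid_m_Bcl2",
                "bind_aBax_Bcl2", "unbind_aBax_Bcl2",
                "bind_Bad_Bcl2", "unbind_Bad_Bcl2",
                "displace_Bad_tBidmBcl2",
                smac_arm, apop_arm)
  switch(code,
         A = unique(mito_all),
         B = smac_arm,
         C = apop_arm,
         D = c(direct, smac_arm),
         E = character(0),
         F = direct,
         stop("unknown subnetwork variant '", code, "'", call. = FALSE))
}

#' Build a knockout subnetwork of the apoptosis model
#'
#' Removes the variant's excluded reactions from the full network, then
#' removes every species that no longer participates in any reaction
#' (knocked-out content is deleted, not zeroed: each subnetwork is a
#' distinct model whose expected values integrate over a reduced parameter
#' space). Accumulators whose member reactions were all removed are dropped.
#' Shared reactions keep their parameter ids, so priors transfer unchanged.
#'
#' @param variant One of `"A"`..`"F"` (see [subnetwork_variants()]) or a
#'   catalogue name such as `"caspase"` or `"full"`.
#' @param initial Optional initial-copy overrides, as in
#'   [build_full_model()]; overrides must name species retained by the
#'   variant.
#' @return A [reaction_network()].
#' @export
build_subnetwork <- function(variant, initial = NULL) {
  codes <- subnetwork_variants()
  code <- if (variant %in% names(codes)) variant else names(codes)[match(variant, codes)]
  if (is.na(code)) {
    stop("unknown subnetwork variant '", variant, "'", call. = FALSE)
  }
  full <- build_full_model()
  drop_rx <- variant_removed_reactions(code)
  keep <- !(reaction_ids(full) %in% drop_rx)
  reactions <- full$reactions[keep]
  used <- unique(unlist(lapply(reactions, function(r)
    c(r$reactants, r$products))))
  sp <- full$species[species_names(full) %in% used]
  acc <- lapply(full$accumulators, function(ids)
    intersect(ids, vapply(reactions, function(r) r$id, character(1))))
  acc <- acc[vapply(acc, length, integer(1)) > 0]
  net <- reaction_network(species = sp, reactions = reactions,
                          accumulators = acc)
  if (!is.null(initial)) {
    unknown <- setdiff(names(initial), species_names(net))
    if (length(unknown)) {
      stop("initial overrides name species absent from variant ", code,
           ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(initial)) net <- set_initial(net, nm, initial[[nm]])
  }
  net
}

#' Set the initial copy number of one species
#'
#' @param network A [reaction_network()].
#' @param species_name Name of a species present in the network. Naming a
#'   knocked-out (absent) species is an error.
#' @param copies New initial abundance, molecules per cell (>= 0).
#' @return A copy of the network with the single initial value replaced;
#'   structure untouched.
#' @export
set_initial <- function(network, species_name, copies) {
  i <- match(species_name, species_names(network))
  if (is.na(i)) {
    stop("species '", species_name, "' not present in this network",
         call. = FALSE)
  }
  if (!is.numeric(copies) || length(copies) != 1L || is.na(copies) ||
      copies < 0) {
    stop("copies must be a single nonnegative number", call. = FALSE)
  }
  network$species[[i]]$initial_copies <- as.numeric(copies)
  network
}
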