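# Minimal SBML Level 3 serialization over xml2.  Covers what the
# package round-trips: species with compartments and (simplified)
# chemical formulas, reactions with stoichiometry, reversibility,
# numeric flux bounds encoded as model-level parameters, reaction
# category and gene list carried in annotation attributes.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"

#' Export a model as SBML Level 3
#'
#' Writes a self-contained SBML document: compartments, species (with
#' the simplified elemental formula, when known, in the species
#' \code{name}), reactions with \code{speciesReference} stoichiometry,
#' reversibility flags, and per-reaction flux bounds and category
#' stored as reaction-local attributes in the leafFBA namespace.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS, level = "3",
                            version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "leafFBA_model")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model@metabolites$compartment))
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  comp <- model@composition
  for (i in seq_len(nrow(model@metabolites))) {
    id <- model@metabolites$id[i]
    sp <- xml2::xml_add_child(ls, "species", id = id,
                              compartment = model@metabolites$compartment[i],
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (!is.null(comp[[id]]))
      xml2::xml_set_attr(sp, "name", .formatFormula(comp[[id]]))
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  rx <- model@reactions
  for (j in seq_len(nrow(rx))) {
    st <- reactionStoichiometry(model, rx$id[j])
    rev <- rx$lower[j] < 0 && rx$upper[j] > 0
    rn <- xml2::xml_add_child(lr, "reaction", id = rx$id[j],
                              reversible = tolower(as.character(rev)))
    fmt <- function(x) format(x, digits = 15, scientific = FALSE,
                              trim = TRUE)
    xml2::xml_set_attr(rn, "metaid", rx$id[j])
    xml2::xml_set_attr(rn, "sboTerm", NULL)
    ## leafFBA extension attributes
    xml2::xml_set_attr(rn, "name",
                       paste0("category=", rx$category[j],
                              ";lb=", fmt(rx$lower[j]),
                              ";ub=", fmt(rx$upper[j]),
                              if (nzchar(rx$genes[j]))
                                paste0(";genes=", rx$genes[j]) else ""))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lsub <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(subs))
        xml2::xml_add_child(lsub, "speciesReference",
                            species = names(subs)[k],
                            stoichiometry = fmt(-subs[k]),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prods))
        xml2::xml_add_child(lp, "speciesReference",
                            species = names(prods)[k],
                            stoichiometry = fmt(prods[k]),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML written by [writeSBML()]
#'
#' Reads species, reactions, stoichiometry, bounds and categories back
#' into a [MetabolicModel-class].  Reactions lacking the leafFBA bound
#' annotation get the default bounds implied by their reversibility
#' flag.
#'
#' @param path SBML file.
#' @return a [MetabolicModel-class].
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  comp <- list()
  for (sp in spNodes) {
    nm <- xml2::xml_attr(sp, "name")
    if (!is.na(nm) && nzchar(nm))
      comp[[xml2::xml_attr(sp, "id")]] <- .parseFormula(nm)
  }
  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rxNodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      st[s] <- (if (is.na(st[s])) 0 else st[s]) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      st[s] <- (if (is.na(st[s])) 0 else st[s]) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lo <- if (rev) -.BIG else 0
    hi <- .BIG
    cat <- NA_character_
    genes <- character(0)
    ann <- xml2::xml_attr(rn, "name")
    if (!is.na(ann) && nzchar(ann)) {
      kv <- strsplit(strsplit(ann, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      for (p in kv) {
        if (length(p) != 2) next
        switch(p[1],
               category = { cat <- p[2] },
               lb = { lo <- as.numeric(p[2]) },
               ub = { hi <- as.numeric(p[2]) },
               genes = { genes <- strsplit(p[2], "|", fixed = TRUE)[[1]] })
      }
    }
    list(id = id, stoichiometry = st[st != 0], lower = lo, upper = hi,
         category = cat, genes = genes)
  })
  m <- .buildModel(rxns, composition = comp)
  validObject(m)
  m
}
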