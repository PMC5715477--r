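#' @include AllClasses.R AllGenerics.R
NULL

#' Infer metabolite compartments from the id prefix convention
#'
#' \code{chl_} chloroplast, \code{mit_} mitochondrion, \code{per_}
#' peroxisome, \code{ext_} external, anything else cytosol.  The
#' mapping is total: every id resolves to exactly one compartment.
#'
#' @param ids character vector of metabolite ids.
#' @return character vector of compartment names.
#' @examples
#' compartmentFromId(c("chl_GAP", "GAP", "per_H2O2", "ext_CO2"))
#' @export
compartmentFromId <- function(ids) {
  out <- rep("cytosol", length(ids))
  out[startsWith(ids, "chl_")] <- "chloroplast"
  out[startsWith(ids, "mit_")] <- "mitochondrion"
  out[startsWith(ids, "per_")] <- "peroxisome"
  out[startsWith(ids, "ext_")] <- "external"
  out
}

## Build a MetabolicModel from a list of reaction descriptions:
## list(id=, stoichiometry=named numeric, lower=, upper=, category=,
## genes=character()).  Metabolites are created on first reference.
#' @noRd
.buildModel <- function(rxns, composition = list(), annotations = list()) {
  ids <- vapply(rxns, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate reaction id: ", paste(unique(dup), collapse = ", "))
  metIds <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  if (is.null(metIds)) metIds <- character(0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$stoichiometry
    st <- st[st != 0]
    if (!length(st))
      stop("reaction with empty stoichiometry: ", ids[j])
    ii <- c(ii, match(names(st), metIds))
    jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(metIds), length(rxns)),
                            dimnames = list(metIds, ids))
  num <- function(f, d) vapply(rxns, function(r) {
    v <- r[[f]]; if (is.null(v) || is.na(v)) d else as.numeric(v)
  }, 0)
  lower <- num("lower", 0)
  upper <- num("upper", .BIG)
  category <- vapply(rxns, function(r) {
    v <- r[["category"]]
    if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_ else v
  }, "")
  genes <- vapply(rxns, function(r) {
    g <- r[["genes"]]
    if (is.null(g)) "" else paste(g, collapse = "|")
  }, "")
  if (any(lower > upper))
    stop("inverted bounds for: ",
         paste(ids[lower > upper], collapse = ", "))
  ## name-based fallback when the category column is absent
  fallback <- function(j) {
    id <- ids[j]
    st <- S[, j]
    if (startsWith(id, "biomass_")) return("biomass_transporter")
    if (sum(st != 0) == 1) return("exchange")
    if (grepl("_tx$", id)) return("intracellular_transporter")
    "metabolic"
  }
  miss <- which(is.na(category))
  for (j in miss) category[j] <- fallback(j)
  reactions <- data.frame(id = ids, lower = lower, upper = upper,
                          category = category, genes = genes,
                          stringsAsFactors = FALSE)
  metabolites <- data.frame(id = metIds,
                            compartment = compartmentFromId(metIds),
                            stringsAsFactors = FALSE)
  new("MetabolicModel", reactions = reactions, stoichiometry = S,
      metabolites = metabolites, composition = composition,
      annotations = annotations)
}

#' @rdname accessors
#' @export
setMethod("reactionIds", "MetabolicModel",
          function(object) object@reactions$id)

#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel",
          function(object) object@metabolites$id)

#' @rdname accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(object, ...) object@stoichiometry)

#' @rdname accessors
#' @export
setMethod("reactionBounds", "MetabolicModel", function(object) {
  data.frame(id = object@reactions$id, lower = object@reactions$lower,
             upper = object@reactions$upper, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("reactionCategories", "MetabolicModel", function(object)
  stats::setNames(object@reactions$category, object@reactions$id))

#' @rdname accessors
#' @export
setMethod("metaboliteCompartments", "MetabolicModel", function(object)
  stats::setNames(object@metabolites$compartment, object@metabolites$id))

#' @rdname accessors
#' @export
setMethod("elementalCompositions", "MetabolicModel",
          function(object) object@composition)

#' Stoichiometry of one reaction
#'
#' @param model a [MetabolicModel-class].
#' @param id reaction id.
#' @return named numeric vector (negative = consumed).
#' @export
reactionStoichiometry <- function(model, id) {
  j <- match(id, model@reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", id)
  col <- model@stoichiometry[, j]
  col <- col[col != 0]
  ## Matrix drops names for length-1 logical subsetting edge cases
  if (is.null(names(col)))
    names(col) <- metaboliteIds(model)[model@stoichiometry[, j] != 0]
  col
}

#' Replace the bounds of one reaction
#'
#' @param model a [MetabolicModel-class].
#' @param id reaction id.
#' @param lower,upper new bounds (either may be NULL to keep).
#' @return the modified model.
#' @export
setReactionBounds <- function(model, id, lower = NULL, upper = NULL) {
  j <- match(id, model@reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", id)
  if (!is.null(lower)) model@reactions$lower[j] <- lower
  if (!is.null(upper)) model@reactions$upper[j] <- upper
  validObject(model)
  model
}

setMethod("show", "MetabolicModel", function(object) {
  rx <- object@reactions
  cat("MetabolicModel with", nrow(rx), "reactions and",
      nrow(object@metabolites), "metabolites\n")
  tb <- table(rx$category)
  for (nm in names(tb)) cat("  ", nm, ": ", tb[[nm]], "\n", sep = "")
  cc <- table(object@metabolites$compartment)
  cat("  compartments:",
      paste(sprintf("%s (%d)", names(cc), cc), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution",
          function(object) object@objectiveValue)

#' @rdname accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status)
  if (object@status == "optimal")
    cat(", objective", format(object@objectiveValue, digits = 8),
        ",", sum(abs(object@fluxes) > 1e-9), "active reactions")
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("scanValues", "ScanResult", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("scanSolutions", "ScanResult", function(object) object@solutions)

#' Flux matrix of a scan
#'
#' @param object a [ScanResult-class].
#' @param optimalOnly drop non-optimal grid points (default TRUE).
#' @param ... unused.
#' @return numeric matrix, reactions x parameter values.
#' @rdname accessors
#' @export
setMethod("fluxMatrix", "ScanResult",
          function(object, optimalOnly = TRUE, ...) {
  keep <- if (optimalOnly)
    vapply(object@solutions, function(s) s@status == "optimal", TRUE)
  else rep(TRUE, length(object@solutions))
  sols <- object@solutions[keep]
  if (!length(sols))
    return(matrix(numeric(0), 0, 0))
  ids <- names(sols[[1]]@fluxes)
  m <- vapply(sols, function(s) s@fluxes[ids], numeric(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids))
  rownames(m) <- ids
  colnames(m) <- format(object@values[keep], trim = TRUE)
  m
})

setMethod("show", "ScanResult", function(object) {
  ok <- vapply(object@solutions, function(s) s@status == "optimal", TRUE)
  cat("ScanResult over", object@parameterName, "with",
      length(object@values), "points (", sum(ok), "optimal )\n")
})

#' @rdname accessors
#' @export
setMethod("modeCounts", "ModeSummary", function(object)
  stats::setNames(object@counts, object@signatures))

setMethod("show", "ModeSummary", function(object) {
  cat("ModeSummary:", length(object@signatures), "modes over",
      object@nIterations, "iterations (",
      object@infeasibleCount, "infeasible )\n")
  ord <- order(object@counts, decreasing = TRUE)
  top <- head(ord, 10)
  for (i in top)
    cat(sprintf("  %-12s %6d\n", object@signatures[i], object@counts[i]))
})

#' @importFrom utils head
NULL
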