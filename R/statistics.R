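#' Count statistics of a metabolic model
#'
#' Totals plus per-compartment counts of metabolic reactions and
#' per-category reaction counts.  A metabolic reaction is assigned the
#' compartment of its participating metabolites (or \code{"mixed"} when
#' these disagree, which a well-formed compartmentalized model avoids);
#' transporters and exchanges are counted by category only, since they
#' straddle compartments by definition.
#'
#' @param model a [MetabolicModel-class].
#' @return object of class \code{ModelStatistics}: a list with elements
#'   \code{reactionCountTotal}, \code{metaboliteCountTotal},
#'   \code{perCompartmentCounts} (metabolic reactions),
#'   \code{perCategoryCounts}, \code{metabolitesPerCompartment}.
#' @examples
#' fx <- buildFixtureNetwork("chain", n = 3)
#' modelStatistics(fx$model)
#' @export
modelStatistics <- function(model) {
  rx <- model@reactions
  compOf <- metaboliteCompartments(model)
  S <- model@stoichiometry
  rxComp <- vapply(seq_len(nrow(rx)), function(j) {
    mets <- metaboliteIds(model)[S[, j] != 0]
    cc <- unique(compOf[mets])
    if (length(cc) == 1) cc else "mixed"
  }, "")
  isMet <- rx$category == "metabolic"
  perComp <- table(factor(rxComp[isMet],
                          levels = c(setdiff(.COMPARTMENTS, "external"),
                                     "mixed")))
  perCat <- table(factor(rx$category, levels = .CATEGORIES))
  out <- list(reactionCountTotal = nrow(rx),
              metaboliteCountTotal = nrow(model@metabolites),
              perCompartmentCounts = as.list(perComp),
              perCategoryCounts = as.list(perCat),
              metabolitesPerCompartment =
                as.list(table(model@metabolites$compartment)))
  class(out) <- "ModelStatistics"
  out
}

#' @export
print.ModelStatistics <- function(x, ...) {
  cat("Reactions:", x$reactionCountTotal,
      " Metabolites:", x$metaboliteCountTotal, "\n")
  cat("Metabolic reactions per compartment:\n")
  for (nm in names(x$perCompartmentCounts))
    if (x$perCompartmentCounts[[nm]] > 0)
      cat(sprintf("  %-14s %d\n", nm, x$perCompartmentCounts[[nm]]))
  cat("Reactions per category:\n")
  for (nm in names(x$perCategoryCounts))
    if (x$perCategoryCounts[[nm]] > 0)
      cat(sprintf("  %-26s %d\n", nm, x$perCategoryCounts[[nm]]))
  invisible(x)
}
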