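#' Read a metabolic model from a tab-separated reaction table
#'
#' The table is UTF-8, tab-separated with a header row and columns
#' \code{reaction_id}, \code{equation}, \code{lower_bound},
#' \code{upper_bound}, \code{category}, \code{genes} (pipe-separated)
#' and optionally \code{subsystem}.  Empty bound cells fall back to the
#' defaults: irreversible reactions (arrow \code{->}) get
#' \code{[0, 1e6]}, reversible (\code{<>}) \code{[-1e6, 1e6]}.  An
#' empty category cell is inferred from the id (\code{biomass_*} ->
#' biomass transporter, single-species stoichiometry -> exchange,
#' \code{*_tx} -> intracellular transporter, else metabolic).
#' Metabolites are created on first reference, with the compartment
#' taken from the id prefix.
#'
#' @param path model table file.
#' @param metaboliteFile optional tab-separated file with columns
#'   \code{metabolite_id}, \code{formula} supplying elemental
#'   compositions (simplified formulas over C,H,N,O,P,S).
#' @return a [MetabolicModel-class].
#' @seealso [writeModelTable()], [parseReactionEquation()]
#' @export
readModelTable <- function(path, metaboliteFile = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(tab)))
    stop("model table must have columns reaction_id and equation")
  getcol <- function(nm) if (nm %in% names(tab)) tab[[nm]] else
    rep("", nrow(tab))
  lowerC <- getcol("lower_bound")
  upperC <- getcol("upper_bound")
  catC <- getcol("category")
  geneC <- getcol("genes")
  rxns <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pe <- parseReactionEquation(tab$equation[i])
    lo <- if (nzchar(lowerC[i])) as.numeric(lowerC[i]) else
      if (pe$reversible) -.BIG else 0
    hi <- if (nzchar(upperC[i])) as.numeric(upperC[i]) else .BIG
    if (is.na(lo) || is.na(hi))
      stop("unparseable bounds in row ", i)
    if (lo > hi)
      stop("inverted bounds for reaction ", tab$reaction_id[i])
    genes <- if (nzchar(geneC[i])) strsplit(geneC[i], "|", fixed = TRUE)[[1]]
             else character(0)
    rxns[[i]] <- list(id = tab$reaction_id[i], stoichiometry = pe$stoichiometry,
                      lower = lo, upper = hi,
                      category = if (nzchar(catC[i])) catC[i] else NA,
                      genes = genes)
  }
  comp <- list()
  if (!is.null(metaboliteFile)) {
    mt <- utils::read.delim(metaboliteFile, stringsAsFactors = FALSE,
                            colClasses = "character")
    for (i in seq_len(nrow(mt)))
      if (nzchar(mt$formula[i]))
        comp[[mt$metabolite_id[i]]] <- .parseFormula(mt$formula[i])
  }
  m <- .buildModel(rxns, composition = comp)
  validObject(m)
  m
}

#' Write a metabolic model to the tabular format
#'
#' Inverse of [readModelTable()]; \code{readModelTable(writeModelTable(m))}
#' reproduces the model up to row ordering.  Reversibility is encoded
#' in the arrow (\code{<>} when \code{lower < 0 < upper}).
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @param metaboliteFile optional path for the metabolite/composition
#'   sidecar table.
#' @return \code{path}, invisibly.
#' @export
writeModelTable <- function(model, path, metaboliteFile = NULL) {
  rx <- model@reactions
  eqs <- vapply(seq_len(nrow(rx)), function(j) {
    buildReactionEquation(reactionStoichiometry(model, rx$id[j]),
                          reversible = rx$lower[j] < 0 && rx$upper[j] > 0)
  }, "")
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  out <- data.frame(reaction_id = rx$id, equation = eqs,
                    lower_bound = fmt(rx$lower), upper_bound = fmt(rx$upper),
                    category = rx$category, genes = rx$genes,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(metaboliteFile)) {
    comp <- model@composition
    mets <- metaboliteIds(model)
    mt <- data.frame(metabolite_id = mets,
                     compartment = model@metabolites$compartment,
                     formula = vapply(mets, function(id) {
                       if (!is.null(comp[[id]])) .formatFormula(comp[[id]])
                       else ""
                     }, ""),
                     stringsAsFactors = FALSE)
    utils::write.table(mt, metaboliteFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a biomass composition table
#'
#' Two tab-separated columns: \code{transporter_id}, \code{flux}.
#'
#' @param path file path.
#' @return named numeric vector of fixed biomass-transporter fluxes.
#' @export
readBiomassComposition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}
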