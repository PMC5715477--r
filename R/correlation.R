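#' @include scenarios.R
NULL

#' Correlate reaction fluxes with the scanned parameter
#'
#' For every reaction, the absolute Pearson correlation coefficient
#' between its flux series and the parameter series across the optimal
#' scan points.  Infeasible points are dropped pairwise first;
#' reactions whose flux shows no change across the scan are excluded
#' (their correlation is undefined) and listed separately.
#'
#' @param scan a [ScanResult-class] with at least 3 optimal points.
#' @param constTolerance flux-series range below which a reaction
#'   counts as constant, default 1e-9.
#' @return object of class \code{CorrelationTable}: list with
#'   \code{entries} (named numeric of |r| values) and
#'   \code{excludedConstant} (character).
#' @seealso [classifyCorrelationStrength()], [compareStrongSets()]
#' @export
correlateScan <- function(scan, constTolerance = 1e-9) {
  ok <- vapply(scanSolutions(scan),
               function(s) solutionStatus(s) == "optimal", TRUE)
  if (sum(ok) < 3)
    stop("correlation needs at least 3 optimal scan points, got ",
         sum(ok))
  fm <- fluxMatrix(scan)              # optimal points only
  p <- scanValues(scan)[ok]
  rng <- apply(fm, 1, function(x) diff(range(x)))
  isConst <- rng <= constTolerance
  entries <- vapply(which(!isConst), function(i)
    abs(stats::cor(fm[i, ], p)), 0)
  names(entries) <- rownames(fm)[!isConst]
  out <- list(entries = entries,
              excludedConstant = rownames(fm)[isConst])
  class(out) <- "CorrelationTable"
  out
}

#' @export
print.CorrelationTable <- function(x, ...) {
  cat("CorrelationTable:", length(x$entries), "reactions (",
      length(x$excludedConstant), "constant excluded )\n")
  top <- sort(x$entries, decreasing = TRUE)
  show <- utils::head(top, 10)
  for (nm in names(show))
    cat(sprintf("  %-24s |r| = %.3f\n", nm, show[[nm]]))
  invisible(x)
}

#' Classify correlation strength
#'
#' Strong when \eqn{|r|} falls in \code{strongBand} (default the
#' closed interval [0.9, 1]); moderate in \code{[moderateCut, 0.9)};
#' weak below.
#'
#' @param table a \code{CorrelationTable} from [correlateScan()].
#' @param strongBand closed interval for "strong", default
#'   \code{c(0.9, 1)}.
#' @param moderateCut lower edge of "moderate", default 0.5.
#' @return named character vector over the table's reactions.
#' @export
classifyCorrelationStrength <- function(table, strongBand = c(0.9, 1),
                                        moderateCut = 0.5) {
  r <- table$entries
  out <- ifelse(r >= strongBand[1] & r <= strongBand[2], "strong",
                ifelse(r >= moderateCut, "moderate", "weak"))
  stats::setNames(out, names(r))
}

#' Compare strongly correlated reaction sets of two scans
#'
#' Partition of the strongly correlated reactions across two
#' correlation tables (e.g. the Vc/Vo scan versus the light scan).
#'
#' @param tableA,tableB \code{CorrelationTable} objects.
#' @param strongBand,moderateCut passed to
#'   [classifyCorrelationStrength()].
#' @return list with \code{onlyA}, \code{onlyB}, \code{both}
#'   (character vectors).
#' @export
compareStrongSets <- function(tableA, tableB, strongBand = c(0.9, 1),
                              moderateCut = 0.5) {
  sa <- names(which(classifyCorrelationStrength(
    tableA, strongBand, moderateCut) == "strong"))
  sb <- names(which(classifyCorrelationStrength(
    tableB, strongBand, moderateCut) == "strong"))
  list(onlyA = setdiff(sa, sb), onlyB = setdiff(sb, sa),
       both = intersect(sa, sb))
}
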