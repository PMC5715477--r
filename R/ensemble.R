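#' @include fba.R
NULL

## Counter-based per-iteration seed derivation: deterministic in
## (masterSeed, i), order-independent, and < 2^31.
#' @noRd
.iterationSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 1000003 + i) %% 2147483647)
}

#' Draw random enzymatic-cost weights
#'
#' Mimics varying enzyme expression: every non-excluded reaction gets
#' an independent uniform weight on \code{range} (default 0 to 1000)
#' from a seeded generator; excluded reactions (by default every
#' non-metabolic category, i.e. all transporters, exchanges, the
#' maintenance demand, and the cyclic and non-cyclic
#' photophosphorylation reactions) keep the baseline weight exactly.
#'
#' The baseline default is 1 rather than 0: weight-0 transporters
#' would carry flux at no objective cost and admit unbounded futile
#' shuttling.
#'
#' @param model a [MetabolicModel-class].
#' @param seed integer seed.
#' @param baseline weight for excluded reactions, default 1.
#' @param range weight interval, default \code{c(0, 1000)}.
#' @param exclude \code{NULL} for the default rule, a character vector
#'   of reaction ids, or a predicate \code{function(id, category)}.
#' @return list with \code{seed}, \code{weights} (named numeric) and
#'   \code{excluded} (character).
#' @seealso [runEnsemble()]
#' @export
drawWeights <- function(model, seed, baseline = 1, range = c(0, 1000),
                        exclude = NULL) {
  rx <- model@reactions
  excluded <- if (is.null(exclude)) {
    rx$id[rx$category != "metabolic"]
  } else if (is.character(exclude)) {
    exclude
  } else if (is.function(exclude)) {
    rx$id[mapply(exclude, rx$id, rx$category)]
  } else stop("exclude must be NULL, ids, or a predicate")
  w <- stats::setNames(rep(baseline, nrow(rx)), rx$id)
  free <- setdiff(rx$id, excluded)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  w[free] <- stats::runif(length(free), range[1], range[2])
  list(seed = seed, weights = w, excluded = intersect(rx$id, excluded))
}

## Save/restore the global RNG state so ensemble runs do not perturb
## the caller's random stream.
#' @noRd
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @noRd
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Activity/direction signature of tracked reactions
#'
#' Componentwise sign of the tracked fluxes with a dead zone:
#' \code{"+"} for flux > tolerance, \code{"-"} for flux < -tolerance,
#' \code{"0"} otherwise, concatenated in tracked order.
#'
#' @param solution a [FluxSolution-class].
#' @param tracked ordered reaction ids.
#' @param tolerance dead-zone half width, default 1e-6.
#' @return single character string, e.g. \code{"+0-"}.
#' @export
computeModeSignature <- function(solution, tracked, tolerance = 1e-6) {
  v <- fluxes(solution)
  miss <- setdiff(tracked, names(v))
  if (length(miss)) stop("tracked reaction missing from solution: ",
                         paste(miss, collapse = ", "))
  s <- ifelse(v[tracked] > tolerance, "+",
              ifelse(v[tracked] < -tolerance, "-", "0"))
  paste(s, collapse = "")
}

#' Random-weight enzymatic cost ensemble
#'
#' Repeats the weighted flux minimization \code{n} times, each with an
#' independent random weight draw ([drawWeights()]), and aggregates
#' the distinct mode signatures of the tracked reactions.  Iteration
#' \code{i} uses a seed derived deterministically from
#' \code{(masterSeed, i)}, so runs are reproducible and
#' order-independent.  Solver failures are counted as infeasible and
#' never abort the run.
#'
#' @param model a [MetabolicModel-class].
#' @param constraints a [ConstraintSet-class]; nutrient and photon
#'   uptakes stay free (>= 0) unless the constraints say otherwise.
#' @param n number of iterations.
#' @param masterSeed integer master seed.
#' @param tracked ordered reaction ids whose signs define a mode.
#' @param modeTolerance dead zone for the sign, default 1e-6.
#' @param baseline,range,exclude weight-draw options, see
#'   [drawWeights()].
#' @param archive if TRUE, attach the per-iteration flux matrix
#'   (reactions x iterations) as attribute \code{"archive"}.
#' @return a [ModeSummary-class].
#' @examples
#' fx <- buildFixtureNetwork("k_parallel", k = 3, demand = 1)
#' ms <- runEnsemble(fx$model, fx$constraints, n = 100, masterSeed = 1,
#'                   tracked = c("R1", "R2", "R3"))
#' modeCounts(ms)
#' @export
runEnsemble <- function(model, constraints, n, masterSeed, tracked,
                        modeTolerance = 1e-6, baseline = 1,
                        range = c(0, 1000), exclude = NULL,
                        archive = FALSE) {
  stopifnot(n >= 1)
  miss <- setdiff(tracked, reactionIds(model))
  if (length(miss)) stop("tracked reaction not in model: ",
                         paste(miss, collapse = ", "))
  sigs <- character(n)
  ok <- logical(n)
  arch <- if (archive)
    matrix(NA_real_, nrow(model@reactions), n,
           dimnames = list(reactionIds(model), NULL))
  else NULL
  for (i in seq_len(n)) {
    wd <- drawWeights(model, .iterationSeed(masterSeed, i),
                      baseline = baseline, range = range,
                      exclude = exclude)
    sol <- tryCatch(minimizeWeightedFlux(model, constraints, wd$weights),
                    error = function(e)
                      new("FluxSolution",
                          fluxes = stats::setNames(
                            rep(NA_real_, nrow(model@reactions)),
                            reactionIds(model)),
                          objectiveValue = NA_real_, status = "error"))
    if (solutionStatus(sol) == "optimal") {
      ok[i] <- TRUE
      sigs[i] <- computeModeSignature(sol, tracked, modeTolerance)
      if (archive) arch[, i] <- fluxes(sol)
    }
  }
  tab <- table(sigs[ok])
  out <- new("ModeSummary", tracked = tracked,
             signatures = names(tab),
             counts = as.integer(tab),
             infeasibleCount = as.integer(sum(!ok)),
             nIterations = as.integer(n))
  if (archive) attr(out, "archive") <- arch
  out
}

#' Tracked-reaction presets for the core leaf model
#'
#' Two presets mirroring the transporter analyses this package's
#' ensemble targets: \code{"transporters"} tracks the chloroplastic
#' and mitochondrial intracellular transporters, and
#' \code{"glu_gln"} tracks the chloroplastic Glu-Gln transporter
#' together with the cytosolic (GS1) and chloroplastic (GS2) glutamine
#' synthetase isoforms.
#'
#' @param model a [MetabolicModel-class].
#' @param preset \code{"transporters"} or \code{"glu_gln"}.
#' @return character vector of reaction ids present in the model.
#' @export
trackedPreset <- function(model, preset = c("transporters", "glu_gln")) {
  preset <- match.arg(preset)
  ids <- reactionIds(model)
  if (preset == "transporters") {
    cats <- reactionCategories(model)
    tx <- ids[cats == "intracellular_transporter"]
    tx[startsWith(tx, "chl_") | startsWith(tx, "mit_")]
  } else {
    intersect(c("chl_GlnGlu_tx", "GS1", "chl_GS2"), ids)
  }
}
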