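#' @include synthetic.R fva.R scenarios.R ensemble.R correlation.R
NULL

.CONFIG_KEYS <- c("model", "metabolite_file", "composition",
                  "maintenance", "out_dir", "seed", "consistency",
                  "vcvo", "light", "ensemble", "carb_id", "oxy_id",
                  "photon_id", "cyclic_id", "noncyclic_id")

#' Read and validate a run configuration
#'
#' YAML configuration for [runExperiment()].  Keys: \code{model}
#' (path to a model table, or \code{"core_leaf"} for the synthetic
#' core model), \code{metabolite_file}, \code{composition} (path or
#' named map of biomass fluxes), \code{maintenance}, \code{out_dir},
#' \code{seed}, \code{consistency} (logical, run checks first),
#' \code{vcvo} (list of ratio strings like \code{"3:1"}), \code{light}
#' (\code{from}, \code{to}, \code{step}), \code{ensemble} (\code{n},
#' \code{tracked} preset or id list, \code{fix_vcvo} ratio string or
#' null for the unconstrained case), plus the reaction-id keys
#' \code{carb_id}, \code{oxy_id}, \code{photon_id}, \code{cyclic_id},
#' \code{noncyclic_id}.  Unknown keys are rejected before any solve.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model)) stop("configuration lacks a model")
  cfg
}

#' @noRd
.parseRatio <- function(s) {
  if (is.numeric(s)) return(c(s, 1))
  ab <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(ab) != 2 || anyNA(ab)) stop("bad ratio: ", s)
  ab
}

#' Run the full simulation pipeline on a model
#'
#' Executes, in order: model loading (or synthesis), consistency
#' checks, flux-minimizing FBA, FVA at Vc/Vo 1:1 and 3:1, the Vc/Vo
#' scan, the light scan, the random-weight ensemble, and the
#' flux-parameter correlations; each stage writes a tab-separated
#' table into the output directory, plus a machine-readable run
#' manifest with the seed and configuration.  A stage failure raises a
#' stage-labeled error; tables already written are retained.
#'
#' @param config a list as returned by [readRunConfig()], or a path to
#'   a YAML file.
#' @return the output directory, invisibly.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- config$out_dir
  if (is.null(out)) stop("configuration lacks out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- load ------------------------------------------------------------
  core <- NULL
  model <- stage("load", {
    if (identical(config$model, "core_leaf")) {
      core <- buildCoreLeafModel()
      core$model
    } else readModelTable(config$model, config$metabolite_file)
  })
  composition <- stage("load", {
    if (is.null(config$composition)) {
      if (!is.null(core)) core$constraints@fixedFluxes else numeric(0)
    } else if (is.character(config$composition)) {
      readBiomassComposition(config$composition)
    } else unlist(config$composition)
  })
  maintenance <- if (is.null(config$maintenance)) 0.1 else
    config$maintenance
  constraints <- stage("load",
    applyBiomassComposition(model, composition, maintenance))

  carbId <- config$carb_id %||% "chl_RuBisCO_carb"
  oxyId <- config$oxy_id %||% "chl_RuBisCO_oxy"
  photonId <- config$photon_id %||% "Photon_tx"
  cycId <- config$cyclic_id %||% "chl_LightCyc"
  noncycId <- config$noncyclic_id %||% "chl_LightNonCyc"

  manifest <- list(package_version =
                     as.character(utils::packageVersion("leafFBA")),
                   seed = seed, config = config)

  ## -- consistency -----------------------------------------------------
  if (!isFALSE(config$consistency)) {
    chk <- stage("consistency", {
      leaks <- findLeaks(model)
      cyc <- detectEnergyCycle(model)
      unb <- elementalBalanceAudit(model)
      list(leaks = leaks$leakingMetabolites,
           energy_cycle = cyc$hasCycle, unbalanced = unb)
    })
    jsonlite::write_json(chk, file.path(out, "consistency.json"),
                         auto_unbox = TRUE)
    if (length(chk$leaks) || isTRUE(chk$energy_cycle))
      stop("stage 'consistency' failed: model has leaks or an ",
           "energy-generating cycle", call. = FALSE)
  }

  writeTable <- function(df, name)
    utils::write.table(df, file.path(out, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  ## -- FBA + FVA at 1:1 and 3:1 ---------------------------------------
  scanIds <- NULL
  if (carbId %in% reactionIds(model)) {
    for (rt in list(c(1, 1), c(3, 1))) {
      lbl <- paste0(rt[1], "to", rt[2])
      lm <- stage("fba", lumpRubisco(model, carbId, oxyId, rt))
      sol <- stage("fba", minimizeWeightedFlux(lm, constraints))
      writeTable(data.frame(reaction_id = names(fluxes(sol)),
                            flux = unname(fluxes(sol))),
                 paste0("fba_vcvo_", lbl, ".tsv"))
      rng <- stage("fva", classifyFluxRanges(runFVA(lm, constraints)))
      writeTable(rng, paste0("fva_vcvo_", lbl, ".tsv"))
    }
  } else {
    sol <- stage("fba", minimizeWeightedFlux(model, constraints))
    writeTable(data.frame(reaction_id = names(fluxes(sol)),
                          flux = unname(fluxes(sol))), "fba.tsv")
    rng <- stage("fva", classifyFluxRanges(runFVA(model, constraints)))
    writeTable(rng, "fva.tsv")
  }

  ## -- scans -----------------------------------------------------------
  corVcvo <- corLight <- NULL
  if (!is.null(config$vcvo)) {
    ratios <- lapply(config$vcvo, .parseRatio)
    sc <- stage("scan-vcvo",
                vcvoScan(model, constraints, ratios, carbId, oxyId))
    fm <- fluxMatrix(sc)
    writeTable(data.frame(reaction_id = rownames(fm), fm,
                          check.names = FALSE), "scan_vcvo.tsv")
    corVcvo <- stage("correlate", correlateScan(sc))
  }
  if (!is.null(config$light)) {
    grid <- seq(config$light$from, config$light$to,
                by = config$light$step %||% 0.5)
    sc <- stage("scan-light",
                lightScan(model, constraints, grid, photonId,
                          cycId, noncycId))
    fm <- fluxMatrix(sc)
    writeTable(data.frame(reaction_id = rownames(fm), fm,
                          check.names = FALSE), "scan_light.tsv")
    corLight <- stage("correlate", correlateScan(sc))
  }
  for (nm in c("vcvo", "light")) {
    ct <- if (nm == "vcvo") corVcvo else corLight
    if (is.null(ct)) next
    cls <- classifyCorrelationStrength(ct)
    writeTable(data.frame(reaction_id = names(ct$entries),
                          abs_r = unname(ct$entries),
                          class = unname(cls)),
               paste0("correlation_", nm, ".tsv"))
  }

  ## -- ensemble --------------------------------------------------------
  if (!is.null(config$ensemble)) {
    en <- config$ensemble
    emodel <- model
    if (!is.null(en$fix_vcvo))
      emodel <- stage("ensemble",
                      lumpRubisco(model, carbId, oxyId,
                                  .parseRatio(en$fix_vcvo)))
    tracked <- if (is.character(en$tracked) && length(en$tracked) == 1 &&
                   startsWith(en$tracked, "preset:"))
      trackedPreset(emodel, sub("^preset:", "", en$tracked))
    else unlist(en$tracked)
    ms <- stage("ensemble",
                runEnsemble(emodel, constraints, n = en$n %||% 1000,
                            masterSeed = seed, tracked = tracked))
    writeTable(data.frame(signature = ms@signatures,
                          count = ms@counts,
                          frequency = ms@counts / ms@nIterations),
               "ensemble_modes.tsv")
    manifest$ensemble <- list(n = ms@nIterations,
                              infeasible = ms@infeasibleCount,
                              tracked = tracked)
  }

  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(out)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
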