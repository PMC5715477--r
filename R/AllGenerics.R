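#' @include AllClasses.R
NULL

#' Accessors for MetabolicModel and solution objects
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param object,x a [MetabolicModel-class], [FluxSolution-class] or
#'   [ScanResult-class] as appropriate.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(object, ...) standardGeneric("stoichiometricMatrix"))

#' @rdname accessors
#' @export
setGeneric("reactionBounds",
           function(object) standardGeneric("reactionBounds"))

#' @rdname accessors
#' @export
setGeneric("reactionCategories",
           function(object) standardGeneric("reactionCategories"))

#' @rdname accessors
#' @export
setGeneric("metaboliteCompartments",
           function(object) standardGeneric("metaboliteCompartments"))

#' @rdname accessors
#' @export
setGeneric("elementalCompositions",
           function(object) standardGeneric("elementalCompositions"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue",
           function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus",
           function(object) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("scanValues", function(object) standardGeneric("scanValues"))

#' @rdname accessors
#' @export
setGeneric("scanSolutions",
           function(object) standardGeneric("scanSolutions"))

#' @rdname accessors
#' @export
setGeneric("fluxMatrix", function(object, ...) standardGeneric("fluxMatrix"))

#' @rdname accessors
#' @export
setGeneric("modeCounts", function(object) standardGeneric("modeCounts"))
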