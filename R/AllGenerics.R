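#' @rdname CtTable-accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname CtTable-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname CtTable-accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname CtTable-accessors
#' @export
setGeneric("candidateNames", function(x) standardGeneric("candidateNames"))

#' @rdname stabilityValues
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname stabilityValues
#' @export
setGeneric("stabilityMethod", function(x) standardGeneric("stabilityMethod"))

#' @rdname RankVector-accessors
#' @export
setGeneric("rankValues", function(x) standardGeneric("rankValues"))

#' @rdname RankVector-accessors
#' @export
setGeneric("tieSets", function(x) standardGeneric("tieSets"))

#' @rdname ConsensusRanking-accessors
#' @export
setGeneric("consensusGeomean", function(x) standardGeneric("consensusGeomean"))

#' @rdname ConsensusRanking-accessors
#' @export
setGeneric("consensusDisplay", function(x) standardGeneric("consensusDisplay"))

#' @rdname ConsensusRanking-accessors
#' @export
setGeneric("finalOrder", function(x) standardGeneric("finalOrder"))

#' @rdname SimSpec-accessors
#' @export
setGeneric("trueDisorder", function(x) standardGeneric("trueDisorder"))
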