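#' @rdname MRExperiment-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname MRExperiment-accessors
#' @export
setGeneric("isTF", function(x) standardGeneric("isTF"))
#' @rdname MRExperiment-accessors
#' @export
setGeneric("caseLevel", function(x) standardGeneric("caseLevel"))
#' @rdname MRExperiment-accessors
#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))
#' @rdname MRExperiment-accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname differentialConnectivity
#' @export
setGeneric("differentialConnectivity",
           function(data) standardGeneric("differentialConnectivity"))
#' @rdname tfCorrelationMatrix
#' @export
setGeneric("tfCorrelationMatrix",
           function(data) standardGeneric("tfCorrelationMatrix"))
#' @rdname masterStatistic
#' @export
setGeneric("masterStatistic",
           function(object) standardGeneric("masterStatistic"))

#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("kPerTF", function(object) standardGeneric("kPerTF"))
#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("kMax", function(object) standardGeneric("kMax"))
#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("masterSet", function(object) standardGeneric("masterSet"))
#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("nBootstrap", function(object) standardGeneric("nBootstrap"))
#' @rdname MasterRegulatorResult-accessors
#' @export
setGeneric("bootstrapStats", function(object) standardGeneric("bootstrapStats"))

#' @rdname MonteCarloResult-accessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))
#' @rdname MonteCarloResult-accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
#' @rdname MonteCarloResult-accessors
#' @export
setGeneric("mcPValues", function(object) standardGeneric("mcPValues"))
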