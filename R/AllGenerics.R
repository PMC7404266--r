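#' @rdname derivePromoters
#' @export
setGeneric("derivePromoters", function(model, kind = c("proximal", "typical", "expanded"), ...)
  standardGeneric("derivePromoters"))

#' @rdname filterExpressed
#' @export
setGeneric("filterExpressed", function(x, mode = c("any_positive", "max_ge_one"))
  standardGeneric("filterExpressed"))

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x) standardGeneric("logTransform"))

#' @rdname tissueMeans
#' @export
setGeneric("tissueMeans", function(x, ...) standardGeneric("tissueMeans"))

#' @rdname sampleCorrelation
#' @export
setGeneric("sampleCorrelation", function(x, ...) standardGeneric("sampleCorrelation"))

#' @rdname TPMExperiment-accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname TPMExperiment-accessors
#' @export
setGeneric("tissues", function(x) standardGeneric("tissues"))

#' @rdname RegionMethExperiment-accessors
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname RegionMethExperiment-accessors
#' @export
setGeneric("nCpgs", function(x) standardGeneric("nCpgs"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("transcriptSummary", function(x) standardGeneric("transcriptSummary"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
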