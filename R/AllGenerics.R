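#' @import methods
NULL

#' Hydraulic diameter of a rectangular channel
#'
#' For a rectangular duct of width \eqn{W} and height \eqn{H} the hydraulic
#' diameter is \eqn{D_h = 2WH/(W+H)}. It is the length scale against which a
#' cell's undeformed diameter is normalised to give its confinement
#' \eqn{D_c/D_h}.
#'
#' @param object a [ChannelGeometry-class] object.
#' @return hydraulic diameter in micrometres (numeric scalar).
#' @examples
#' hydraulicDiameter(channelGeometry(widthUm = 18, heightUm = 19.8))
#' @export
setGeneric("hydraulicDiameter", function(object)
    standardGeneric("hydraulicDiameter"))

#' @rdname SamplePopulation-class
#' @param object a `SamplePopulation`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname SamplePopulation-class
#' @export
setGeneric("cellRecords", function(object) standardGeneric("cellRecords"))

#' @rdname SamplePopulation-class
#' @export
setGeneric("sampleMetadata", function(object) standardGeneric("sampleMetadata"))

#' @rdname SamplePopulation-class
#' @export
setGeneric("diMax", function(object) standardGeneric("diMax"))

#' Gate a population on confinement
#'
#' Retains only cells whose confinement \eqn{D_c/D_h} lies strictly inside
#' `(lo, hi)`. Deformation is negligible below the lower bound and cells risk
#' wall contact above the upper one, so population comparisons are run on this
#' window only. The gate bounds are recorded in the population metadata and the
#' operation is idempotent.
#'
#' @param object a [SamplePopulation-class].
#' @param lo,hi open-interval gate bounds on \eqn{D_c/D_h} (defaults 0.85 and
#'   0.95).
#' @return a gated `SamplePopulation`.
#' @export
setGeneric("confinementGate", function(object, lo = 0.85, hi = 0.95)
    standardGeneric("confinementGate"))

#' Five-quantile boxplot summary
#'
#' Median, quartiles and the 10th/90th percentiles (the whisker convention
#' used for deformability boxplots), using the linear-interpolation quantile
#' definition (`stats::quantile` type 7), plus the sample size. A warning is
#' emitted below n = 100, the floor used for population boxplots.
#'
#' @param object a [SamplePopulation-class] (summarises its gated `di_max`
#'   values) or a numeric vector.
#' @return named list with `median`, `q25`, `q75`, `p10`, `p90`, `n`.
#' @examples
#' boxplotSummary(1:9)
#' @export
setGeneric("boxplotSummary", function(object) standardGeneric("boxplotSummary"))
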