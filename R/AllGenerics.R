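#' Accessor generics
#'
#' Small family of accessor generics shared by the sampled-trace, event-list
#' and imaging classes. Accessors are the supported way to reach slot
#' contents.
#'
#' @param x an object of one of the package classes.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' @rdname accessors
#' @export
setGeneric("site", function(x) standardGeneric("site"))

#' @rdname accessors
#' @export
setGeneric("stateLabel", function(x) standardGeneric("stateLabel"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("siteOnsets", function(x) standardGeneric("siteOnsets"))

#' @rdname accessors
#' @export
setGeneric("stimulusTable", function(x) standardGeneric("stimulusTable"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameRateHz", function(x) standardGeneric("frameRateHz"))

#' @rdname accessors
#' @export
setGeneric("frameTimesS", function(x) standardGeneric("frameTimesS"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("latencies", function(x) standardGeneric("latencies"))

#' @rdname accessors
#' @export
setGeneric("speeds", function(x) standardGeneric("speeds"))

#' @rdname accessors
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Response latency estimation (generic)
#'
#' @param x a [PhotometryTrace-class] (events are detected internally for
#'   `mode = "swa_onset"`) or an [EventList-class].
#' @param ... passed to methods; see [responseLatencyTrace()].
#' @export
setGeneric("responseLatency", function(x, ...) standardGeneric("responseLatency"))

#' Response area (generic)
#'
#' @param x a stimulus-triggered average movie ([CalciumMovie-class]) or a
#'   [LatencyMap-class].
#' @param ... passed to methods; see [responseAreaStack()].
#' @export
setGeneric("responseArea", function(x, ...) standardGeneric("responseArea"))
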