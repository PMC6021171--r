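#' @name plugdyn-generics
#' @title Accessor generics for plugdyn data containers
#' @description Small accessor generics used across the package's S4
#'   containers, in place of direct slot access.
#' @param object a plugdyn S4 object
#' @return The accessed component; see the methods on each class.
NULL

#' @rdname plugdyn-generics
#' @export
setGeneric("photonData", function(object) standardGeneric("photonData"))

#' @rdname plugdyn-generics
#' @export
setGeneric("nPhotons", function(object) standardGeneric("nPhotons"))

#' @rdname plugdyn-generics
#' @export
setGeneric("clockRate", function(object) standardGeneric("clockRate"))

#' @rdname plugdyn-generics
#' @export
setGeneric("alternationPeriod",
           function(object) standardGeneric("alternationPeriod"))

#' @rdname plugdyn-generics
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname plugdyn-generics
#' @export
setGeneric("burstData", function(object) standardGeneric("burstData"))

#' @rdname plugdyn-generics
#' @export
setGeneric("nBursts", function(object) standardGeneric("nBursts"))

#' @rdname plugdyn-generics
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))

#' @rdname plugdyn-generics
#' @export
setGeneric("framePeriod", function(object) standardGeneric("framePeriod"))

#' @rdname plugdyn-generics
#' @export
setGeneric("traceIds", function(object) standardGeneric("traceIds"))

#' @rdname plugdyn-generics
#' @export
setGeneric("avPositions", function(object) standardGeneric("avPositions"))
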