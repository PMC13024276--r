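#' Accessors for ParticleTable and BinaryMask
#'
#' \code{particleData} returns the per-particle property data.frame,
#' \code{runName} the sample run name, \code{dialect} the detected
#' [VspDialect-class], \code{nParticles} the row count; \code{maskPixels}
#' the logical matrix of a mask, \code{pixelSize} its micrometre-per-pixel
#' scale and \code{maskArea} its foreground pixel count.
#'
#' @param x a [ParticleTable-class] or [BinaryMask-class]
#' @return see each accessor's description
#' @examples
#' tab <- exampleParticleTable()
#' nParticles(tab)
#' head(particleData(tab))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("particleData", function(x) standardGeneric("particleData"))
#' @rdname accessors
#' @export
setGeneric("runName", function(x) standardGeneric("runName"))
#' @rdname accessors
#' @export
setGeneric("dialect", function(x) standardGeneric("dialect"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname accessors
#' @export
setMethod("particleData", "ParticleTable", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("runName", "ParticleTable", function(x) x@runName)
#' @rdname accessors
#' @export
setMethod("dialect", "ParticleTable", function(x) x@dialect)
#' @rdname accessors
#' @export
setMethod("nParticles", "ParticleTable", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("maskArea", "BinaryMask", function(x) sum(x@pixels))
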