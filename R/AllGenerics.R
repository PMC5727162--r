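#' Accessors for OrigamiDesign and result objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object an object of the corresponding class.
#' @return `stapleSet()` the staple data.frame; `modulePartition()` the module
#'   data.frame; `designSeams()` the seam data.frame; `helixLayout()` the
#'   bundle helix layout (the adjuster pseudo-helix excluded);
#'   `adjusterState()` the adjuster list; `scaffoldUsage()` the total number
#'   of scaffold bases the design occupies; `heights()` the numeric height
#'   matrix; `pixelSize()` nm per pixel.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stapleSet", function(object) standardGeneric("stapleSet"))
#' @rdname accessors
#' @export
setGeneric("modulePartition", function(object) standardGeneric("modulePartition"))
#' @rdname accessors
#' @export
setGeneric("designSeams", function(object) standardGeneric("designSeams"))
#' @rdname accessors
#' @export
setGeneric("helixLayout", function(object) standardGeneric("helixLayout"))
#' @rdname accessors
#' @export
setGeneric("adjusterState", function(object) standardGeneric("adjusterState"))
#' @rdname accessors
#' @export
setGeneric("scaffoldUsage", function(object) standardGeneric("scaffoldUsage"))
#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("stapleSet", "OrigamiDesign", function(object) object@staples)
#' @rdname accessors
#' @export
setMethod("modulePartition", "OrigamiDesign", function(object) object@partition)
#' @rdname accessors
#' @export
setMethod("designSeams", "OrigamiDesign", function(object) object@seams)
#' @rdname accessors
#' @export
setMethod("helixLayout", "OrigamiDesign", function(object)
    object@layout[!object@layout$is_adjuster, , drop = FALSE])
#' @rdname accessors
#' @export
setMethod("adjusterState", "OrigamiDesign", function(object) object@adjuster)

#' @rdname accessors
#' @export
setMethod("scaffoldUsage", "OrigamiDesign", function(object) {
    lay <- object@layout[!object@layout$is_adjuster, , drop = FALSE]
    sum(lay$length_nt) + object@adjuster$full_length_nt
})

#' @rdname accessors
#' @export
setMethod("heights", "HeightMap", function(object) object@heights)
#' @rdname accessors
#' @export
setMethod("pixelSize", "HeightMap", function(object) object@pixel_size)
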