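#' @name foldconn-accessors
#' @title Accessor generics for foldconn classes
#' @description Slot access for the core data containers goes through these
#'   accessors; user code should never reach into slots directly.
#' @param x an object of the documented class.
#' @keywords internal
NULL

#' @rdname foldconn-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname foldconn-accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname foldconn-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname foldconn-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname foldconn-accessors
#' @export
setGeneric("mapUnits", function(x) standardGeneric("mapUnits"))
#' @rdname foldconn-accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))
#' @rdname foldconn-accessors
#' @export
setGeneric("tensorData", function(x) standardGeneric("tensorData"))
#' @rdname foldconn-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname foldconn-accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname foldconn-accessors
#' @export
setGeneric("streamlineLengths", function(x) standardGeneric("streamlineLengths"))
#' @rdname foldconn-accessors
#' @export
setGeneric("streamlineMetrics", function(x) standardGeneric("streamlineMetrics"))
#' @rdname foldconn-accessors
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))
#' @rdname foldconn-accessors
#' @export
setGeneric("clusterVertices", function(x) standardGeneric("clusterVertices"))
#' @rdname foldconn-accessors
#' @export
setGeneric("clusterP", function(x) standardGeneric("clusterP"))

setMethod("vertices", "TriSurface", function(x) x@vertices)
setMethod("triangles", "TriSurface", function(x) x@triangles)
setMethod("nVertices", "TriSurface", function(x) nrow(x@vertices))
setMethod("mapValues", "ScalarMap", function(x) x@values)
setMethod("mapUnits", "ScalarMap", function(x) x@units)
setMethod("affine", "TensorVolume", function(x) x@affine)
setMethod("affine", "VoxelMask", function(x) x@affine)
setMethod("tensorData", "TensorVolume", function(x) x@data)
setMethod("maskArray", "VoxelMask", function(x) x@mask)
setMethod("streamlines", "StreamlineSet", function(x) x@points)
setMethod("streamlineLengths", "StreamlineSet", function(x) x@lengths)
setMethod("streamlineMetrics", "StreamlineSet", function(x) x@metrics)
setMethod("nStreamlines", "StreamlineSet", function(x) length(x@points))
setMethod("clusterVertices", "ClusterResult", function(x) x@vertices)
setMethod("clusterP", "ClusterResult", function(x) x@p)

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d vertices, %d triangles, total area %.1f mm^2\n",
              nrow(object@vertices), nrow(object@triangles),
              sum(triangleAreas(object@vertices, object@triangles))))
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values
  cat(sprintf("ScalarMap [%s]: %d vertices, range [%.4g, %.4g], %d NA\n",
              if (nzchar(object@units)) object@units else "dimensionless",
              length(v), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "TensorVolume", function(object) {
  d <- dim(object@data)
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("TensorVolume: %d x %d x %d voxels of %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
})

setMethod("show", "StreamlineSet", function(object) {
  n <- length(object@points)
  if (n == 0) { cat("StreamlineSet: empty\n"); return(invisible(NULL)) }
  cat(sprintf("StreamlineSet: %d streamlines, length %.1f-%.1f mm (median %.1f)%s\n",
              n, min(object@lengths), max(object@lengths),
              median(object@lengths),
              if (nrow(object@metrics)) ", metrics attached" else ""))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask: %s grid, %d voxels set\n",
              paste(dim(object@mask), collapse = " x "), sum(object@mask)))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: k = %d, logLik = %.2f\n", object@k, object@logLik))
  print(data.frame(weight = round(object@weights, 4),
                   mean_mm = round(object@means, 2),
                   sd_mm = round(object@sds, 2)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d vertices, peak t = %.2f at vertex %d, area %.1f mm^2, p = %.4g\n",
    length(object@vertices), object@peakT, object@peakVertex,
    object@areaMM2, object@p))
})
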