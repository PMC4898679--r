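#' @import methods
#' @importFrom stats approx coef complete.cases cor dist dnorm ecdf kmeans lm
#'   median model.matrix pchisq pf pnorm pt qnorm qt quantile resid rnorm
#'   runif sd setNames var weighted.mean
#' @importFrom utils head modifyList read.delim tail write.table
NULL

#' Triangulated surface mesh
#'
#' Carrier of pial, white and outer-hull cortical geometry: vertex positions
#' in millimetres and 1-based triangle index triples.  Validity enforces
#' index bounds and non-degenerate (positive-area) triangles; closedness and
#' manifoldness are checked by [isClosedManifold()] where an operation
#' requires them (a full half-edge audit is too costly to run on every
#' object construction).
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot triangles integer matrix, one row per triangle, 1-based vertex ids.
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", triangles = "matrix"))

setValidity("TriSurface", function(object) {
  v <- object@vertices; f <- object@triangles
  if (ncol(v) != 3L) return("vertices must have 3 columns (x, y, z in mm)")
  if (ncol(f) != 3L) return("triangles must have 3 columns")
  if (!all(is.finite(v))) return("non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) return("triangle index out of range")
    a <- triangleAreas(v, f)
    if (any(a <= 0)) return("degenerate triangle (area <= 0)")
  }
  TRUE
})

#' Per-vertex scalar map
#'
#' One real value per surface vertex with a named unit ("" for the
#' dimensionless local gyrification index, "mm^2" for area, "mm" for
#' thickness and depth, "1/mm" for curvature, "t" for test statistics).
#' Non-finite values are permitted only as explicit `NA` (degenerate
#' vertices are flagged, never silently dropped).
#'
#' @slot values numeric vector, one per vertex.
#' @slot units single character string naming the unit.
#' @export
setClass("ScalarMap", representation(values = "numeric", units = "character"))

setValidity("ScalarMap", function(object) {
  if (length(object@units) != 1L) return("units must be a single string")
  if (any(is.nan(object@values) | is.infinite(object@values)))
    return("values must be finite or NA")
  TRUE
})

#' Voxel grid of symmetric diffusion tensors
#'
#' A 4-D array `(nx, ny, nz, 6)` holding the unique tensor elements in
#' lower-triangular order (dxx, dxy, dyy, dxz, dyz, dzz; mm^2/s), plus the
#' 4x4 voxel-to-world (RAS mm) affine.  Voxel indices are 0-based in the
#' affine convention: world = A %*% c(i, j, k, 1).
#'
#' @slot data numeric 4-D array, last dimension of length 6.
#' @slot affine numeric 4x4 voxel-to-world matrix.
#' @export
setClass("TensorVolume", representation(data = "array", affine = "matrix"))

setValidity("TensorVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 6L)
    return("data must be (nx, ny, nz, 6) with lower-triangular tensor order")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine[1:3, 1:3])) < 1e-12) return("singular affine")
  TRUE
})

#' Set of tractography streamlines
#'
#' Polylines in world millimetres with per-streamline arc length and
#' (optionally) mean tensor metrics sampled along the line.
#'
#' @slot points list of numeric matrices (n_points x 3, world mm).
#' @slot lengths numeric vector of polyline arc lengths (mm).
#' @slot metrics data.frame with columns fa, md, ad, rd (one row per
#'   streamline) or a zero-row placeholder before metrics are attached.
#' @export
setClass("StreamlineSet",
  representation(points = "list", lengths = "numeric", metrics = "data.frame"))

setValidity("StreamlineSet", function(object) {
  n <- length(object@points)
  if (length(object@lengths) != n) return("lengths must match streamline count")
  if (nrow(object@metrics) && nrow(object@metrics) != n)
    return("metrics rows must match streamline count")
  ok <- vapply(object@points, function(p)
    is.matrix(p) && ncol(p) == 3L && all(is.finite(p)), logical(1))
  if (n && !all(ok)) return("each streamline must be a finite n x 3 matrix")
  TRUE
})

#' Boolean voxel mask aligned to a tensor grid
#'
#' @slot mask logical 3-D array.
#' @slot affine numeric 4x4 voxel-to-world matrix (shared with the volume).
#' @export
setClass("VoxelMask", representation(mask = "array", affine = "matrix"))

setValidity("VoxelMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3-D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Univariate Gaussian mixture model of streamline lengths
#'
#' @slot k integer component count.
#' @slot weights mixing proportions, positive, summing to one.
#' @slot means component means (mm), sorted ascending.
#' @slot sds component standard deviations (mm), all positive.
#' @slot logLik maximized log-likelihood of the fit.
#' @export
setClass("MixtureModel",
  representation(k = "integer", weights = "numeric", means = "numeric",
                 sds = "numeric", logLik = "numeric"))

setValidity("MixtureModel", function(object) {
  k <- object@k
  if (length(object@weights) != k || length(object@means) != k ||
      length(object@sds) != k) return("parameter lengths must equal k")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (is.unsorted(object@means)) return("means must be sorted ascending")
  TRUE
})

#' Suprathreshold cluster on a surface
#'
#' A connected component of suprathreshold vertices from a vertex-wise
#' statistical map, with its peak statistic, corrected cluster p-value,
#' surface area and resel extent.
#'
#' @slot vertices integer vertex ids forming the cluster.
#' @slot peakT peak t-value (signed).
#' @slot peakVertex vertex id of the peak.
#' @slot p corrected cluster p-value.
#' @slot areaMM2 cluster surface area in mm^2.
#' @slot resels cluster extent in resels (local-FWHM-warped area).
#' @slot sign +1 or -1, the tail the cluster belongs to.
#' @export
setClass("ClusterResult",
  representation(vertices = "integer", peakT = "numeric",
                 peakVertex = "integer", p = "numeric",
                 areaMM2 = "numeric", resels = "numeric", sign = "numeric"))

setValidity("ClusterResult", function(object) {
  if (length(object@vertices) < 1L) return("cluster must contain vertices")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})
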