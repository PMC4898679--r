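#' Specification of a synthetic folded cortical surface
#'
#' Describes a radially folded sphere: a smooth base sphere carrying
#' concentric sinusoidal folds (sulci cut inward from the sphere) confined
#' to a circular patch around `patch_center`.  The fold crests always reach
#' the base sphere, so the outer envelope of the folded surface is the base
#' sphere itself - which makes the analytic outer hull of the synthetic
#' geometry known exactly.
#'
#' @param base_radius sphere radius in mm.
#' @param fold_amplitude peak sulcal depth in mm (>= 0).
#' @param fold_frequency fold density in cycles per radian of angular
#'   distance from the patch centre.
#' @param patch_center unit 3-vector; the folding patch is centred on this
#'   direction.
#' @param patch_width angular half-width of the patch in radians, in (0, pi).
#' @param subdivision_level icosphere subdivision level (>= 2).
#' @param thickness inward offset of the white surface along vertex normals
#'   (mm).
#' @param phase_jitter_sd SD of the random fold phase jitter (radians) drawn
#'   per surface; models inter-individual variation in folding pattern.
#' @return a `FoldSpec` (classed list).
#' @export
foldSpec <- function(base_radius = 30, fold_amplitude = 3,
                     fold_frequency = 4, patch_center = c(0.8, 0.55, 0.2),
                     patch_width = 0.9, subdivision_level = 4L,
                     thickness = 2.5, phase_jitter_sd = 0.2) {
  stopifnot(base_radius > 0, fold_amplitude >= 0, fold_frequency > 0,
            patch_width > 0, patch_width < pi, subdivision_level >= 2,
            thickness >= 0)
  pc <- patch_center / sqrt(sum(patch_center^2))
  structure(list(base_radius = base_radius, fold_amplitude = fold_amplitude,
                 fold_frequency = fold_frequency, patch_center = pc,
                 patch_width = patch_width,
                 subdivision_level = as.integer(subdivision_level),
                 thickness = thickness, phase_jitter_sd = phase_jitter_sd),
            class = "FoldSpec")
}

# windowed fold field p(alpha) in [0, 1]; alpha = angle from patch centre.
# Crests (p = 0) reach the base sphere regardless of the window, sulcal
# floors follow the squared-cosine window.
foldField <- function(alpha, width, freq, phase = 0) {
  w <- ifelse(alpha < width, cos(pi * alpha / (2 * width))^2, 0)
  w * 0.5 * (1 + cos(2 * pi * freq * alpha + phase))
}

#' Generate a folded pial/white surface pair
#'
#' The pial surface is an icosphere perturbed radially inward by windowed
#' concentric sinusoidal folds (see [foldSpec()]); the white surface is the
#' pial offset inward along the vertex normals by the spec thickness.  With
#' `fold_amplitude = 0` the pial surface is the base sphere.  The output is
#' rejected if the perturbation breaks star-shapedness (the mesh would
#' self-intersect).
#'
#' @param spec a [foldSpec()].
#' @param seed integer seed controlling the fold phase jitter; identical
#'   spec + seed give bit-identical surfaces.
#' @return list with elements `pial` and `white`, both [TriSurface-class].
#' @export
generateFoldedSurface <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "FoldSpec"))
  base <- icosphere(spec$subdivision_level, radius = 1)
  dirs <- vertices(base)
  alpha <- acos(pmin(1, pmax(-1, drop(dirs %*% spec$patch_center))))
  phase <- withSeed(seed, {
    rnorm(1, 0, spec$phase_jitter_sd)
  })
  p <- foldField(alpha, spec$patch_width, spec$fold_frequency, phase)
  r <- spec$base_radius - spec$fold_amplitude * p
  if (any(r <= 0))
    stop("fold_amplitude too large: radius becomes non-positive")
  pial <- triSurface(dirs * r, triangles(base))
  # star-shapedness check: all tetrahedra (origin, triangle) positively
  # oriented; violation means radial folds self-intersect
  f <- triangles(pial); v <- vertices(pial)
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; c3 <- v[f[, 3], ]
  vol <- rowSums(a * cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
                           b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
                           b[, 1] * c3[, 2] - b[, 2] * c3[, 1]))
  if (any(vol <= 0))
    stop("self-intersecting fold geometry: reduce fold_amplitude or ",
         "fold_frequency (amplitude x frequency too large for base_radius)")
  nrm <- vertexNormals(pial)
  white <- triSurface(v - spec$thickness * nrm, f)
  # the inward offset self-intersects once the thickness exceeds the local
  # curvature radius of the sulcal floors: flipped white normals betray it
  nw <- vertexNormals(white)
  flipped <- mean(rowSums(nrm * nw) < 0)
  # isolated flips at the sharpest sulcal floors are tolerated; a larger
  # fraction means the offset genuinely folds through itself
  if (flipped > 0.025)
    stop("self-intersecting white surface (", round(100 * flipped, 1),
         "% flipped normals): fold amplitude x frequency too large for ",
         "the requested thickness")
  list(pial = pial, white = white)
}

# evaluate an expression under a temporary RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  expr
}
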