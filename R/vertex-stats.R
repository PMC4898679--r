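#' Vertex-wise general linear model
#'
#' Fits `Y_v = X b + e` by ordinary least squares independently at every
#' vertex and returns the t-statistic of one coefficient (the group effect
#' in the two-group design: intercept, group, center, age, FSIQ), together
#' with the residuals needed for smoothness estimation.
#'
#' @param Y numeric matrix, vertices x subjects.
#' @param X design matrix, subjects x predictors (must include an
#'   intercept column; full column rank).
#' @param coef name or index of the tested coefficient (default "group").
#' @return list with `t` ([ScalarMap-class]; NA at degenerate vertices with
#'   zero residual variance), `beta` (V x p), `residuals` (V x n), `df`,
#'   `se`.
#' @export
fitVertexGLM <- function(Y, X, coef = "group") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (ncol(Y) != n) stop("Y must be vertices x subjects, matching the design")
  if (n < p + 2) stop("need at least ", p + 2, " subjects for ", p,
                      " design columns")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  j <- if (is.character(coef)) match(coef, colnames(X)) else as.integer(coef)
  if (is.na(j)) stop("coefficient '", coef, "' not found in the design")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% XtXinv                   # V x p coefficients
  R <- Y - tcrossprod(B, X)                 # V x n residuals
  df <- n - p
  sigma2 <- rowSums(R^2) / df
  se <- sqrt(sigma2 * XtXinv[j, j])
  t <- B[, j] / se
  # degenerate vertices (residual variance at numerical zero) are flagged
  t[sigma2 <= 1e-14 * (rowMeans(Y^2) + .Machine$double.xmin)] <- NA
  list(t = scalarMap(t, "t"), beta = B, residuals = R, df = df, se = se)
}

# edge resls (squared resel-space edge lengths) from normalized residuals:
# the standard surface smoothness estimator
edgeResl <- function(surface, residuals) {
  e <- meshEdges(surface)
  nrm <- sqrt(rowSums(residuals^2))
  nrm[nrm == 0] <- Inf                      # degenerate vertices: no gradient
  U <- residuals / nrm
  resl <- rowSums((U[e[, 1], , drop = FALSE] - U[e[, 2], , drop = FALSE])^2)
  list(edges = e, resl = resl)
}

# per-triangle and per-vertex resel areas; triangle area in resel space by
# Heron's formula on resl edge lengths, scaled by (4 log 2)^-1
reselAreas <- function(surface, residuals) {
  er <- edgeResl(surface, residuals)
  f <- triangles(surface)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- setNames(er$resl, key(er$edges[, 1], er$edges[, 2]))
  l1 <- sqrt(lut[key(f[, 1], f[, 2])])
  l2 <- sqrt(lut[key(f[, 2], f[, 3])])
  l3 <- sqrt(lut[key(f[, 3], f[, 1])])
  s <- (l1 + l2 + l3) / 2
  h2 <- pmax(s * (s - l1) * (s - l2) * (s - l3), 0)
  triResel <- sqrt(h2) / (4 * log(2))
  nv <- nVertices(surface)
  vr <- numeric(nv)
  for (k in 1:3) {
    acc <- rowsum(triResel, f[, k])
    idx <- as.integer(rownames(acc))
    vr[idx] <- vr[idx] + acc[, 1] / 3
  }
  list(triResel = triResel, vertexResel = vr, total = sum(triResel))
}

# connected components of a vertex subset on the mesh graph
vertexComponents <- function(surface, idx) {
  if (!length(idx)) return(list())
  e <- meshEdges(surface)
  keep <- e[, 1] %in% idx & e[, 2] %in% idx
  g <- igraph::graph_from_edgelist(cbind(match(e[keep, 1], idx),
                                         match(e[keep, 2], idx)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) idx[comp$membership == ci])
}

# 2-D Euler characteristic densities of a t field (unit-FWHM resel units)
tFieldEC <- function(u, df) {
  rho0 <- pt(u, df, lower.tail = FALSE)
  rho2 <- (4 * log(2)) * (2 * pi)^(-1.5) *
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) *
    u * (1 + u^2 / df)^(-(df - 1) / 2)
  list(rho0 = rho0, rho2 = rho2)
}

#' Random-field-theory cluster correction on a surface
#'
#' Thresholds the t-map at the cluster-forming quantile, finds connected
#' components on the mesh, and assigns each cluster a family-wise corrected
#' p-value from the expected-cluster formulas of random field theory for
#' t fields.  Non-isotropic smoothness is handled by measuring cluster
#' extent in resels: residual-normalized gradients give each edge a length
#' in resel space, triangle areas follow by Heron's formula, so regions of
#' rough noise count as larger extent.  For a closed surface the resel
#' counts are (L0, L1, L2) = (2, 0, total resel area).
#'
#' @param tmap [ScalarMap-class] of t-values.
#' @param residuals V x n residual matrix from [fitVertexGLM()].
#' @param surface the [TriSurface-class] carrying the maps.
#' @param df error degrees of freedom.
#' @param clusterFormingP vertex-wise p-value forming clusters (default
#'   0.001; two-tailed when `twoTailed`).
#' @param clusterAlpha corrected cluster significance threshold (default
#'   0.05); clusters above it are still returned (use `clusterP()` to
#'   filter), flagged in `significant`.
#' @param twoTailed test both signs (default TRUE); cluster p-values are
#'   then doubled.
#' @return list with `clusters` (list of [ClusterResult-class], sorted by
#'   p), `significant` (logical), `threshold` (t units), `resels`,
#'   `fwhmMm` (average smoothness).
#' @export
rftClusterCorrect <- function(tmap, residuals, surface, df,
                              clusterFormingP = 0.001, clusterAlpha = 0.05,
                              twoTailed = TRUE) {
  tv <- mapValues(tmap)
  pf <- if (twoTailed) clusterFormingP / 2 else clusterFormingP
  u <- qt(pf, df, lower.tail = FALSE)
  ra <- reselAreas(surface, residuals)
  av <- mapValues(vertexArea(surface))
  # average FWHM (mm): total area / resel area = FWHM^2
  fwhm <- sqrt(sum(av) / max(ra$total, .Machine$double.eps))
  ec <- tFieldEC(u, df)
  Em <- 2 * ec$rho0 + ra$total * ec$rho2    # expected clusters, one tail
  EN <- ra$total * ec$rho0                  # expected suprathreshold resels
  beta <- if (EN > 0) Em / EN else Inf
  mkClusters <- function(idx, sgn) {
    comps <- vertexComponents(surface, idx)
    lapply(comps, function(vs) {
      s <- sum(ra$vertexResel[vs])
      pclu <- 1 - exp(-Em * exp(-beta * s))
      if (!is.finite(pclu)) pclu <- 1   # degenerate forming threshold
      if (twoTailed) pclu <- min(1, 2 * pclu)
      pk <- vs[which.max(abs(tv[vs]))]
      new("ClusterResult", vertices = as.integer(vs), peakT = tv[pk],
          peakVertex = as.integer(pk), p = pclu, areaMM2 = sum(av[vs]),
          resels = s, sign = sgn)
    })
  }
  pos <- which(!is.na(tv) & tv >= u)
  cl <- mkClusters(pos, 1)
  if (twoTailed) {
    neg <- which(!is.na(tv) & tv <= -u)
    cl <- c(cl, mkClusters(neg, -1))
  }
  ord <- order(vapply(cl, function(x) x@p, numeric(1)))
  cl <- cl[ord]
  list(clusters = cl,
       significant = vapply(cl, function(x) x@p < clusterAlpha, logical(1)),
       threshold = u, resels = ra$total, fwhmMm = fwhm)
}

#' Permutation oracle for cluster inference
#'
#' Maximum-cluster-extent permutation test: group labels are shuffled
#' within center strata, the vertex GLM is refitted, and the maximal
#' suprathreshold cluster resel extent (from that permutation's own
#' residual smoothness) builds the null distribution.  Used to validate
#' the parametric RFT p-values.
#'
#' @param Y vertices x subjects matrix.
#' @param group 0/1 vector.
#' @param center factor-like vector of acquisition centers (permutation
#'   strata).
#' @param covars optional data.frame of additional covariates (age, FSIQ).
#' @param surface the [TriSurface-class].
#' @param nPerm number of permutations (>= 500).
#' @param seed integer seed.
#' @param clusterFormingP vertex-wise forming threshold (two-tailed when
#'   `twoTailed`).
#' @param twoTailed cluster on |t| with sign split (default TRUE).
#' @return data.frame with one row per observed cluster: peak t, resel
#'   extent, permutation p; plus attribute `nullMax` (the permutation
#'   distribution).
#' @export
permutationClusterOracle <- function(Y, group, center, covars = NULL, surface,
                                     nPerm = 1000L, seed = 1L,
                                     clusterFormingP = 0.001,
                                     twoTailed = TRUE) {
  if (nPerm < 500L) stop("use at least 500 permutations")
  buildX <- function(g) {
    df <- data.frame(group = g, center = factor(center))
    if (!is.null(covars)) df <- cbind(df, covars)
    model.matrix(~ ., df)
  }
  maxExtent <- function(g) {
    X <- buildX(g)
    fit <- fitVertexGLM(Y, X, coef = 2L)
    tv <- mapValues(fit$t)
    pf <- if (twoTailed) clusterFormingP / 2 else clusterFormingP
    u <- qt(pf, fit$df, lower.tail = FALSE)
    ra <- reselAreas(surface, fit$residuals)
    idx <- if (twoTailed) which(!is.na(tv) & abs(tv) >= u) else
      which(!is.na(tv) & tv >= u)
    if (!length(idx)) return(list(max = 0, fit = fit, ra = ra, u = u))
    # split |t| clusters by sign so opposite-signed patches never merge
    ext <- c(0)
    for (sgn in if (twoTailed) c(1, -1) else 1) {
      sel <- idx[sign(tv[idx]) == sgn]
      comps <- vertexComponents(surface, sel)
      ext <- c(ext, vapply(comps, function(vs) sum(ra$vertexResel[vs]),
                           numeric(1)))
    }
    list(max = max(ext), fit = fit, ra = ra, u = u,
         idx = idx)
  }
  obs <- maxExtent(group)
  tv <- mapValues(obs$fit$t)
  obsClusters <- list()
  for (sgn in if (twoTailed) c(1, -1) else 1) {
    sel <- obs$idx[sign(tv[obs$idx]) == sgn]
    if (length(sel))
      obsClusters <- c(obsClusters, vertexComponents(surface, sel))
  }
  obsExt <- vapply(obsClusters, function(vs) sum(obs$ra$vertexResel[vs]),
                   numeric(1))
  nullMax <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      g <- group
      for (lv in unique(center)) {
        sel <- which(center == lv)
        g[sel] <- g[sel][sample.int(length(sel))]
      }
      maxExtent(g)$max
    }, numeric(1))
  })
  p <- vapply(obsExt, function(s) (1 + sum(nullMax >= s)) / (nPerm + 1),
              numeric(1))
  out <- data.frame(
    peakT = vapply(obsClusters, function(vs) tv[vs[which.max(abs(tv[vs]))]],
                   numeric(1)),
    resels = obsExt, pPerm = p)
  attr(out, "nullMax") <- nullMax
  attr(out, "clusters") <- obsClusters
  out
}

#' Extract and mirror cluster ROIs
#'
#' `extractClusterROI` returns the vertex ids of a cluster;
#' `mirrorCluster` maps them to the contralateral homolog through a
#' left/right vertex correspondence (see [mirrorCorrespondence()]),
#' giving the control ROI.  Mirroring is an involution and preserves
#' cardinality (hence area, under exact mesh symmetry).
#'
#' @param cluster a [ClusterResult-class].
#' @param surface the carrier [TriSurface-class] (bounds check).
#' @return integer vertex ids.
#' @export
extractClusterROI <- function(cluster, surface) {
  vs <- cluster@vertices
  if (max(vs) > nVertices(surface))
    stop("cluster vertices outside the surface")
  vs
}

#' @rdname extractClusterROI
#' @param correspondence integer vector from [mirrorCorrespondence()].
#' @export
mirrorCluster <- function(cluster, correspondence) {
  if (max(cluster@vertices) > length(correspondence))
    stop("missing correspondence for cluster vertices")
  as.integer(correspondence[cluster@vertices])
}
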