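#' Default pipeline configuration
#'
#' Returns the full nested configuration of the end-to-end synthetic
#' analysis: cohort generation, surface synthesis, morphometry, vertex
#' statistics, tractography, length-mixture classification and coupling
#' statistics.  Values can be overridden through a YAML file
#' ([loadPipelineConfig()]) or an override list; unknown keys are
#' rejected.
#'
#' @param overrides named nested list of overrides.
#' @return a `PipelineConfig` (classed nested list).
#' @export
pipelineConfig <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    cohort = as.list(unclass(cohortSpec())),
    surface = list(
      base_radius = 40, fold_frequency = 4,
      patch_center = c(0.8, 0.55, 0.2), patch_width = 0.9,
      subdivision_level = 4L, thickness = 2.5, phase_jitter_sd = 0.15,
      amplitude_grid = c(0.5, 2, 3.5, 5, 6.5, 8)),
    morphometry = list(
      lgi_radius = 10, closing_diameter = 15, smoothing_fwhm = 5),
    volume = list(shape = c(48L, 48L, 48L), voxel_size = 2),
    bundles = list(
      u_span_deg = 32, u_depth = 6, u_radius = 2.5,
      long_target_deg = 130, long_offset_deg = 24, long_radius = 3),
    tracking = list(fa_threshold = 0.2, angle_max_deg = 35, step_mm = 1,
                    min_len_mm = 20),
    roi = list(band = 1.5),
    mixture = list(k_range = 1:4, gain_threshold = 0.01, n_splits = 3L,
                   n_restarts = 2L, dip_n_boot = 1000L, upper_mm = 150,
                   fallback_cutoff = 30, max_n = 12000L),
    stats = list(cluster_forming_p = 0.001, cluster_alpha = 0.05,
                 alpha = 0.05, n_tests = 8L, two_tailed = TRUE)
  )
  mergeConfig(cfg, overrides)
}

# recursive merge with unknown-key rejection
mergeConfig <- function(base, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", path, nm)
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- mergeConfig(base[[nm]], over[[nm]], paste0(path, nm, "."))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file of overrides.
#' @export
loadPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

# orthonormal tangent frame of the patch centre direction
patchFrame <- function(pc) {
  pc <- pc / sqrt(sum(pc^2))
  a <- if (abs(pc[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- a - sum(a * pc) * pc
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pc[2] * e1[3] - pc[3] * e1[2], pc[3] * e1[1] - pc[1] * e1[3],
          pc[1] * e1[2] - pc[2] * e1[1])
  list(n = pc, e1 = e1, e2 = e2)
}

# subject bundle set: a short U-fiber under the folding patch, a long
# straight bundle from the patch into the depth, and their mirrored
# control copies (with the subject's null control diffusivities) on the
# contralateral side.  Endpoints are anchored to the subject's own white
# surface (the nearest white vertex along each anchor direction, pulled
# 1 mm inward), so tract terminations follow the folded sheet and ROI
# capture does not depend on the subject's folding amplitude.
subjectBundles <- function(cfg, white, adShort, adLong, rdShort, rdLong,
                           adShortCtl, adLongCtl) {
  s <- cfg$surface; b <- cfg$bundles
  fr <- patchFrame(s$patch_center)
  wv <- vertices(white)
  anchor <- function(dir) {
    i <- which.max(wv %*% dir)
    p <- wv[i, ]
    p * (1 - 1 / sqrt(sum(p^2)))
  }
  mk <- function(p) { m <- p; m[1] <- -m[1]; m }
  half <- (b$u_span_deg / 2) * pi / 180
  d0 <- cos(half) * fr$n - sin(half) * fr$e1
  d1 <- cos(half) * fr$n + sin(half) * fr$e1
  off <- b$long_offset_deg * pi / 180
  dl0 <- cos(off) * fr$n - sin(off) * fr$e2
  dl1 <- cos(b$long_target_deg * pi / 180) * fr$n +
    sin(b$long_target_deg * pi / 180) * fr$e2
  uB <- function(da, db, ev) {
    ea <- anchor(da); eb <- anchor(db)
    nmid <- (da + db); nmid <- nmid / sqrt(sum(nmid^2))
    apex <- ((sqrt(sum(ea^2)) + sqrt(sum(eb^2))) / 2 - b$u_depth) * nmid
    bundleSpec("u_shaped", rbind(ea, apex, eb),
               crossSectionRadius = b$u_radius, eigenvalues = ev)
  }
  lB <- function(da, db, ev) {
    bundleSpec("straight", rbind(anchor(da), anchor(db)),
               crossSectionRadius = b$long_radius, eigenvalues = ev)
  }
  list(
    roiShort = uB(d0, d1, c(adShort, rdShort, rdShort)),
    roiLong = lB(dl0, dl1, c(adLong, rdLong, rdLong)),
    ctlShort = uB(mk(d0), mk(d1), c(adShortCtl, rdShort, rdShort)),
    ctlLong = lB(mk(dl0), mk(dl1), c(adLongCtl, rdLong, rdLong)))
}

# measured patch-mean lGI as a function of fold amplitude, on the template
# geometry; inverted by monotone interpolation to map cohort lGI targets to
# subject fold amplitudes
calibrateAmplitude <- function(cfg) {
  s <- cfg$surface
  grid <- s$amplitude_grid
  meas <- vapply(grid, function(a) {
    fs <- generateFoldedSurface(
      foldSpec(base_radius = s$base_radius, fold_amplitude = a,
               fold_frequency = s$fold_frequency,
               patch_center = s$patch_center, patch_width = s$patch_width,
               subdivision_level = s$subdivision_level,
               thickness = s$thickness, phase_jitter_sd = 0),
      seed = 0L)
    hull <- computeOuterHull(fs$pial, cfg$morphometry$closing_diameter)
    lgi <- mapValues(computeLGI(fs$pial, hull, cfg$morphometry$lgi_radius))
    dirs <- vertices(fs$pial) / sqrt(rowSums(vertices(fs$pial)^2))
    inPatch <- acos(pmin(1, pmax(-1, drop(dirs %*% (s$patch_center /
      sqrt(sum(s$patch_center^2))))))) < s$patch_width
    aw <- mapValues(vertexArea(fs$pial))
    weighted.mean(lgi[inPatch], aw[inPatch])
  }, numeric(1))
  if (any(diff(meas) <= 0))
    stop("amplitude calibration curve is not monotone; refine the grid")
  function(lgiTarget) {
    approx(meas, grid, xout = pmin(pmax(lgiTarget, min(meas)), max(meas)),
           rule = 2)$y
  }
}

#' Assemble a per-subject summary row
#'
#' Combines a subject's morphometric cluster means and per-class tract
#' metrics into the one-row summary consumed by the coupling statistics.
#' Missing tract classes yield explicit NA metrics with a zero count.
#'
#' @param subject subject id.
#' @param covars list/row with group, center, age, fsiq.
#' @param clusterMeans named list: lgi, thickness, depth, curvature.
#' @param shortMetrics,longMetrics named vectors fa/md/ad/rd (NA if the
#'   class is empty).
#' @param counts named vector: nShort, nLong, nExcluded.
#' @return one-row data.frame.
#' @export
summarizeSubject <- function(subject, covars, clusterMeans, shortMetrics,
                             longMetrics, counts) {
  data.frame(subject = subject, group = covars$group, center = covars$center,
             age = covars$age, fsiq = covars$fsiq,
             lgi = clusterMeans$lgi, thickness = clusterMeans$thickness,
             depth = clusterMeans$depth, curvature = clusterMeans$curvature,
             fa_short = shortMetrics[["fa"]], md_short = shortMetrics[["md"]],
             ad_short = shortMetrics[["ad"]], rd_short = shortMetrics[["rd"]],
             fa_long = longMetrics[["fa"]], md_long = longMetrics[["md"]],
             ad_long = longMetrics[["ad"]], rd_long = longMetrics[["rd"]],
             n_short = counts[["nShort"]], n_long = counts[["nLong"]],
             n_excluded = counts[["nExcluded"]])
}

# class metrics of a dissected streamline set given a cutoff
classSummary <- function(streams, cutoff, upper) {
  sp <- splitShortLong(streams, cutoff, upper)
  met <- function(ss) {
    if (nStreamlines(ss) == 0L)
      return(c(fa = NA_real_, md = NA_real_, ad = NA_real_, rd = NA_real_))
    colMeans(streamlineMetrics(ss), na.rm = TRUE)
  }
  list(short = met(sp$short), long = met(sp$long),
       counts = c(nShort = nStreamlines(sp$short),
                  nLong = nStreamlines(sp$long),
                  nExcluded = sp$nExcluded))
}

#' Run the end-to-end synthetic coupling analysis
#'
#' Executes, in order: cohort generation; per-subject folded-surface
#' synthesis and morphometry (lGI, area, thickness, depth, curvature,
#' smoothing); the vertex-wise group GLM with RFT cluster correction;
#' cluster ROI extraction and contralateral mirroring; per-subject tensor
#' phantom synthesis, whole-volume tractography and endpoint dissection
#' for both ROIs; pooled tract-length dip test, mixture fitting with
#' cross-validated k, cutoff derivation and short/long splitting;
#' per-subject summaries; and the full coupling statistics (per-metric
#' group GLMs with Bonferroni control, moderation models, SURE
#' comparisons, partial correlations), plus the same group GLMs in the
#' mirrored control ROI.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when given, the cohort table,
#'   subject summaries, cluster table, JSON report and a run manifest are
#'   written there.
#' @param verbose print stage progress.
#' @return list: `report` (nested results), `summaries` (per-subject
#'   data.frame), `cohort`, `clusters`, `mixture`, `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
  t00 <- Sys.time()
  say <- function(...) if (verbose) message("[foldconn] ", ...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    r
  }
  cfgSeed <- config$seed

  say("stage 1/7: cohort generation")
  csp <- do.call(cohortSpec, config$cohort)
  csp$seed <- cfgSeed
  cohort <- stage("cohort", generateCohort(csp))
  n <- nrow(cohort)

  say("stage 2/7: amplitude calibration + per-subject morphometry (n = ",
      n, ")")
  ampOf <- stage("calibration", calibrateAmplitude(config))
  s <- config$surface
  template <- icosphere(s$subdivision_level, 1)
  V <- nVertices(template)
  pcUnit <- s$patch_center / sqrt(sum(s$patch_center^2))
  morph <- stage("morphometry", {
    Ylgi <- matrix(NA_real_, V, n)
    Mthk <- Mdep <- Mcur <- matrix(NA_real_, V, n)
    surfaces <- vector("list", n)
    amp <- ampOf(cohort$lgi)
    for (i in seq_len(n)) {
      fs <- generateFoldedSurface(
        foldSpec(base_radius = s$base_radius, fold_amplitude = amp[i],
                 fold_frequency = s$fold_frequency, patch_center = pcUnit,
                 patch_width = s$patch_width,
                 subdivision_level = s$subdivision_level,
                 thickness = s$thickness,
                 phase_jitter_sd = s$phase_jitter_sd),
        seed = (cfgSeed %% 100000L) * 10000L + i)
      hull <- computeOuterHull(fs$pial, config$morphometry$closing_diameter)
      # lGI is computed where folds can influence the geodesic disc; the
      # remainder of the surface is exactly spherical (convex), where the
      # index is 1 by construction
      alpha <- acos(pmin(1, pmax(-1, drop(
        (vertices(fs$pial) / sqrt(rowSums(vertices(fs$pial)^2))) %*% pcUnit))))
      at <- which(alpha < s$patch_width +
                    2.2 * config$morphometry$lgi_radius / s$base_radius)
      lgi <- computeLGI(fs$pial, hull, config$morphometry$lgi_radius, at = at)
      lv <- mapValues(lgi); lv[is.na(lv)] <- 1
      lgi <- scalarMap(lv, "")
      Ylgi[, i] <- mapValues(smoothScalar(
        fs$pial, lgi, config$morphometry$smoothing_fwhm))
      Mthk[, i] <- mapValues(computeThickness(fs$white, fs$pial))
      Mdep[, i] <- mapValues(computeSulcalDepth(fs$pial, hull))
      Mcur[, i] <- mapValues(computeMeanCurvature(fs$pial))
      surfaces[[i]] <- fs
    }
    list(Ylgi = Ylgi, thk = Mthk, dep = Mdep, cur = Mcur,
         surfaces = surfaces, amp = amp)
  })

  say("stage 3/7: vertex GLM + RFT cluster correction")
  X <- model.matrix(~ group + center + age + fsiq, cohort)
  colnames(X)[2] <- "group"
  vstat <- stage("vertexstats", {
    fit <- fitVertexGLM(morph$Ylgi, X, coef = "group")
    rc <- rftClusterCorrect(fit$t, fit$residuals, template, fit$df,
                            config$stats$cluster_forming_p,
                            config$stats$cluster_alpha,
                            config$stats$two_tailed)
    list(fit = fit, rc = rc)
  })
  sig <- vstat$rc$clusters[vstat$rc$significant]
  posSig <- sig[vapply(sig, function(x) x@sign > 0, logical(1))]
  hasCluster <- length(posSig) > 0
  roiCluster <- if (hasCluster) posSig[[1]] else NULL
  say("  significant clusters: ", length(sig),
      if (hasCluster) paste0(" (primary: ", length(roiCluster@vertices),
                             " vertices, p = ",
                             signif(roiCluster@p, 3), ")") else
        " - continuing with the control-only branch")
  corr <- mirrorCorrespondence(template)
  roiVerts <- if (hasCluster) extractClusterROI(roiCluster, template) else
    integer(0)
  ctlVerts <- if (hasCluster) mirrorCluster(roiCluster, corr) else integer(0)

  say("stage 4/7: per-subject tractography + endpoint dissection")
  tract <- stage("tractography", {
    perSubj <- vector("list", n)
    for (i in seq_len(n)) {
      bl <- subjectBundles(cfg = config, white = morph$surfaces[[i]]$white,
                           adShort = cohort$ad_short[i],
                           adLong = cohort$ad_long[i],
                           rdShort = cohort$rd_short[i],
                           rdLong = cohort$rd_long[i],
                           adShortCtl = cohort$ad_short_ctl[i],
                           adLongCtl = cohort$ad_long_ctl[i])
      vol <- suppressMessages(
        generateTensorVolume(config$volume$shape, config$volume$voxel_size,
                             bundles = unname(bl)))
      st <- trackWholeVolume(vol, config$tracking$fa_threshold,
                             config$tracking$angle_max_deg,
                             config$tracking$step_mm,
                             config$tracking$min_len_mm)
      st <- streamlineMeanMetrics(st, vol)$streams
      fs <- morph$surfaces[[i]]
      dissect <- function(verts) {
        if (!length(verts)) return(subsetStreamlines(st, integer(0)))
        pos <- rbind(vertices(fs$pial)[verts, , drop = FALSE],
                     vertices(fs$white)[verts, , drop = FALSE])
        roiSurf <- triSurface(pos, matrix(integer(0), 0, 3))
        mask <- voxelizeSurfaceROI(seq_len(nrow(pos)), roiSurf, affine(vol),
                                   config$volume$shape, config$roi$band)
        dissectByEndpoints(st, mask)
      }
      perSubj[[i]] <- list(roi = dissect(roiVerts), ctl = dissect(ctlVerts))
    }
    perSubj
  })

  say("stage 5/7: tract-length distribution + mixture classification")
  mixture <- stage("mixture", {
    pooled <- unlist(lapply(tract, function(x) streamlineLengths(x$roi)))
    if (length(pooled) >= 4) {
      dip <- dipStatistic(pooled)
      dp <- dipPvalue(dip, length(pooled),
                      nBoot = config$mixture$dip_n_boot,
                      seed = cfgSeed + 17L)
      # mixture fitting on a deterministic subsample at large n
      fitSample <- if (length(pooled) > config$mixture$max_n)
        withSeed(cfgSeed + 19L, sample(pooled, config$mixture$max_n)) else
        pooled
      sel <- selectKCrossval(fitSample, config$mixture$k_range,
                             seed = cfgSeed + 23L,
                             nSplits = config$mixture$n_splits,
                             gainThreshold = config$mixture$gain_threshold,
                             nRestarts = config$mixture$n_restarts)
      model <- fitGmmEM(fitSample, max(sel$k, 1L), seed = cfgSeed + 29L,
                        nRestarts = max(config$mixture$n_restarts, 3L))
      # the short/long split separates the two *dominant* classes: take the
      # boundary immediately above the lower of the two heaviest components
      # (robust when cross-validation splits one physical class in two)
      cutoff <- if (model@k >= 2L) {
        bounds <- classCutoffs(model)
        dom <- sort(order(model@weights, decreasing = TRUE)[1:2])
        bounds[dom[1]]
      } else config$mixture$fallback_cutoff
      list(dip = dip, dipP = dp$p, k = sel$k, heldOut = sel$heldOutLogLik,
           model = model, cutoff = cutoff, nPooled = length(pooled))
    } else {
      list(dip = NA, dipP = NA, k = NA, model = NULL,
           cutoff = config$mixture$fallback_cutoff, nPooled = length(pooled))
    }
  })
  say("  pooled streamlines: ", mixture$nPooled, ", dip = ",
      signif(mixture$dip, 3), " (p = ", signif(mixture$dipP, 3),
      "), k = ", mixture$k, ", cutoff = ", signif(mixture$cutoff, 4), " mm")

  say("stage 6/7: per-subject summaries")
  summaries <- stage("summaries", {
    aw <- mapValues(vertexArea(template))   # unit-sphere weights as fallback
    rows <- lapply(seq_len(n), function(i) {
      fs <- morph$surfaces[[i]]
      awS <- mapValues(vertexArea(fs$pial))
      cm <- if (hasCluster) list(
        lgi = weighted.mean(morph$Ylgi[roiVerts, i], awS[roiVerts]),
        thickness = weighted.mean(morph$thk[roiVerts, i], awS[roiVerts]),
        depth = weighted.mean(morph$dep[roiVerts, i], awS[roiVerts]),
        curvature = weighted.mean(morph$cur[roiVerts, i], awS[roiVerts]))
      else list(lgi = NA_real_, thickness = NA_real_, depth = NA_real_,
                curvature = NA_real_)
      cs <- classSummary(tract[[i]]$roi, mixture$cutoff,
                         config$mixture$upper_mm)
      summarizeSubject(cohort$subject[i], cohort[i, ], cm,
                       cs$short, cs$long, cs$counts)
    })
    do.call(rbind, rows)
  })
  ctlSummaries <- stage("ctl_summaries", {
    rows <- lapply(seq_len(n), function(i) {
      cs <- classSummary(tract[[i]]$ctl, mixture$cutoff,
                         config$mixture$upper_mm)
      cbind(data.frame(subject = cohort$subject[i]),
            t(setNames(c(cs$short, cs$long),
                       c(paste0(names(cs$short), "_short"),
                         paste0(names(cs$long), "_long")))),
            t(cs$counts))
    })
    do.call(rbind, rows)
  })

  say("stage 7/7: coupling statistics")
  statsRes <- stage("stats", couplingReport(cohort, summaries, ctlSummaries,
                                            config, hasCluster))

  clustersDf <- do.call(rbind, lapply(vstat$rc$clusters, function(cl)
    data.frame(nVertices = length(cl@vertices), peakT = cl@peakT,
               peakVertex = cl@peakVertex, p = cl@p, areaMM2 = cl@areaMM2,
               resels = cl@resels, sign = cl@sign)))
  report <- list(
    seed = cfgSeed,
    cluster = list(
      nSignificant = length(sig),
      table = clustersDf,
      primary = if (hasCluster) list(
        nVertices = length(roiCluster@vertices), peakT = roiCluster@peakT,
        p = roiCluster@p, areaMM2 = roiCluster@areaMM2) else NULL,
      fwhmMm = vstat$rc$fwhmMm, resels = vstat$rc$resels),
    mixture = list(dip = mixture$dip, dipP = mixture$dipP, k = mixture$k,
                   cutoffMm = mixture$cutoff, nPooled = mixture$nPooled,
                   model = if (!is.null(mixture$model)) list(
                     weights = mixture$model@weights,
                     means = mixture$model@means,
                     sds = mixture$model@sds) else NULL),
    stats = statsRes,
    timings = timings,
    totalSeconds = round(as.numeric(Sys.time() - t00, units = "secs"), 1))

  out <- list(report = report, summaries = summaries,
              ctlSummaries = ctlSummaries, cohort = cohort,
              clusters = vstat$rc, mixture = mixture, config = config)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

# group GLMs over the 8 class x metric combinations of a summary table
groupGlmTable <- function(summaries, alphaCorrected) {
  combos <- expand.grid(metric = c("fa", "md", "ad", "rd"),
                        class = c("short", "long"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    col <- paste0(combos$metric[i], "_", combos$class[i])
    if (!col %in% names(summaries) || all(is.na(summaries[[col]])))
      return(data.frame(measure = col, F = NA, p = NA, beta = NA,
                        significant = NA))
    g <- fitGroupGLM(summaries[[col]], summaries$group, summaries$center,
                     summaries$age, summaries$fsiq)
    data.frame(measure = col, F = g$F, p = g$p, beta = g$beta,
               significant = g$p < alphaCorrected)
  })
  do.call(rbind, rows)
}

# full coupling-statistics block of the pipeline report
couplingReport <- function(cohort, summaries, ctlSummaries, config,
                           hasCluster) {
  alphaC <- bonferroniThreshold(config$stats$alpha, config$stats$n_tests)
  res <- list(bonferroniThreshold = alphaC)
  summaries$age <- cohort$age; summaries$fsiq <- cohort$fsiq
  res$groupGlm <- groupGlmTable(summaries, alphaC)
  ctl <- cbind(ctlSummaries,
               cohort[, c("group", "center", "age", "fsiq")])
  res$controlGroupGlm <- groupGlmTable(ctl, alphaC)
  # streamline-count comparisons (short / long / all below the upper bound)
  cnt <- function(v) {
    tt <- stats::t.test(v ~ summaries$group)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  res$countTests <- rbind(short = cnt(summaries$n_short),
                          long = cnt(summaries$n_long),
                          all = cnt(summaries$n_short + summaries$n_long))
  if (hasCluster && !all(is.na(summaries$ad_short))) {
    # moderation models in both directions (short-tract AD <-> lGI)
    res$moderationAdOnLgi <- fitModerationGLM(
      summaries$ad_short, summaries$lgi, summaries$group,
      summaries$center)[c("F", "p", "coef")]
    res$moderationLgiOnAd <- fitModerationGLM(
      summaries$lgi, summaries$ad_short, summaries$group,
      summaries$center)[c("F", "p", "coef")]
    resLong <- tryCatch(fitModerationGLM(
      summaries$ad_long, summaries$lgi, summaries$group,
      summaries$center)[c("F", "p")], error = function(e) NULL)
    res$moderationAdLongOnLgi <- resLong
    # SURE: group effect on lGI vs on AD; lGI->AD vs AD->lGI
    z <- function(v) (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    cDum <- model.matrix(~ center, summaries)[, -1, drop = FALSE]
    ok <- complete.cases(summaries$lgi, summaries$ad_short)
    X0 <- cbind(1, group = summaries$group, cDum)[ok, , drop = FALSE]
    colnames(X0)[1] <- "(Intercept)"
    zl <- z(summaries$lgi)[ok]; za <- z(summaries$ad_short)[ok]
    sGroup <- sureFit(zl, X0, za, X0)
    res$sureGroup <- sureCompare(sGroup, c("eq1:group", "eq2:group"))
    Xl <- cbind(X0, pred = zl); Xa <- cbind(X0, pred = za)
    sDir <- sureFit(za, Xl, zl, Xa)
    res$sureDirection <- sureCompare(sDir, c("eq1:pred", "eq2:pred"))
    # partial correlations of lGI with short-tract AD given other features
    pc <- function(covarCols) {
      covs <- summaries[ok, covarCols, drop = FALSE]
      partialCorrelation(summaries$lgi[ok], summaries$ad_short[ok], covs)
    }
    res$partial <- list(
      raw = partialCorrelation(summaries$lgi[ok], summaries$ad_short[ok]),
      givenThickness = pc("thickness"),
      givenDepth = pc("depth"),
      givenCurvature = pc("curvature"))
    # association with long tracts for the scale-dependence contrast
    okL <- complete.cases(summaries$lgi, summaries$ad_long)
    res$partialLong <- partialCorrelation(summaries$lgi[okL],
                                          summaries$ad_long[okL])
  }
  res
}

# write pipeline outputs + manifest (atomically: temp file then rename)
writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name, writer) {
    p <- file.path(outDir, name)
    tmp <- paste0(p, ".tmp")
    writer(obj, tmp)
    file.rename(tmp, p)
    p
  }
  files <- c(
    wr(out$cohort, "cohort.tsv", writeTsv),
    wr(out$summaries, "subject_summaries.tsv", writeTsv),
    wr(out$report$cluster$table %||% data.frame(), "clusters.tsv",
       function(o, p) writeTsv(as.data.frame(o), p)),
    wr(out$report, "report.json", function(o, p)
      jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(out$config),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    timings = out$report$timings)
  wr(manifest, "manifest.json", function(o, p)
    jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA, force = TRUE))
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
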