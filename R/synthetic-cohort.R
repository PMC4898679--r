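#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate the study conditions of a two-center case-control
#' diffusion/morphometry cohort: 51 cases and 48 controls, adult male age
#' and IQ ranges, a raised local gyrification index in cases, and
#' short-tract axial diffusivity (AD) that is coupled to the lGI on top of
#' a direct group effect.  The default AD means/SDs reproduce the reported
#' short-streamline values (1.10 vs 1.08 x10^-3 mm^2/s, SD 0.04 x10^-3),
#' with the standardized group difference calibrated to the reported
#' F(1) = 8.09 (the F pins the effect more precisely than the two-decimal
#' means); the coupling slope is set so the raw lGI-AD correlation is
#' ~0.30, matching the reported partial correlations (~0.28).  Long-tract
#' AD carries no group effect and no coupling (the reported long-tract
#' pattern).
#'
#' @param n_group1 cases (default 51); `group = 1`.
#' @param n_group2 controls (default 48); `group = 0`.
#' @param group_lgi_delta lGI increase in cases (dimensionless).
#' @param group_ad_delta direct (non-lGI-mediated) AD increase in cases,
#'   mm^2/s.
#' @param coupling_slope AD change per unit lGI, mm^2/s.
#' @param noise_sd_lgi between-subject lGI SD.
#' @param noise_sd_ad residual AD SD, mm^2/s (total short-AD SD then
#'   ~0.04e-3 once the lGI-mediated part is added).
#' @param lgi_mean control-group mean lGI.
#' @param ad_short_mean control-group mean short-tract AD, mm^2/s.
#' @param ad_long_mean mean long-tract AD (both groups), mm^2/s.
#' @param ad_long_sd long-tract AD SD.
#' @param rd_short_mean,rd_short_sd,rd_long_mean,rd_long_sd radial
#'   diffusivity of the two tract classes, mm^2/s (no planted effects).
#' @param center_proportions sampling fractions of the two centers (sum 1).
#' @param center_ad_delta AD offset of center 2, mm^2/s.
#' @param center_lgi_delta lGI offset of center 2.
#' @param age_range,age_mean,age_sd years (drawn matched between groups).
#' @param fsiq_range,fsiq_mean,fsiq_sd full-scale IQ (matched).
#' @param seed integer; all randomness derives from it.
#' @return a `CohortSpec` (classed list).
#' @export
cohortSpec <- function(n_group1 = 51L, n_group2 = 48L,
                       group_lgi_delta = 0.04,
                       group_ad_delta = 1.08e-5,
                       coupling_slope = 3.0e-4,
                       noise_sd_lgi = 0.04,
                       noise_sd_ad = 3.816e-5,
                       lgi_mean = 1.10,
                       ad_short_mean = 1.08e-3,
                       ad_long_mean = 1.14e-3,
                       ad_long_sd = 3.5e-5,
                       rd_short_mean = 6.2e-4, rd_short_sd = 5e-5,
                       rd_long_mean = 5.8e-4, rd_long_sd = 4.5e-5,
                       center_proportions = c(0.5, 0.5),
                       center_ad_delta = 8e-6,
                       center_lgi_delta = 0.01,
                       age_range = c(18, 43), age_mean = 27, age_sd = 6.5,
                       fsiq_range = c(77, 137), fsiq_mean = 113, fsiq_sd = 12,
                       seed = 1L) {
  stopifnot(n_group1 > 0, n_group2 > 0, noise_sd_lgi >= 0, noise_sd_ad >= 0,
            abs(sum(center_proportions) - 1) < 1e-8,
            length(center_proportions) == 2L)
  structure(as.list(environment()), class = "CohortSpec")
}

# truncated-normal draw by resampling out-of-range values
rtruncn <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic cohort table
#'
#' Draws per-subject ground-truth summary measures under the spec: mean
#' lGI with a group offset and center effect; short-tract AD as
#' `intercept + coupling_slope * (lGI - lgi_mean) + group and center
#' effects + noise`; long-tract AD, and radial diffusivities, without
#' planted effects; age and FSIQ matched between groups.  Deterministic
#' given the spec seed (one top-level seed, split per draw).
#'
#' @param spec a [cohortSpec()].
#' @return data.frame with one row per subject: `subject`, `group` (0
#'   control / 1 case), `center` ("c1"/"c2"), `age`, `fsiq`, `lgi`,
#'   `ad_short`, `ad_long`, `rd_short`, `rd_long`.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n_group1 + spec$n_group2
  group <- rep(c(1L, 0L), c(spec$n_group1, spec$n_group2))
  withSeed(spec$seed, {
    center <- paste0("c", 1L + (runif(n) < spec$center_proportions[2]))
    c2 <- as.numeric(center == "c2")
    age <- rtruncn(n, spec$age_mean, spec$age_sd,
                   spec$age_range[1], spec$age_range[2])
    fsiq <- rtruncn(n, spec$fsiq_mean, spec$fsiq_sd,
                    spec$fsiq_range[1], spec$fsiq_range[2])
    lgi <- spec$lgi_mean + spec$group_lgi_delta * group +
      spec$center_lgi_delta * (c2 - mean(spec$center_proportions[2])) +
      rnorm(n, 0, spec$noise_sd_lgi)
    adShort <- spec$ad_short_mean +
      spec$coupling_slope * (lgi - spec$lgi_mean) +
      spec$group_ad_delta * group +
      spec$center_ad_delta * (c2 - spec$center_proportions[2]) +
      rnorm(n, 0, spec$noise_sd_ad)
    adLong <- spec$ad_long_mean + rnorm(n, 0, spec$ad_long_sd)
    rdShort <- spec$rd_short_mean + rnorm(n, 0, spec$rd_short_sd)
    rdLong <- spec$rd_long_mean + rnorm(n, 0, spec$rd_long_sd)
    # contralateral (control-ROI) tract values: same marginal variability,
    # no group effect and no lGI coupling
    sdCtl <- sqrt(spec$noise_sd_ad^2 +
                  (spec$coupling_slope * spec$noise_sd_lgi)^2)
    adShortCtl <- spec$ad_short_mean + rnorm(n, 0, sdCtl)
    adLongCtl <- spec$ad_long_mean + rnorm(n, 0, spec$ad_long_sd)
    data.frame(subject = sprintf("sub-%03d", seq_len(n)),
               group = group, center = center, age = age, fsiq = fsiq,
               lgi = lgi, ad_short = adShort, ad_long = adLong,
               rd_short = rdShort, rd_long = rdLong,
               ad_short_ctl = adShortCtl, ad_long_ctl = adLongCtl)
  })
}
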