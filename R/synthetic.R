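#' Concentric-cylinder fixture slice
#'
#' Two concentric regular polygons approximating circles of radius `Ri`
#' (lumen) and `Ro` (outer), with no lipid or calcification; the standard
#' validation geometry for the tube-inflation oracle.
#'
#' @param Ri,Ro inner/outer radius (mm), 0 < Ri < Ro.
#' @param n_vertices polygon resolution.
#' @param pressure_mmHg optional dia/sys pressures.
#' @return A [slice_contours()] object.
#' @export
generate_cylinder_fixture <- function(Ri = 1.5, Ro = 3, n_vertices = 360L,
                                      pressure_mmHg = list(dia = 75, sys = 140)) {
  if (Ri >= Ro) stop("Ri must be smaller than Ro")
  if (Ri <= 0) stop("Ri must be positive")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  slice_contours("cylinder", "fixture", "baseline",
                 lumen = cbind(Ri * cos(th), Ri * sin(th)),
                 outer = cbind(Ro * cos(th), Ro * sin(th)),
                 pressure_mmHg = pressure_mmHg)
}

#' Cohort generator specification
#'
#' Defines the statistical laws of the synthetic matched baseline/follow-up
#' cohort. Defaults emulate the study conditions the pipeline assumes:
#' 114 matched slice pairs from 10 patients, a heavily right-skewed minimum
#' cap thickness distribution (most slices in the thickest-cap category),
#' and a small morphology-linked mean progression so that positive
#' outcomes are the minority class (order of 16 positive vs 98 negative
#' cap-category changes).
#'
#' @param n_patients number of patients.
#' @param slices_per_patient integer vector (recycled) of slices per
#'   patient; the default totals 114 pairs.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param cap_thickness_law log-normal meanlog/sdlog of the minimum cap
#'   thickness (mm); the default matches a 79/21/7/7 split over the
#'   (0.36,2)/(0.26,0.36]/(0.20,0.26]/(0,0.20] mm categories.
#' @param lipid_arc_law uniform bounds of the lipid pool arc (degrees).
#' @param lumen_radius_law normal mean/sd of the mean lumen radius (mm).
#' @param wall_thickness_law normal mean/sd of the base wall thickness (mm).
#' @param progression coefficients of the follow-up model. Cap thickness
#'   progresses multiplicatively: log(capT_fu) = log(capT_bl) + intercept +
#'   pb_coef * (PB - pb_ref) + capt_coef * (log(capT_bl) - log(capt_ref)) +
#'   Normal(0, sd); lumen area changes by factor exp(Normal(la_drift, la_sd)).
#' @param pressure_law dia/sys mean and sd (mmHg) drawn per patient.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10L,
                        slices_per_patient = c(12L, 12L, 12L, 12L, 11L,
                                               11L, 11L, 11L, 11L, 11L),
                        seed = 1L,
                        cap_thickness_law = list(meanlog = -0.738, sdlog = 0.563),
                        lipid_arc_law = list(min = 40, max = 130),
                        lumen_radius_law = list(mean = 1.6, sd = 0.22),
                        wall_thickness_law = list(mean = 1.05, sd = 0.15),
                        progression = list(intercept = -0.10,
                                           pb_coef = -0.55, pb_ref = 0.62,
                                           capt_coef = -0.12, capt_ref = 0.45,
                                           sd = 0.10,
                                           la_drift = 0, la_sd = 0.04),
                        pressure_law = list(dia_mean = 72, dia_sd = 10,
                                            sys_mean = 139, sys_sd = 14)) {
  stopifnot(n_patients >= 1, all(slices_per_patient >= 1),
            cap_thickness_law$sdlog > 0, lumen_radius_law$sd >= 0,
            wall_thickness_law$sd >= 0, progression$sd >= 0)
  spec <- list(n_patients = as.integer(n_patients),
               slices_per_patient =
                 rep_len(as.integer(slices_per_patient), n_patients),
               seed = as.integer(seed),
               cap_thickness_law = cap_thickness_law,
               lipid_arc_law = lipid_arc_law,
               lumen_radius_law = lumen_radius_law,
               wall_thickness_law = wall_thickness_law,
               progression = progression,
               pressure_law = pressure_law)
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a matched baseline/follow-up synthetic cohort
#'
#' Each slice has a perturbed-ellipse lumen, an offset outer wall with an
#' eccentric plaque bulge, and one lipid pool subtending the drawn arc at
#' the drawn cap thickness. The follow-up slice applies the progression
#' model (cap thinning/thickening linked to baseline plaque burden and cap
#' thickness, plus noise) to the same geometry. Every slice passes
#' [slice_contours()] validation; non-simple draws are re-jittered.
#'
#' @param spec a [cohort_spec()].
#' @return List of pairs; each element has `baseline` and `followup`
#'   [slice_contours()] objects sharing `slice_id`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  pairs <- list()
  for (p in seq_len(spec$n_patients)) {
    dia <- max(45, rnorm(1, spec$pressure_law$dia_mean, spec$pressure_law$dia_sd))
    sys <- max(dia + 25, rnorm(1, spec$pressure_law$sys_mean, spec$pressure_law$sys_sd))
    press <- list(dia = dia, sys = sys)
    for (s in seq_len(spec$slices_per_patient[p])) {
      sid <- sprintf("P%02d_S%02d", p, s)
      geom <- draw_slice_geometry(spec)
      bl <- build_synthetic_slice(sid, sprintf("P%02d", p), "baseline",
                                  geom, press)
      pb <- geom$pb_approx
      pr <- spec$progression
      dlog <- pr$intercept + pr$pb_coef * (pb - pr$pb_ref) +
        pr$capt_coef * (log(geom$cap_t) - log(pr$capt_ref)) +
        rnorm(1, 0, pr$sd)
      geom_fu <- geom
      geom_fu$cap_t <- max(0.04, geom$cap_t * exp(dlog))
      geom_fu$r0 <- geom$r0 * exp(rnorm(1, pr$la_drift, pr$la_sd) / 2)
      fu <- build_synthetic_slice(sid, sprintf("P%02d", p), "followup",
                                  geom_fu, press)
      pairs[[length(pairs) + 1L]] <- list(baseline = bl, followup = fu)
    }
  }
  pairs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

draw_slice_geometry <- function(spec) {
  r0 <- max(0.8, rnorm(1, spec$lumen_radius_law$mean, spec$lumen_radius_law$sd))
  wall <- max(0.55, rnorm(1, spec$wall_thickness_law$mean,
                          spec$wall_thickness_law$sd))
  cap_t <- min(1.9, max(0.05, rlnorm(1, spec$cap_thickness_law$meanlog,
                                     spec$cap_thickness_law$sdlog)))
  # thick caps need room for the lipid pool behind them; thicken the wall
  # rather than truncating the configured cap-thickness law
  wall <- max(wall, cap_t / 0.5)
  arc <- runif(1, spec$lipid_arc_law$min, spec$lipid_arc_law$max) * pi / 180
  lipid_angle <- runif(1, 0, 2 * pi)
  ecc <- runif(1, 0, 0.12)          # ellipse eccentricity of the lumen
  phase <- runif(1, 0, 2 * pi)
  bump <- runif(1, 0.25, 0.6) * wall  # plaque bulge amplitude at the pool
  # rough plaque burden of this geometry (annulus + bump), used by the
  # progression model so that outcomes are morphology-linked
  la <- pi * r0^2
  pa <- pi * ((r0 + wall)^2 - r0^2) + bump * (r0 + wall / 2) * arc / 2
  list(r0 = r0, wall = wall, cap_t = cap_t, arc = arc,
       lipid_angle = lipid_angle, ecc = ecc, phase = phase, bump = bump,
       pb_approx = pa / (pa + la))
}

build_synthetic_slice <- function(slice_id, patient_id, timepoint, g, press,
                                  n_vertices = 96L, max_attempts = 100L) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  for (attempt in seq_len(max_attempts)) {
    jit <- if (attempt == 1L) 0 else 0.01 * attempt
    rl <- g$r0 * (1 + g$ecc * cos(2 * (th - g$phase))) +
      jit * sin(3 * th + attempt)
    dth <- angdiff(th, g$lipid_angle)
    bulge <- g$bump * exp(-(dth / (g$arc / 1.6))^2)
    ro <- rl + g$wall + bulge
    # lipid pool: sector of half-arc g$arc/2 about lipid_angle, radially
    # from (lumen + cap, thinnest at the arc centre) to 75% of the wall
    sector <- abs(dth) <= g$arc / 2
    if (sum(sector) < 6L) {
      g$arc <- g$arc * 1.3
      next
    }
    ths <- th[sector]
    o <- order(angdiff(ths, g$lipid_angle))
    ths <- ths[o]
    dts <- angdiff(ths, g$lipid_angle)
    capline <- g$cap_t + 0.6 * g$cap_t * (dts / (g$arc / 2))^2  # thin centre
    idx <- match(round(wrap_angle(ths), 10), round(th, 10))
    rin <- rl[idx] + capline
    rout <- ro[idx]
    rout_l <- pmin(rout - 0.12, rin + pmax(0.15, 0.7 * (rout - 0.12 - rin)))
    if (any(rout_l <= rin + 0.03)) {
      g$cap_t <- max(0.05, g$cap_t * 0.9)
      next
    }
    lipid <- rbind(cbind(rin * cos(ths), rin * sin(ths)),
                   cbind(rev(rout_l) * cos(rev(ths)),
                         rev(rout_l) * sin(rev(ths))))
    ok <- tryCatch({
      sl <- suppressWarnings(
        slice_contours(slice_id, patient_id, timepoint,
                       lumen = cbind(rl * cos(th), rl * sin(th)),
                       outer = cbind(ro * cos(th), ro * sin(th)),
                       lipids = list(lipid), pressure_mmHg = press))
      sl
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  stop("failed to generate a simple synthetic slice after ",
       max_attempts, " attempts")
}

angdiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d
}

wrap_angle <- function(a) a %% (2 * pi)
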