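#' Apply axial + circumferential pre-shrink to a slice
#'
#' Maps the in-vivo slice to a candidate zero-load state: the lumen
#' contour is scaled about the lumen centroid by (1 - circ_shrink), and
#' the outer contour is rescaled about the same centroid so that the
#' zero-load wall area equals the in-vivo wall area / (1 - axial_shrink)
#' — wall volume conservation when the vessel shortens axially by
#' `axial_shrink`. Internal component contours follow a radial blend of
#' the lumen and outer scalings.
#'
#' @param slice in-vivo [slice_contours()].
#' @param circ_shrink circumferential shrink fraction in [0, 1).
#' @param axial_shrink axial shrink fraction (0.05 convention).
#' @return The shrunk [slice_contours()].
#' @export
apply_shrink <- function(slice, circ_shrink, axial_shrink = 0.05) {
  stopifnot(inherits(slice, "slice_contours"),
            circ_shrink >= 0, circ_shrink < 1,
            axial_shrink >= 0, axial_shrink < 1)
  ctr <- polygon_centroid(slice$lumen)
  a_lum <- polygon_area(slice$lumen)
  a_out <- polygon_area(slice$outer)
  s_l <- 1 - circ_shrink
  a_wall_target <- (a_out - a_lum) / (1 - axial_shrink)
  s_o <- sqrt((a_wall_target + s_l^2 * a_lum) / a_out)
  scale_about <- function(poly, s) {
    sweep(sweep(as_polygon(poly), 2L, ctr) * s, 2L, ctr, `+`)
  }
  lumen2 <- scale_about(slice$lumen, s_l)
  outer2 <- scale_about(slice$outer, s_o)
  # radial blend for internal contours: a vertex at radial fraction f
  # between lumen and outer keeps f under the new boundary radii
  map_internal <- function(poly) {
    p <- as_polygon(poly)
    d <- sweep(p, 2L, ctr)
    th <- atan2(d[, 2L], d[, 1L])
    r <- sqrt(rowSums(d^2))
    rl <- polar_boundary_radius(slice$lumen, ctr, th)
    ro <- polar_boundary_radius(slice$outer, ctr, th)
    f <- (r - rl) / (ro - rl)
    r2 <- s_l * rl + f * (s_o * ro - s_l * rl)
    cbind(ctr[1L] + r2 * cos(th), ctr[2L] + r2 * sin(th))
  }
  out <- tryCatch(
    slice_contours(slice$slice_id, slice$patient_id, slice$timepoint,
                   lumen = lumen2, outer = outer2,
                   lipids = lapply(slice$lipids, map_internal),
                   calcifications = lapply(slice$calcifications, map_internal),
                   pressure_mmHg = slice$pressure_mmHg),
    error = function(e) {
      stop("shrink produced invalid geometry (outer inside lumen?): ",
           conditionMessage(e))
    })
  out
}

#' Find the per-slice circumferential shrink matching in-vivo morphology
#'
#' Bisection on circ_shrink in [0, 0.3]: each candidate zero-load geometry
#' is meshed coarsely and pressurised to the target pressure with axial
#' stretch 1/(1 - axial_shrink); the pressurised lumen area is compared to
#' the in-vivo lumen area. Returns the shrink whose relative lumen-area
#' error is within `tol`.
#'
#' @param slice in-vivo [slice_contours()].
#' @param materials material map ([default_materials()]).
#' @param pressure matching pressure (kPa); conventionally systolic.
#' @param tol relative lumen-area tolerance (default 0.01).
#' @param axial_shrink axial shrink fraction (default 0.05).
#' @param element_size coarse mesh size for the search (mm).
#' @param n_increments load increments per FE solve during the search.
#' @param max_iter bisection iteration limit.
#' @param method "bisection" (default) or "illinois" (regula falsi with
#'   bracket maintenance; same bracket, fewer FE evaluations).
#' @param n_theta,n_radial optional explicit search-mesh resolution.
#' @return A `shrink_result` list: `shrunk` (zero-load slice),
#'   `circ_shrink`, `axial_shrink`, `achieved_lumen_area_error`,
#'   `iterations`, and `solution` (FE solution at the matched shrink).
#' @export
find_circ_shrink <- function(slice, materials = default_materials(),
                             pressure, tol = 0.01, axial_shrink = 0.05,
                             element_size = 0.3, n_increments = 4L,
                             max_iter = 25L, method = c("bisection", "illinois"),
                             n_theta = NULL, n_radial = NULL,
                             newton_tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(tol > 0, pressure >= 0)
  target <- polygon_area(slice$lumen)
  axial_stretch <- 1 / (1 - axial_shrink)
  # fix the grid resolution once so consecutive candidates share the mesh
  # topology and can warm-start from the previous equilibrium
  if (is.null(n_theta) || is.null(n_radial)) {
    m0 <- build_mesh(slice, element_size = element_size)
    n_theta <- m0$n_theta; n_radial <- m0$n_radial
  }
  u_prev <- NULL
  eval_candidate <- function(s) {
    shr <- apply_shrink(slice, s, axial_shrink)
    mesh <- build_mesh(shr, element_size = element_size,
                       n_theta = n_theta, n_radial = n_radial)
    sol <- solve_slice(mesh, materials, pressure, axial_stretch,
                       n_increments = n_increments,
                       newton_tol = newton_tol, u0 = u_prev)
    u_prev <<- as.vector(t(sol$u))
    # correct the polygonisation bias of the coarse ring
    ln <- mesh$lumen_nodes
    ref_ring <- polygon_area(mesh$nodes[ln, , drop = FALSE])
    a <- sol$lumen_area_deformed * polygon_area(shr$lumen) / ref_ring
    list(err = a / target - 1, sol = sol, shrunk = shr)
  }
  try_candidate <- function(s) {
    for (nudge in c(0, 0.01, -0.01, 0.02)) {
      cand <- min(max(s + nudge, 0), 0.3)
      r <- tryCatch(eval_candidate(cand), error = function(e) NULL)
      if (!is.null(r)) { r$s <- cand; return(r) }
      warning(sprintf("FE solve failed at circ_shrink %.3f; candidate skipped",
                      cand))
    }
    stop("FE solve failed for all nudged candidates near ", s)
  }
  lo <- 0; hi <- 0.3
  rlo <- try_candidate(lo)
  if (abs(rlo$err) <= tol) {
    return(shrink_result(rlo, axial_shrink, 1L))
  }
  rhi <- try_candidate(hi)
  if (rlo$err * rhi$err > 0) {
    stop(sprintf(
      "no sign change on [0, 0.3]: area error %.4f at 0 and %.4f at 0.3",
      rlo$err, rhi$err))
  }
  it <- 2L
  flo <- rlo$err; fhi <- rhi$err
  while (it < max_iter) {
    mid <- if (method == "illinois") {
      m <- (lo * fhi - hi * flo) / (fhi - flo)
      min(max(m, lo + 0.02 * (hi - lo)), hi - 0.02 * (hi - lo))
    } else {
      (lo + hi) / 2
    }
    rm <- try_candidate(mid)
    it <- it + 1L
    if (abs(rm$err) <= tol) {
      return(shrink_result(rm, axial_shrink, it))
    }
    if (rm$err * flo < 0) {
      hi <- rm$s; fhi <- rm$err; rhi <- rm
      if (method == "illinois") flo <- flo / 2
    } else {
      lo <- rm$s; flo <- rm$err; rlo <- rm
      if (method == "illinois") fhi <- fhi / 2
    }
  }
  stop(sprintf(
    "iteration limit (%d) before reaching tolerance %g; best error %.4g",
    max_iter, tol, min(abs(rlo$err), abs(rhi$err))))
}

shrink_result <- function(r, axial_shrink, iterations) {
  structure(list(shrunk = r$shrunk, circ_shrink = r$s,
                 axial_shrink = axial_shrink,
                 achieved_lumen_area_error = abs(r$err),
                 iterations = iterations, solution = r$sol),
            class = "shrink_result")
}

#' @export
print.shrink_result <- function(x, ...) {
  cat(sprintf(
    "<shrink_result> circ_shrink %.4f (axial %.2f), lumen-area error %.3g, %d FE evaluations\n",
    x$circ_shrink, x$axial_shrink, x$achieved_lumen_area_error, x$iterations))
  invisible(x)
}
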