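#' Semi-analytic inflation of an incompressible thick-walled tube
#'
#' Reduction of the pressurised cylinder with circumferential fibers under
#' exact incompressibility and fixed axial stretch: with deformed inner
#' radius ri, the deformed map is r(R) = sqrt(ri^2 + (R^2 - Ri^2)/lz) and
#' the pressure-radius relation P = integral over the wall of
#' (sigma_theta - sigma_r)/r dr is evaluated by quadrature; ri is found by
#' root bracketing. Used as an independent oracle for the finite-element
#' solver on the cylinder fixture.
#'
#' @param mat a [material_params()] object (isotropic, or vessel with
#'   circumferential fibers).
#' @param Ri,Ro reference inner/outer radii (mm), 0 < Ri < Ro.
#' @param pressure lumen pressure (kPa).
#' @param axial_stretch fixed axial stretch.
#' @param n_quad quadrature points across the wall.
#' @return List: `ri` (deformed inner radius, mm), `r` (deformed radius
#'   profile), `hoop` (Cauchy hoop stress profile, kPa), `radial` (Cauchy
#'   radial stress profile, kPa).
#' @export
analytic_tube_inflation <- function(mat, Ri, Ro, pressure,
                                    axial_stretch = 1 / 0.95,
                                    n_quad = 400L) {
  stopifnot(0 < Ri, Ri < Ro, pressure >= 0, axial_stretch > 0)
  lz <- axial_stretch
  R <- seq(Ri, Ro, length.out = n_quad)
  dWdI <- function(I1, I4) {
    w1 <- mat$c1 + mat$D1 * mat$D2 * exp(mat$D2 * (I1 - 3))
    w4 <- if (identical(mat$tissue, "vessel")) {
      2 * mat$K1 * (I4 - 1) * exp(mat$K2 * (I4 - 1)^2)
    } else 0
    list(w1 = w1, w2 = mat$c2, w4 = w4)
  }
  stress_diff <- function(ri) {
    r <- sqrt(ri^2 + (R^2 - Ri^2) / lz)
    lt <- r / R
    lr <- 1 / (lt * lz)
    I1 <- lr^2 + lt^2 + lz^2
    I4 <- lt^2
    w <- dWdI(I1, I4)
    list(r = r,
         d = 2 * (lt^2 - lr^2) * (w$w1 + lz^2 * w$w2) + 2 * w$w4 * lt^2)
  }
  P_of_ri <- function(ri) {
    sd <- stress_diff(ri)
    pracma::trapz(sd$r, sd$d / sd$r)
  }
  f <- function(ri) P_of_ri(ri) - pressure
  # P(ri) is monotone increasing; bracket outward from the pure-axial state
  ri0 <- Ri / sqrt(lz)
  lo <- ri0; hi <- ri0
  for (k in 1:60) {
    flo <- f(lo)
    if (is.finite(flo) && flo < 0) break
    lo <- lo * 0.95
    if (lo < 1e-3 * Ri) stop("no root in physical range for the tube relation")
  }
  for (k in 1:60) {
    fhi <- f(hi)
    if (is.finite(fhi) && fhi > 0) break
    hi <- hi * 1.1
    if (hi > 50 * Ro) stop("no root in physical range for the tube relation")
  }
  if (!(is.finite(f(lo)) && is.finite(f(hi)) && f(lo) < 0 && f(hi) > 0)) {
    stop("no root in physical range for the tube relation")
  }
  ri <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  sd <- stress_diff(ri)
  # sigma_rr(r): -P at inner wall, 0 at outer wall
  integrand <- sd$d / sd$r
  cum <- c(0, cumsum((integrand[-1L] + integrand[-length(integrand)]) / 2 *
                       diff(sd$r)))
  sig_rr <- -pressure + cum
  sig_tt <- sig_rr + sd$d
  list(ri = ri, r = sd$r, hoop = sig_tt, radial = sig_rr)
}

#' Mesh-convergence loop
#'
#' Re-solves the slice on successively finer meshes (element size reduced
#' by 10 percent per step) until the cap stress summary changes by less
#' than `tol` (2 percent by default) between successive meshes.
#'
#' @param slice zero-load [slice_contours()].
#' @param materials material map.
#' @param pressure kPa.
#' @param axial_stretch out-of-plane stretch.
#' @param start_size initial element size (mm).
#' @param tol relative change threshold between successive meshes.
#' @param max_refine maximum refinement steps.
#' @param samples optional [cap_samples()] on the in-vivo slice; when the
#'   slice has a lipid the convergence metric is MaxCapS, otherwise the
#'   peak principal Cauchy stress on the lumen ring.
#' @param ... passed to [solve_slice()].
#' @return List: `solution`, `mesh`, `history` (data frame of element size
#'   and metric per step).
#' @export
mesh_convergence <- function(slice, materials = default_materials(),
                             pressure, axial_stretch = 1 / 0.95,
                             start_size = 0.25, tol = 0.02,
                             max_refine = 15L, samples = NULL, ...) {
  size <- start_size
  prev <- NULL
  hist <- data.frame(element_size = numeric(), metric = numeric(),
                     rel_change = numeric())
  for (step in seq_len(max_refine + 1L)) {
    mesh <- build_mesh(slice, element_size = size)
    sol <- solve_slice(mesh, materials, pressure, axial_stretch, ...)
    metric <- if (!is.null(samples) && any(samples$in_cap)) {
      cs <- extract_cap_mechanics(sol, samples)
      max(cs$stress[cs$in_cap])
    } else {
      max(lumen_wall_recovery(sol)$stress_max)
    }
    rel <- if (is.null(prev)) NA_real_ else abs(metric - prev) / abs(prev)
    hist <- rbind(hist, data.frame(element_size = size, metric = metric,
                                   rel_change = rel))
    if (!is.null(prev) && rel < tol) {
      return(list(solution = sol, mesh = mesh, history = hist))
    }
    prev <- metric
    size <- size * 0.9
  }
  stop("mesh convergence not reached after ", max_refine,
       " refinements; history: ",
       paste(sprintf("%.4g", hist$metric), collapse = ", "))
}

#' Cap stress/strain predictors from a solved slice
#'
#' For each Four-Quarter Even-Spacing lumen sample, assigns the maximum
#' principal Cauchy stress and maximum principal Green-Lagrange strain of
#' the nearest lumen-adjacent element in deformed coordinates. Cap
#' aggregates (MaxCapS, MeanCapS, MaxCapSn, MeanCapSn) are taken over cap
#' points via [cap_aggregates()].
#'
#' @param solution a converged [solve_slice()] result.
#' @param samples [cap_samples()] (with cap membership filled when the
#'   slice has lipid).
#' @return `samples` with `stress` (kPa) and `strain` columns filled.
#' @export
extract_cap_mechanics <- function(solution, samples) {
  stopifnot(inherits(solution, "solution_field"))
  if (!isTRUE(solution$converged)) stop("solution not converged")
  wall <- lumen_wall_recovery(solution)
  pts <- cbind(samples$x, samples$y)
  nn <- apply(pts, 1L, function(p) {
    which.min((wall$x - p[1L])^2 + (wall$y - p[2L])^2)
  })
  samples$stress <- wall$stress_max[nn]
  samples$strain <- wall$strain_max[nn]
  samples
}

# Lumen-wall stress/strain recovery. Constant-strain elements carry the
# field at their centroids; in the steep transmural gradient near the
# lumen this under-reads the wall value, so per circumferential column the
# tensor components of the innermost three radial layers are extrapolated
# quadratically (in deformed radial distance) to the deformed lumen ring.
lumen_wall_recovery <- function(solution) {
  mesh <- solution$mesh
  nt <- mesh$n_theta
  u <- solution$u
  def <- mesh$nodes + u
  ctr <- mesh$centroid
  col_of_quad <- (seq_len(nt * mesh$n_radial) - 1L) %% nt + 1L
  lay_of_quad <- (seq_len(nt * mesh$n_radial) - 1L) %/% nt + 1L
  col <- col_of_quad[mesh$quad_of_tri]
  lay <- lay_of_quad[mesh$quad_of_tri]
  cent <- (def[mesh$tri[, 1L], ] + def[mesh$tri[, 2L], ] +
             def[mesh$tri[, 3L], ]) / 3
  rad <- sqrt((cent[, 1L] - ctr[1L])^2 + (cent[, 2L] - ctr[2L])^2)
  ln <- mesh$lumen_nodes
  wall_xy <- def[ln, , drop = FALSE]
  rwall <- sqrt((wall_xy[, 1L] - ctr[1L])^2 + (wall_xy[, 2L] - ctr[2L])^2)
  nlay <- min(3L, mesh$n_radial)
  sten <- matrix(NA_real_, nt, 4L)
  eten <- matrix(NA_real_, nt, 4L)
  for (j in seq_len(nt)) {
    rk <- sk <- matrix(NA_real_, nlay, 4L)
    rr <- numeric(nlay)
    for (k in seq_len(nlay)) {
      sel <- col == j & lay == k
      w <- mesh$area[sel]
      rr[k] <- sum(rad[sel] * w) / sum(w)
      rk[k, ] <- colSums(solution$stress[sel, , drop = FALSE] * w) / sum(w)
      sk[k, ] <- colSums(solution$strain[sel, , drop = FALSE] * w) / sum(w)
    }
    r0 <- rwall[j]
    if (nlay >= 3L) {
      # quadratic Lagrange extrapolation to the wall radius
      L <- vapply(1:3, function(a) {
        o <- setdiff(1:3, a)
        prod((r0 - rr[o]) / (rr[a] - rr[o]))
      }, 0)
      sten[j, ] <- colSums(rk * L)
      eten[j, ] <- colSums(sk * L)
    } else {
      sten[j, ] <- rk[1L, ]
      eten[j, ] <- sk[1L, ]
    }
  }
  list(x = wall_xy[, 1L], y = wall_xy[, 2L],
       stress_max = max_principal(sten), strain_max = max_principal(eten),
       stress = sten, strain = eten, r = rwall)
}

#' Aggregate cap mechanics and thickness over cap points
#'
#' @param samples a filled `cap_samples` data frame.
#' @return One-row data frame: MinCapT, MeanCapT, MaxCapS, MeanCapS,
#'   MaxCapSn, MeanCapSn (NA when the slice has no cap points).
#' @export
cap_aggregates <- function(samples) {
  idx <- which(samples$in_cap)
  if (!length(idx)) {
    return(data.frame(MinCapT = NA_real_, MeanCapT = NA_real_,
                      MaxCapS = NA_real_, MeanCapS = NA_real_,
                      MaxCapSn = NA_real_, MeanCapSn = NA_real_))
  }
  data.frame(MinCapT = min(samples$cap_thickness[idx]),
             MeanCapT = mean(samples$cap_thickness[idx]),
             MaxCapS = max(samples$stress[idx]),
             MeanCapS = mean(samples$stress[idx]),
             MaxCapSn = max(samples$strain[idx]),
             MeanCapSn = mean(samples$strain[idx]))
}
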