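# Generalized plane strain hyperelastic solver.
#
# Total-Lagrangian formulation on the zero-load mesh: in-plane displacement
# unknowns with a prescribed uniform out-of-plane stretch, follower
# (pressure) load on the lumen boundary, incremental loading with Newton
# iteration. The volumetric penalty uses the cell-averaged volume ratio
# (mean dilatation over the four crossed triangles of each quad cell) to
# avoid locking; the stress returned per element uses the same split, so
# stresses are the exact work conjugates of the discrete energy.

solver_setup <- function(mesh, materials, axial_stretch) {
  nq <- nrow(mesh$quad_nodes)
  qn <- mesh$quad_nodes
  # per-quad, per-slot reference shape gradients and areas
  loc <- list(c(1L, 2L, 5L), c(2L, 3L, 5L), c(3L, 4L, 5L), c(4L, 1L, 5L))
  slots <- vector("list", 4L)
  for (s in 1:4) {
    n1 <- qn[, loc[[s]][1L]]; n2 <- qn[, loc[[s]][2L]]; n3 <- qn[, loc[[s]][3L]]
    X1 <- mesh$nodes[n1, , drop = FALSE]
    X2 <- mesh$nodes[n2, , drop = FALSE]
    X3 <- mesh$nodes[n3, , drop = FALSE]
    d1 <- X2 - X1; d2 <- X3 - X1
    twoA <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
    # gradients of the three linear shape functions
    dNx <- cbind(X2[, 2L] - X3[, 2L], X3[, 2L] - X1[, 2L], X1[, 2L] - X2[, 2L]) / twoA
    dNy <- cbind(X3[, 1L] - X2[, 1L], X1[, 1L] - X3[, 1L], X2[, 1L] - X1[, 1L]) / twoA
    tri_rows <- seq(s, by = 4L, length.out = nq)
    tis <- mesh$tissue[tri_rows]
    mt <- materials[tis]
    slots[[s]] <- list(
      loc = loc[[s]], dNx = dNx, dNy = dNy, A = twoA / 2,
      c1 = vapply(mt, `[[`, 0, "c1"), c2 = vapply(mt, `[[`, 0, "c2"),
      D1 = vapply(mt, `[[`, 0, "D1"), D2 = vapply(mt, `[[`, 0, "D2"),
      K1 = vapply(mt, function(m) m$K1 %||% 0, 0),
      K2 = vapply(mt, function(m) m$K2 %||% 1, 0),
      kap = vapply(mt, `[[`, 0, "kappa"),
      n1 = mesh$fiber[tri_rows, 1L], n2 = mesh$fiber[tri_rows, 2L],
      tri_rows = tri_rows)
  }
  Aq <- slots[[1L]]$A + slots[[2L]]$A + slots[[3L]]$A + slots[[4L]]$A
  list(slots = slots, Aq = Aq, nq = nq, qn = qn)
}

# deformation measures for one slot given local node displacements
slot_state <- function(sl, ux1, uy1, ux2, uy2, ux3, uy3, lamz) {
  F11 <- 1 + ux1 * sl$dNx[, 1L] + ux2 * sl$dNx[, 2L] + ux3 * sl$dNx[, 3L]
  F12 <-     ux1 * sl$dNy[, 1L] + ux2 * sl$dNy[, 2L] + ux3 * sl$dNy[, 3L]
  F21 <-     uy1 * sl$dNx[, 1L] + uy2 * sl$dNx[, 2L] + uy3 * sl$dNx[, 3L]
  F22 <- 1 + uy1 * sl$dNy[, 1L] + uy2 * sl$dNy[, 2L] + uy3 * sl$dNy[, 3L]
  J2 <- F11 * F22 - F12 * F21
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, J2 = J2, J = J2 * lamz)
}

# in-plane PK2 stress components of one slot; Jbar is the cell-average J
slot_stress <- function(sl, st, lamz, Jbar, full = FALSE) {
  F11 <- st$F11; F12 <- st$F12; F21 <- st$F21; F22 <- st$F22
  C11 <- F11^2 + F21^2
  C12 <- F11 * F12 + F21 * F22
  C22 <- F12^2 + F22^2
  C33 <- lamz^2
  J <- st$J
  det2 <- st$J2^2
  Ci11 <- C22 / det2; Ci22 <- C11 / det2; Ci12 <- -C12 / det2
  Ci33 <- 1 / C33
  I1 <- C11 + C22 + C33
  I2 <- (I1^2 - (C11^2 + 2 * C12^2 + C22^2 + C33^2)) / 2
  I4 <- C11 * sl$n1^2 + 2 * C12 * sl$n1 * sl$n2 + C22 * sl$n2^2
  Jm23 <- J^(-2 / 3); Jm43 <- Jm23^2
  I1b <- Jm23 * I1; I4b <- Jm23 * I4
  w1 <- sl$c1 + sl$D1 * sl$D2 * exp(sl$D2 * (I1b - 3))
  w4 <- 2 * sl$K1 * (I4b - 1) * exp(sl$K2 * (I4b - 1)^2)
  kt <- sl$kap * (Jbar - 1) * J
  S11 <- 2 * w1 * Jm23 * (1 - I1 / 3 * Ci11) +
    2 * sl$c2 * Jm43 * (I1 - C11 - 2 * I2 / 3 * Ci11) +
    2 * w4 * Jm23 * (sl$n1^2 - I4 / 3 * Ci11) + kt * Ci11
  S22 <- 2 * w1 * Jm23 * (1 - I1 / 3 * Ci22) +
    2 * sl$c2 * Jm43 * (I1 - C22 - 2 * I2 / 3 * Ci22) +
    2 * w4 * Jm23 * (sl$n2^2 - I4 / 3 * Ci22) + kt * Ci22
  S12 <- 2 * w1 * Jm23 * (-I1 / 3 * Ci12) +
    2 * sl$c2 * Jm43 * (-C12 - 2 * I2 / 3 * Ci12) +
    2 * w4 * Jm23 * (sl$n1 * sl$n2 - I4 / 3 * Ci12) + kt * Ci12
  out <- list(S11 = S11, S12 = S12, S22 = S22)
  if (full) {
    out$S33 <- 2 * w1 * Jm23 * (1 - I1 / 3 * Ci33) +
      2 * sl$c2 * Jm43 * (I1 - C33 - 2 * I2 / 3 * Ci33) +
      2 * w4 * Jm23 * (-I4 / 3 * Ci33) + kt * Ci33
    out$C <- list(C11 = C11, C12 = C12, C22 = C22, C33 = C33)
  }
  out
}

# internal nodal forces of every cell: ux,uy are nq x 5 local displacements
patch_forces <- function(sp, ux, uy, lamz) {
  nq <- sp$nq
  states <- vector("list", 4L)
  AJ <- 0
  for (s in 1:4) {
    sl <- sp$slots[[s]]; l <- sl$loc
    states[[s]] <- slot_state(sl, ux[, l[1L]], uy[, l[1L]],
                              ux[, l[2L]], uy[, l[2L]],
                              ux[, l[3L]], uy[, l[3L]], lamz)
    AJ <- AJ + sl$A * states[[s]]$J
  }
  Jbar <- AJ / sp$Aq
  fx <- matrix(0, nq, 5L); fy <- matrix(0, nq, 5L)
  for (s in 1:4) {
    sl <- sp$slots[[s]]; st <- states[[s]]; l <- sl$loc
    ss <- slot_stress(sl, st, lamz, Jbar)
    P11 <- st$F11 * ss$S11 + st$F12 * ss$S12
    P12 <- st$F11 * ss$S12 + st$F12 * ss$S22
    P21 <- st$F21 * ss$S11 + st$F22 * ss$S12
    P22 <- st$F21 * ss$S12 + st$F22 * ss$S22
    for (a in 1:3) {
      gx <- sl$dNx[, a]; gy <- sl$dNy[, a]
      fx[, l[a]] <- fx[, l[a]] + sl$A * (P11 * gx + P12 * gy)
      fy[, l[a]] <- fy[, l[a]] + sl$A * (P21 * gx + P22 * gy)
    }
  }
  list(fx = fx, fy = fy)
}

gather_local <- function(u, qn) {
  list(ux = matrix(u[2L * qn - 1L], nrow(qn), 5L),
       uy = matrix(u[2L * qn], nrow(qn), 5L))
}

scatter_forces <- function(f, qn, ndof) {
  r <- numeric(ndof)
  idx <- as.vector(qn)
  rx <- rowsum(as.vector(f$fx), idx)
  ry <- rowsum(as.vector(f$fy), idx)
  ids <- as.integer(rownames(rx))
  r[2L * ids - 1L] <- rx
  r[2L * ids] <- ry
  r
}

# follower pressure on the deformed lumen ring (CCW); per unit reference
# thickness the traction is scaled by the axial stretch
pressure_residual <- function(mesh, u, p, lamz) {
  ln <- mesh$lumen_nodes
  nb <- length(ln)
  x <- mesh$nodes[ln, 1L] + u[2L * ln - 1L]
  y <- mesh$nodes[ln, 2L] + u[2L * ln]
  nxt <- c(2:nb, 1L)
  dx <- x[nxt] - x; dy <- y[nxt] - y
  f <- numeric(length(u))
  fx <- p * lamz * dy / 2; fy <- -p * lamz * dx / 2
  recv <- c(ln, ln[nxt])
  ax <- rowsum(c(fx, fx), recv)
  ay <- rowsum(c(fy, fy), recv)
  ids <- as.integer(rownames(ax))
  f[2L * ids - 1L] <- ax
  f[2L * ids] <- ay
  f
}

pressure_tangent_triplets <- function(mesh) {
  ln <- mesh$lumen_nodes
  nb <- length(ln)
  nxt <- c(2:nb, 1L)
  n1 <- ln; n2 <- ln[nxt]
  # f_x(node) = +/- c * (y2 - y1), f_y(node) = -/+ c * (x2 - x1), c = p*lamz/2
  ii <- jj <- vv <- list()
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L; ii[[k]] <<- i; jj[[k]] <<- j; vv[[k]] <<- v
  }
  for (recv in list(n1, n2)) {
    add(2L * recv - 1L, 2L * n2, rep(+0.5, nb))   # dfx/dy2
    add(2L * recv - 1L, 2L * n1, rep(-0.5, nb))   # dfx/dy1
    add(2L * recv, 2L * n2 - 1L, rep(-0.5, nb))   # dfy/dx2
    add(2L * recv, 2L * n1 - 1L, rep(+0.5, nb))   # dfy/dx1
  }
  list(i = unlist(ii), j = unlist(jj), scale = unlist(vv))
}

#' Solve the pressurised thin-slice model
#'
#' Static equilibrium of the cross-section under lumen pressure and a
#' prescribed out-of-plane (axial) stretch, with the modified Mooney-Rivlin
#' materials. Load is applied in `n_increments` with Newton iteration per
#' increment; on divergence the increment is halved (up to 5 times). Rigid
#' body modes are removed by Lagrange constraints on the mean translation
#' and rotation.
#'
#' @param mesh a [build_mesh()] mesh of the zero-load geometry.
#' @param materials named list of [material_params()] (vessel/lipid/
#'   calcification).
#' @param pressure lumen pressure (kPa).
#' @param axial_stretch prescribed out-of-plane stretch (1/(1-0.05) for the
#'   5 percent axial shrink convention).
#' @param n_increments number of load increments (default 10).
#' @param newton_tol relative residual tolerance (default 1e-8).
#' @param max_newton Newton iterations per increment.
#' @param u0 optional displacement warm start (interleaved x/y, as long as
#'   2x the node count); when supplied the full load is attempted in one
#'   increment from it, falling back to incremental loading on failure.
#' @return A `solution_field` list: displacement `u` (N x 2), per-element
#'   Cauchy `stress` and Green-Lagrange `strain` (columns 11, 12, 22, 33),
#'   `converged`, `residual_norm`, deformed lumen area, and the inputs.
#' @export
solve_slice <- function(mesh, materials = default_materials(),
                        pressure, axial_stretch = 1 / 0.95,
                        n_increments = 10L, newton_tol = 1e-8,
                        max_newton = 50L, u0 = NULL) {
  stopifnot(inherits(mesh, "vessel_mesh"), pressure >= 0, axial_stretch > 0)
  ndof <- 2L * nrow(mesh$nodes)
  sp <- solver_setup(mesh, materials, axial_stretch)
  qn <- sp$qn
  # tangent sparsity pattern: 10x10 patch blocks + pressure blocks + constraints
  dof_loc <- cbind(2L * qn - 1L, 2L * qn)[, c(1L, 6L, 2L, 7L, 3L, 8L, 4L, 9L, 5L, 10L)]
  blk_i <- dof_loc[, rep(1:10, times = 10L)]
  blk_j <- dof_loc[, rep(1:10, each = 10L)]
  pt <- pressure_tangent_triplets(mesh)
  X <- mesh$nodes
  ci <- rep(1:3, each = ndof)
  cj <- rep(seq_len(ndof), 3L)
  cx <- c(rep(c(1, 0), ndof / 2L),            # sum ux
          rep(c(0, 1), ndof / 2L),            # sum uy
          as.vector(rbind(-X[, 2L], X[, 1L])))  # sum (x uy - y ux)
  keep <- cx != 0
  Ci <- ci[keep]; Cj <- cj[keep]; Cx <- cx[keep]
  all_i <- c(as.vector(blk_i), pt$i, ndof + Ci, Cj)
  all_j <- c(as.vector(blk_j), pt$j, Cj, ndof + Ci)
  n_sys <- ndof + 3L
  u <- numeric(ndof)
  h <- 1e-6
  gamma_done <- 0
  dgamma <- 1 / n_increments
  halvings <- 0L
  res_norm <- NA_real_
  if (!is.null(u0) && length(u0) == ndof) {
    # warm start: try the full load in one shot from the supplied state
    u <- u0
    gamma_done <- 1 - 1e-9
    dgamma <- 1e-9
  }
  warm <- !is.null(u0)
  while (gamma_done < 1 - 1e-12) {
    gamma <- min(1, gamma_done + dgamma)
    p_g <- gamma * pressure
    lamz_g <- 1 + gamma * (axial_stretch - 1)
    u_try <- u
    ok <- FALSE
    Alu <- NULL
    fresh_tangent <- FALSE
    resid_at <- function(uu) {
      gl <- gather_local(uu, qn)
      fint <- tryCatch(
        scatter_forces(patch_forces(sp, gl$ux, gl$uy, lamz_g), qn, ndof),
        error = function(e) NULL)
      if (is.null(fint) || !all(is.finite(fint))) return(NULL)
      fp <- pressure_residual(mesh, uu, p_g, lamz_g)
      R <- fint - fp
      ref <- max(sqrt(sum(fp^2)), 1e-2)
      # rigid modes are constrained; measure the projected residual
      Rc <- constrained_residual(R, Ci, Cj, Cx, ndof)
      list(R = R, norm = sqrt(sum(Rc^2)) / ref)
    }
    st <- resid_at(u_try)
    for (it in seq_len(max_newton)) {
      if (is.null(st)) break
      res_norm <- st$norm
      if (res_norm < newton_tol) { ok <- TRUE; break }
      # modified Newton: reuse the factorised tangent; refresh on demand
      if (is.null(Alu)) {
        gl <- gather_local(u_try, qn)
        kv <- patch_tangent(sp, gl$ux, gl$uy, lamz_g, h)
        xx <- c(kv, -p_g * lamz_g * pt$scale, rep(Cx, 2L))
        A <- Matrix::sparseMatrix(i = all_i, j = all_j, x = xx,
                                  dims = c(n_sys, n_sys))
        Alu <- tryCatch(Matrix::lu(A), error = function(e) NULL)
        if (is.null(Alu)) break
        fresh_tangent <- TRUE
      }
      rhs <- c(-st$R, -as.vector(constraint_values(u_try, Ci, Cj, Cx)))
      du <- tryCatch(as.numeric(Matrix::solve(Alu, rhs)),
                     error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) break
      du <- du[seq_len(ndof)]
      # backtracking line search against residual increase / element inversion
      accepted <- FALSE
      for (alpha in 2^-(0:5)) {
        st_new <- resid_at(u_try + alpha * du)
        if (!is.null(st_new) && st_new$norm < res_norm) {
          u_try <- u_try + alpha * du
          st <- st_new
          accepted <- TRUE
          if (alpha < 1 || st_new$norm > 0.3 * res_norm) Alu <- NULL
          break
        }
      }
      if (!accepted) {
        if (!fresh_tangent) { Alu <- NULL; fresh_tangent <- FALSE; next }
        break
      }
      fresh_tangent <- FALSE
    }
    if (ok) {
      u <- u_try
      gamma_done <- gamma
    } else if (warm) {
      # warm start failed: restart with plain incremental loading
      u <- numeric(ndof)
      gamma_done <- 0
      dgamma <- 1 / n_increments
      warm <- FALSE
    } else {
      dgamma <- dgamma / 2
      halvings <- halvings + 1L
      if (halvings > 5L) {
        stop(sprintf(
          "Newton divergence: load fraction reached %.3f after 5 halvings",
          gamma_done))
      }
    }
  }
  fields <- recover_fields(mesh, sp, u, axial_stretch)
  ln <- mesh$lumen_nodes
  lum <- cbind(mesh$nodes[ln, 1L] + u[2L * ln - 1L],
               mesh$nodes[ln, 2L] + u[2L * ln])
  out <- list(mesh = mesh, u = matrix(u, ncol = 2L, byrow = TRUE),
              stress = fields$stress, strain = fields$strain,
              converged = TRUE, residual_norm = res_norm,
              pressure = pressure, axial_stretch = axial_stretch,
              lumen_area_deformed = polygon_area(lum))
  class(out) <- "solution_field"
  out
}

constraint_values <- function(u, Ci, Cj, Cx, ndof) {
  g <- numeric(3L)
  for (k in 1:3) {
    sel <- Ci == k
    g[k] <- sum(Cx[sel] * u[Cj[sel]])
  }
  g
}

constrained_residual <- function(R, Ci, Cj, Cx, ndof) {
  # subtract the component of R lying in the span of the constraint rows
  Cm <- matrix(0, 3L, length(R))
  Cm[cbind(Ci, Cj)] <- Cx
  G <- Cm %*% t(Cm)
  lam <- solve(G, Cm %*% R)
  R - as.vector(t(Cm) %*% lam)
}

# central-difference tangent of the patch force w.r.t. its 10 local dofs;
# returns values aligned with the (blk_i, blk_j) pattern
patch_tangent <- function(sp, ux, uy, lamz, h) {
  nq <- sp$nq
  kv <- matrix(0, nq, 100L)
  for (ld in 1:10) {
    l <- (ld + 1L) %/% 2L
    is_x <- ld %% 2L == 1L
    uxp <- ux; uyp <- uy; uxm <- ux; uym <- uy
    if (is_x) {
      uxp[, l] <- uxp[, l] + h; uxm[, l] <- uxm[, l] - h
    } else {
      uyp[, l] <- uyp[, l] + h; uym[, l] <- uym[, l] - h
    }
    fp <- patch_forces(sp, uxp, uyp, lamz)
    fm <- patch_forces(sp, uxm, uym, lamz)
    dfx <- (fp$fx - fm$fx) / (2 * h)
    dfy <- (fp$fy - fm$fy) / (2 * h)
    # rows interleaved (x1,y1,...,x5,y5), column = local dof ld
    dcol <- matrix(0, nq, 10L)
    dcol[, seq(1L, 9L, 2L)] <- dfx
    dcol[, seq(2L, 10L, 2L)] <- dfy
    kv[, ((ld - 1L) * 10L + 1L):(ld * 10L)] <- dcol
  }
  as.vector(kv)
}

# per-element Cauchy stress and Green-Lagrange strain at the converged state
recover_fields <- function(mesh, sp, u, lamz) {
  ntri <- nrow(mesh$tri)
  stress <- matrix(NA_real_, ntri, 4L,
                   dimnames = list(NULL, c("s11", "s12", "s22", "s33")))
  strain <- matrix(NA_real_, ntri, 4L,
                   dimnames = list(NULL, c("e11", "e12", "e22", "e33")))
  gl <- gather_local(u, sp$qn)
  states <- vector("list", 4L)
  AJ <- 0
  for (s in 1:4) {
    sl <- sp$slots[[s]]; l <- sl$loc
    states[[s]] <- slot_state(sl, gl$ux[, l[1L]], gl$uy[, l[1L]],
                              gl$ux[, l[2L]], gl$uy[, l[2L]],
                              gl$ux[, l[3L]], gl$uy[, l[3L]], lamz)
    AJ <- AJ + sl$A * states[[s]]$J
  }
  Jbar <- AJ / sp$Aq
  for (s in 1:4) {
    sl <- sp$slots[[s]]; st <- states[[s]]
    ss <- slot_stress(sl, st, lamz, Jbar, full = TRUE)
    J <- st$J
    F11 <- st$F11; F12 <- st$F12; F21 <- st$F21; F22 <- st$F22
    # sigma = F S F' / J, with F33 = lamz
    sig11 <- (F11 * (F11 * ss$S11 + F12 * ss$S12) +
                F12 * (F11 * ss$S12 + F12 * ss$S22)) / J
    sig12 <- (F21 * (F11 * ss$S11 + F12 * ss$S12) +
                F22 * (F11 * ss$S12 + F12 * ss$S22)) / J
    sig22 <- (F21 * (F21 * ss$S11 + F22 * ss$S12) +
                F22 * (F21 * ss$S12 + F22 * ss$S22)) / J
    sig33 <- lamz^2 * ss$S33 / J
    rows <- sl$tri_rows
    stress[rows, ] <- cbind(sig11, sig12, sig22, sig33)
    strain[rows, ] <- cbind((ss$C$C11 - 1) / 2, ss$C$C12 / 2,
                            (ss$C$C22 - 1) / 2, (ss$C$C33 - 1) / 2)
  }
  list(stress = stress, strain = strain)
}

# max principal value of the (11,12,22,33) block tensors, per row
max_principal <- function(tens) {
  ctr <- (tens[, 1L] + tens[, 3L]) / 2
  rad <- sqrt(((tens[, 1L] - tens[, 3L]) / 2)^2 + tens[, 2L]^2)
  pmax(ctr + rad, tens[, 4L])
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(
    "<solution_field> p = %.3g kPa, axial stretch %.4g, %s (residual %.2e)\n",
    x$pressure, x$axial_stretch,
    if (x$converged) "converged" else "NOT converged", x$residual_norm))
  cat(sprintf("  peak principal Cauchy stress %.4g kPa, deformed lumen area %.4g mm^2\n",
              max(max_principal(x$stress)), x$lumen_area_deformed))
  invisible(x)
}
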