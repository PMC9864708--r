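#' Construct a segmented cross-section (slice) object
#'
#' Bundles the segmented contours of one IVUS+OCT cross-section: the lumen
#' border, the vessel outer boundary, and zero or more lipid and
#' calcification regions, all as closed polylines in millimetres. Contours
#' are validated (simple, nested, finite) and re-oriented counter-clockwise.
#'
#' @param slice_id,patient_id identifiers.
#' @param timepoint "baseline" or "followup".
#' @param lumen,outer closed polylines, n x 2 matrices (mm).
#' @param lipids,calcifications lists of closed polylines (mm), possibly empty.
#' @param pressure_mmHg named list/vector with elements `dia` and `sys`, or NULL.
#' @return An object of class `slice_contours`.
#' @export
slice_contours <- function(slice_id, patient_id, timepoint,
                           lumen, outer,
                           lipids = list(), calcifications = list(),
                           pressure_mmHg = NULL) {
  timepoint <- match.arg(timepoint, c("baseline", "followup"))
  lumen <- validate_contour(lumen, "lumen")
  outer <- validate_contour(outer, "outer")
  lipids <- lapply(seq_along(lipids), function(i) {
    validate_contour(lipids[[i]], paste0("lipid[", i, "]"))
  })
  calcifications <- lapply(seq_along(calcifications), function(i) {
    validate_contour(calcifications[[i]], paste0("ca[", i, "]"))
  })
  if (!polygon_inside_polygon(lumen, outer)) {
    stop("validation error: lumen contour is not strictly inside the outer boundary")
  }
  if (!is.null(pressure_mmHg)) {
    pressure_mmHg <- as.list(pressure_mmHg)
    if (!all(c("dia", "sys") %in% names(pressure_mmHg))) {
      stop("pressure_mmHg must have elements 'dia' and 'sys'")
    }
  }
  structure(
    list(slice_id = as.character(slice_id),
         patient_id = as.character(patient_id),
         timepoint = timepoint,
         lumen = lumen, outer = outer,
         lipids = lipids, calcifications = calcifications,
         pressure_mmHg = pressure_mmHg),
    class = "slice_contours")
}

validate_contour <- function(poly, what) {
  p <- tryCatch(as_polygon(poly),
                error = function(e) stop("contour '", what, "': ", conditionMessage(e)))
  if (nrow(p) < 3L) stop("contour '", what, "' has fewer than 3 vertices")
  if (nrow(p) < 8L) warning("contour '", what, "' is coarse (< 8 vertices)")
  if (!polygon_is_simple(p)) {
    stop("validation error: contour '", what, "' is self-intersecting")
  }
  ensure_ccw(p)
}

#' @export
print.slice_contours <- function(x, ...) {
  cat(sprintf("<slice_contours> %s (%s, %s): lumen %d pts, outer %d pts, %d lipid, %d ca\n",
              x$slice_id, x$patient_id, x$timepoint,
              nrow(x$lumen), nrow(x$outer),
              length(x$lipids), length(x$calcifications)))
  invisible(x)
}

#' Read a slice contour file
#'
#' Reads the JSON contour dialect: one slice per file with fields
#' `slice_id`, `patient_id`, `timepoint`, `pressure_mmHg` (`dia`/`sys`) and
#' `contours` holding `lumen`, `outer` and optional `lipid`/`ca` lists of
#' polylines (mm, closure implicit).
#'
#' @param path file path.
#' @return A validated [slice_contours()] object.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("parse error in ", path, ": ",
                                         conditionMessage(e)))
  for (f in c("slice_id", "patient_id", "timepoint", "contours")) {
    if (is.null(j[[f]])) stop("parse error: missing field '", f, "' in ", path)
  }
  ct <- j$contours
  for (f in c("lumen", "outer")) {
    if (is.null(ct[[f]])) stop("parse error: missing contour '", f, "' in ", path)
  }
  as_poly_list <- function(x) {
    if (is.null(x) || length(x) == 0L) return(list())
    if (is.matrix(x)) return(list(x))
    if (is.array(x) && length(dim(x)) == 3L) {
      return(lapply(seq_len(dim(x)[1L]), function(i) x[i, , ]))
    }
    lapply(x, as.matrix)
  }
  slice_contours(j$slice_id, j$patient_id, j$timepoint,
                 lumen = as.matrix(ct$lumen), outer = as.matrix(ct$outer),
                 lipids = as_poly_list(ct$lipid),
                 calcifications = as_poly_list(ct$ca),
                 pressure_mmHg = j$pressure_mmHg)
}

#' Write a slice contour file
#'
#' @param slice a [slice_contours()] object.
#' @param path output path.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "slice_contours"))
  j <- list(slice_id = slice$slice_id, patient_id = slice$patient_id,
            timepoint = slice$timepoint,
            pressure_mmHg = slice$pressure_mmHg,
            contours = list(lumen = unname(slice$lumen),
                            outer = unname(slice$outer),
                            lipid = lapply(slice$lipids, unname),
                            ca = lapply(slice$calcifications, unname)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Morphological risk factors of a slice
#'
#' Computes lumen area (LA), plaque area (PA = outer area minus lumen area),
#' plaque burden PB = PA/(PA+LA), and when the slice has at least one lipid
#' pool, minimum and mean fibrous-cap thickness (MinCapT/MeanCapT) over the
#' cap arc from [cap_thickness_profile()]. Slices without lipid have cap
#' fields `NA` (they have no fibrous cap).
#'
#' @param slice a [slice_contours()] object.
#' @param n_points number of even-spaced lumen points used for the cap
#'   thickness profile (default 100).
#' @return A one-row data frame: slice_id, patient_id, timepoint, LA, PA,
#'   PB, MinCapT, MeanCapT.
#' @export
morphology <- function(slice, n_points = 100L) {
  stopifnot(inherits(slice, "slice_contours"))
  la <- polygon_area(slice$lumen)
  ao <- polygon_area(slice$outer)
  if (ao <= la) stop("geometry error: outer area <= lumen area")
  pa <- ao - la
  mincap <- meancap <- NA_real_
  if (length(slice$lipids) > 0L) {
    cs <- cap_thickness_profile(slice, cap_samples(slice, n_points))
    if (any(cs$in_cap)) {
      mincap <- min(cs$cap_thickness[cs$in_cap])
      meancap <- mean(cs$cap_thickness[cs$in_cap])
    }
  }
  data.frame(slice_id = slice$slice_id, patient_id = slice$patient_id,
             timepoint = slice$timepoint,
             LA = la, PA = pa, PB = pa / (pa + la),
             MinCapT = mincap, MeanCapT = meancap,
             stringsAsFactors = FALSE)
}

#' Four-Quarter Even-Spacing lumen samples
#'
#' Places `n` evenly spaced points (arc length) on the lumen contour and
#' labels four consecutive quarters of n/4 points each. Cap membership,
#' cap thickness and mechanics fields are filled by
#' [cap_thickness_profile()] and [extract_cap_mechanics()].
#'
#' @param slice a [slice_contours()] object.
#' @param n number of samples, a multiple of 4 (default 100).
#' @return A `cap_samples` data frame: x, y, quarter, in_cap,
#'   cap_thickness, stress, strain.
#' @export
cap_samples <- function(slice, n = 100L) {
  stopifnot(inherits(slice, "slice_contours"))
  if (n %% 4L != 0L) stop("n must be a multiple of 4")
  pts <- resample_even(slice$lumen, n)
  out <- data.frame(x = pts[, 1L], y = pts[, 2L],
                    quarter = rep(1:4, each = n / 4L),
                    in_cap = FALSE,
                    cap_thickness = NA_real_,
                    stress = NA_real_, strain = NA_real_)
  class(out) <- c("cap_samples", class(out))
  attr(out, "centroid") <- polygon_centroid(slice$lumen)
  out
}

#' Cap membership and cap thickness along the lumen
#'
#' A lumen sample point belongs to the fibrous cap when the ray from the
#' lumen centroid through the point crosses a lipid pool; there the cap
#' thickness is the minimum Euclidean distance from the point to the
#' nearest lipid border. Aggregates MinCapT/MeanCapT are taken over cap
#' points only.
#'
#' @param slice a [slice_contours()] object with >= 1 lipid region.
#' @param samples output of [cap_samples()].
#' @return `samples` with `in_cap` and `cap_thickness` filled.
#' @export
cap_thickness_profile <- function(slice, samples) {
  stopifnot(inherits(slice, "slice_contours"))
  if (length(slice$lipids) < 1L) stop("slice has no lipid region")
  ctr <- attr(samples, "centroid")
  if (is.null(ctr)) ctr <- polygon_centroid(slice$lumen)
  pts <- cbind(samples$x, samples$y)
  in_cap <- rep(FALSE, nrow(pts))
  for (lip in slice$lipids) {
    in_cap <- in_cap | ray_hits_polygon(ctr, pts, lip)
  }
  thick <- rep(NA_real_, nrow(pts))
  if (any(in_cap)) {
    d <- rep(Inf, sum(in_cap))
    for (lip in slice$lipids) {
      d <- pmin(d, dist_points_to_polyline(pts[in_cap, , drop = FALSE], lip))
    }
    thick[in_cap] <- d
  } else {
    warning("lipid present but no lumen sample lies over it; cap stats absent")
  }
  samples$in_cap <- in_cap
  samples$cap_thickness <- thick
  samples
}

# does the ray from `origin` through each row of `pts` hit polygon `poly`?
ray_hits_polygon <- function(origin, pts, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  dirs <- sweep(pts, 2L, origin)
  hit <- rep(FALSE, nrow(pts))
  for (k in seq_len(n)) {
    e <- b[k, ] - a[k, ]
    w <- matrix(a[k, ] - origin, nrow(pts), 2L, byrow = TRUE)
    denom <- dirs[, 1L] * (-e[2L]) + dirs[, 2L] * e[1L]
    ok <- abs(denom) > 1e-14
    t_ray <- (w[, 1L] * (-e[2L]) + w[, 2L] * e[1L]) / denom
    s_seg <- (dirs[, 1L] * w[, 2L] - dirs[, 2L] * w[, 1L]) / denom
    hit <- hit | (ok & t_ray > 0 & s_seg >= 0 & s_seg <= 1)
  }
  hit
}

# min distance from each point to the closed polyline `poly`
dist_points_to_polyline <- function(pts, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(n)) {
    e <- b[k, ] - a[k, ]
    L2 <- sum(e^2)
    w1 <- pts[, 1L] - a[k, 1L]; w2 <- pts[, 2L] - a[k, 2L]
    t <- if (L2 > 0) pmin(1, pmax(0, (w1 * e[1L] + w2 * e[2L]) / L2)) else 0
    dx <- w1 - t * e[1L]; dy <- w2 - t * e[2L]
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}
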