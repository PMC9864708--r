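test_that("shoelace area matches closed forms and ignores orientation", {
  expect_equal(polygon_area(square_poly(1)), 1)
  expect_equal(polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))), 0.5)
  # regular 360-gon, circumradius 2: area = n R^2 sin(2 pi / n) / 2
  expect_equal(polygon_area(circle_poly(2, 360)),
               0.5 * 360 * 4 * sin(2 * pi / 360), tolerance = 1e-12)
  # within 0.1% of the circle area at 360 vertices
  expect_lt(abs(polygon_area(circle_poly(2, 360)) - 4 * pi) / (4 * pi), 1e-3)
  cw <- square_poly(1)[4:1, ]
  expect_equal(polygon_area(cw), 1)
  expect_error(polygon_area(cbind(c(0, 1), c(0, 1))), "3 vertices")
})

test_that("slice validation enforces nesting, simplicity and orientation", {
  s <- suppressWarnings(
    slice_contours("a", "p", "baseline", square_poly(2, -1, -1),
                   square_poly(4, -2, -2)))
  expect_s3_class(s, "slice_contours")
  expect_gt(polygon_signed_area_exported(s$lumen), 0)  # CCW after validation
  # clockwise input is re-oriented, area unchanged
  s2 <- suppressWarnings(
    slice_contours("a", "p", "baseline", square_poly(2, -1, -1)[4:1, ],
                   square_poly(4, -2, -2)))
  expect_equal(polygon_area(s2$lumen), 4)
  expect_gt(polygon_signed_area_exported(s2$lumen), 0)
  # lumen crossing the outer boundary
  expect_error(
    suppressWarnings(
      slice_contours("a", "p", "baseline", square_poly(4, -2, -2),
                     square_poly(2, -1, -1))),
    "inside")
  # self-intersecting bow-tie
  bow <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(
    suppressWarnings(
      slice_contours("a", "p", "baseline", bow, square_poly(4, -2, -2))),
    "self-intersecting")
})

test_that("contour JSON round trip preserves geometry and metadata", {
  sl <- annular_lipid_slice()
  path <- withr::local_tempfile(fileext = ".json")
  write_slice(sl, path)
  sl2 <- read_slice(path)
  expect_equal(sl2$slice_id, sl$slice_id)
  expect_equal(sl2$lumen, sl$lumen, tolerance = 1e-12)
  expect_equal(length(sl2$lipids), 1L)
  expect_equal(sl2$pressure_mmHg$sys, 140)
  expect_error(read_slice(file.path(tempdir(), "nope.json")), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"slice_id": "x"}', bad)
  expect_error(read_slice(bad), "missing field")
})

test_that("morphology computes LA, PA, PB per the area definitions", {
  # LA = 4, outer area = 10-ish via rectangle: use squares 2 and sqrt(10)?
  # direct arithmetic instead on concentric circles
  sl <- suppressWarnings(
    slice_contours("c", "p", "baseline", circle_poly(1.5, 360),
                   circle_poly(3, 360)))
  m <- morphology(sl)
  expect_equal(m$LA, pi * 1.5^2, tolerance = 1e-3)
  expect_equal(m$PA, pi * (9 - 2.25), tolerance = 1e-3)
  expect_equal(m$PB, 0.75, tolerance = 1e-9)  # ratio is resolution-exact
  expect_true(is.na(m$MinCapT) && is.na(m$MeanCapT))  # no lipid, no cap
  # PB arithmetic: LA = 4, outer = 10 -> PA = 6, PB = 0.6
  expect_equal(6 / (6 + 4), 0.6)
  sq <- suppressWarnings(
    slice_contours("s", "p", "baseline", square_poly(2, -1, -1),
                   cbind(c(-2.5, 2.5, 2.5, -2.5) * sqrt(10) / 5,
                         c(-2.5, -2.5, 2.5, 2.5) * sqrt(10) / 5)))
  ms <- morphology(sq)
  expect_equal(ms$LA, 4, tolerance = 1e-12)
  expect_equal(ms$PA, 6, tolerance = 1e-9)
  expect_equal(ms$PB, 0.6, tolerance = 1e-9)
})

test_that("even resampling spaces points by perimeter/n from the +x start", {
  sq <- square_poly(1)
  pts <- resample_even(sq, 100)
  d <- sqrt(rowSums((pts[c(2:100, 1), ] - pts)^2))
  # consecutive spacing 0.04 except across the 4 corners
  expect_equal(sort(unique(round(d, 6)))[1], 0.04, tolerance = 1e-6)
  expect_equal(sum(d), 4, tolerance = 1e-6)
  circ4 <- resample_even(circle_poly(1, 720), 4)
  ang <- atan2(circ4[, 2], circ4[, 1])
  expect_equal(diff(ang) %% (2 * pi), rep(pi / 2, 3), tolerance = 1e-3)
  # start point: maximum +x
  expect_equal(circ4[1, 1], 1, tolerance = 1e-4)
  # perimeter reconstruction within 0.5% on a smooth contour
  smooth <- circle_poly(2, 400)
  rs <- resample_even(smooth, 100)
  per_rs <- sum(sqrt(rowSums((rs[c(2:100, 1), ] - rs)^2)))
  expect_lt(abs(per_rs - polygon_perimeter_exported(smooth)) /
              polygon_perimeter_exported(smooth), 0.005)
  expect_error(resample_even(sq, 3), ">= 4")
})

test_that("densifying the input contour leaves the resampling invariant", {
  th <- 2 * pi * (0:199) / 200
  wav <- cbind((2 + 0.2 * cos(3 * th)) * cos(th),
               (2 + 0.2 * cos(3 * th)) * sin(th))
  th2 <- 2 * pi * (0:799) / 800
  wav2 <- cbind((2 + 0.2 * cos(3 * th2)) * cos(th2),
                (2 + 0.2 * cos(3 * th2)) * sin(th2))
  a <- resample_even(wav, 64)
  b <- resample_even(wav2, 64)
  expect_lt(max(sqrt(rowSums((a - b)^2))), 0.01)
})

test_that("cap membership and thickness follow the centroid-ray rule", {
  sl <- annular_lipid_slice(rl = 1.5, ro = 3, cap = 0.2)
  cs <- cap_thickness_profile(sl, cap_samples(sl, 100))
  expect_true(any(cs$in_cap))
  # the lipid subtends a 90-degree sector: about a quarter of samples
  expect_equal(mean(cs$in_cap), 0.25, tolerance = 0.08)
  expect_equal(min(cs$cap_thickness[cs$in_cap]), 0.2, tolerance = 0.01)
  agg_min <- min(cs$cap_thickness[cs$in_cap])
  expect_lte(agg_min, mean(cs$cap_thickness[cs$in_cap]))
  # MinCapT = 0.15 mm scores C-PVI category 4 downstream
  sl2 <- annular_lipid_slice(cap = 0.15)
  cs2 <- cap_thickness_profile(sl2, cap_samples(sl2, 100))
  expect_equal(score_pvi(min(cs2$cap_thickness[cs2$in_cap]),
                         pvi_thresholds("C")), 4L)
  # lipid entirely outside the sampled ray cone: tiny blob beyond outer arc
  # (construct lipid in the wall but subtending no lumen sample ray is not
  # geometrically possible for rays from the centroid; instead verify the
  # warning path with a lipid subtending an arc between two sample rays)
  expect_warning(
    cap_thickness_profile(
      within_slice_tiny_lipid(), cap_samples(within_slice_tiny_lipid(), 4L)),
    "cap stats absent")
})

test_that("cap samples form four balanced quarters at even spacing", {
  sl <- annular_lipid_slice()
  cs <- cap_samples(sl, 100)
  expect_equal(as.vector(table(cs$quarter)), rep(25L, 4))
  d <- sqrt(diff(cs$x)^2 + diff(cs$y)^2)
  # smooth contour: arc-length spacing uniform to high accuracy
  expect_lt(diff(range(d)) / mean(d), 1e-2)
  expect_error(cap_samples(sl, 30), "multiple of 4")
})

test_that("morphology invariants hold under rigid motion", {
  sl <- annular_lipid_slice()
  m0 <- morphology(sl)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(p) sweep(p %*% t(R), 2, c(3.2, -1.1), `+`)
  sl2 <- slice_contours("r", "p", "baseline", mv(sl$lumen), mv(sl$outer),
                        lipids = lapply(sl$lipids, mv),
                        pressure_mmHg = sl$pressure_mmHg)
  m1 <- morphology(sl2)
  expect_equal(m1$LA, m0$LA, tolerance = 1e-9)
  expect_equal(m1$PB, m0$PB, tolerance = 1e-9)
  expect_equal(m1$MinCapT, m0$MinCapT, tolerance = 1e-4)
  expect_equal(m1$MeanCapT, m0$MeanCapT, tolerance = 1e-3)
  expect_lte(m1$MinCapT, m1$MeanCapT)
  expect_gt(m0$PB, 0); expect_lt(m0$PB, 1)
})
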