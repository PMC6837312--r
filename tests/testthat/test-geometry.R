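test_that("Kocher point matches the closed-form spherical arc construction", {
  R <- 80
  head <- head_model(scalp_radius = R)
  ## independent spherical-coordinate expression: posterior arc theta along
  ## the midsagittal great circle (nasion at azimuth 0), lateral arc phi
  theta <- 100 / R
  phi <- 30 / R
  expected_right <- R * c(sin(phi), cos(phi) * cos(theta), cos(phi) * sin(theta))
  kp <- kocher_point(head, "right")
  expect_equal(kp, expected_right, tolerance = 1e-12)
  expect_lt(abs(sqrt(sum(kp^2)) - R), 1e-6)

  ## zero lateral offset lands on the midsagittal plane
  kp0 <- kocher_point(head, "right", lateral_mm = 0)
  expect_lt(abs(sum(kp0 * head$midline_normal) - sum(head$center * head$midline_normal)),
            1e-9)

  ## left and right are mirror images on a symmetric head
  kl <- kocher_point(head, "left")
  expect_equal(kl, kp * c(-1, 1, 1), tolerance = 1e-12)
})

test_that("instrument construction enforces its invariants", {
  head <- head_model()
  ins <- build_instrument(head, "right")
  expect_equal(ins$radius, 2)
  expect_equal(ins$entry, kocher_point(head, "right"))
  expect_equal(ins$target, head$foramen_right)
  expect_error(build_instrument(head, "right", radius = 0), "positive")
  expect_error(kocher_point(head_model(scalp_radius = 20,
                                       foramen_left = c(-2, 3, 1),
                                       foramen_right = c(2, 3, 1)), "right"),
               "too small")
  il <- build_instrument(head, "left")
  expect_equal(il$entry, ins$entry * c(-1, 1, 1), tolerance = 1e-12)
})

test_that("transects handles exact and degenerate cases", {
  head <- head_model()
  ins <- build_instrument(head, "right")
  along <- rbind(ins$entry, (ins$entry + ins$target) / 2, ins$target)
  r <- transects(along, ins)
  expect_true(r$transected)
  expect_equal(r$min_distance, 0)

  ## parallel straight streamline at 10 mm offset
  axis_dir <- (ins$target - ins$entry) / sqrt(sum((ins$target - ins$entry)^2))
  perp <- c(axis_dir[2], -axis_dir[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  off <- rbind(ins$entry + 10 * perp, ins$target + 10 * perp)
  r2 <- transects(off, ins)
  expect_false(r2$transected)
  expect_equal(r2$min_distance, 10, tolerance = 1e-9)

  expect_error(transects(matrix(ins$entry, 1, 3), ins), "at least 2 points")
})

test_that("transection is reversal-symmetric, rigid-motion invariant and radius-monotone", {
  head <- head_model()
  ins <- build_instrument(head, "right", radius = 2)
  ins5 <- build_instrument(head, "right", radius = 5)
  set.seed(11)
  ## random rotation (QR of a Gaussian matrix) + translation
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  shift <- c(5, -7, 3)
  mk_ins <- function(entry, target, radius)
    structure(list(entry = entry, target = target, radius = radius,
                   side = "right"), class = "virtual_instrument")
  ins_m <- mk_ins(as.vector(qr_rot %*% ins$entry) + shift,
                  as.vector(qr_rot %*% ins$target) + shift, ins$radius)
  for (i in 1:50) {
    sl <- rand_streamline(5, 40) + matrix(ins$entry, 5, 3, byrow = TRUE)
    r <- transects(sl, ins)
    rev_r <- transects(sl[5:1, ], ins)
    expect_equal(r$min_distance, rev_r$min_distance, tolerance = 1e-12)
    expect_identical(r$transected, rev_r$transected)
    sl_m <- t(qr_rot %*% t(sl)) + matrix(shift, 5, 3, byrow = TRUE)
    rm_ <- transects(sl_m, ins_m)
    expect_equal(r$min_distance, rm_$min_distance, tolerance = 1e-9)
    if (r$transected) expect_true(transects(sl, ins5)$transected)
  }
})

test_that("exact segment distances agree with a dense-sampling oracle", {
  q0 <- c(0, 0, 0); q1 <- c(0, 0, 10)
  ins <- structure(list(entry = q0, target = q1, radius = 2, side = "right"),
                   class = "virtual_instrument")
  set.seed(21)
  n_checked <- 0
  for (i in 1:300) {
    sl <- rand_streamline(4, 10)
    r <- transects(sl, ins)
    if (abs(r$min_distance - ins$radius) <= 0.01) next  # boundary case
    d_oracle <- oracle_polyline_segment_distance(sl, q0, q1)
    expect_identical(r$transected, d_oracle < ins$radius)
    expect_lt(abs(r$min_distance - d_oracle), 0.06)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("apply_lesion conserves streamlines and removes the right ones", {
  head <- head_model()
  ins <- build_instrument(head, "right")
  spec <- tiny_cohort_spec()
  tr <- generate_tractogram(spec, head, 7, group = "right")
  les <- apply_lesion(tr, ins)
  expect_equal(n_streamlines(les$tractogram) + length(les$report$transected_ids),
               n_streamlines(tr))
  expect_true(all(les$report$min_distance[les$report$transected_ids] < ins$radius))
  keep <- setdiff(seq_len(n_streamlines(tr)), les$report$transected_ids)
  expect_true(all(les$report$min_distance[keep] >= ins$radius))

  ## far instrument: untouched; axis-hugging streamlines: all removed
  far <- structure(list(entry = c(500, 0, 0), target = c(500, 0, 10),
                        radius = 2, side = "right"), class = "virtual_instrument")
  les_far <- apply_lesion(tr, far)
  expect_equal(n_streamlines(les_far$tractogram), n_streamlines(tr))
  expect_equal(les_far$tractogram$points, tr$points)
  axis_tr <- tractogram(rbind(ins$entry, ins$target, ins$entry, ins$target),
                        rep(0.5, 4), c(2L, 2L))
  expect_equal(n_streamlines(apply_lesion(axis_tr, ins)$tractogram), 0L)
})

test_that("instrument probability maps count cylinder membership", {
  mk <- function(entry, target, radius = 2)
    structure(list(entry = entry, target = target, radius = radius,
                   side = "right"), class = "virtual_instrument")
  a <- mk(c(0, 0, 0), c(0, 0, 20))
  map1 <- instrument_probability_map(list(a), grid_spacing = 1)
  expect_true(all(map1 %in% c(0, 1)))
  ## indicator check against a direct point-to-segment computation
  org <- attr(map1, "origin")
  dims <- dim(map1)
  idx <- which(map1 == 1, arr.ind = TRUE)
  pts <- sweep((idx - 1), 2, org, "+")   # spacing 1
  tz <- pmin(pmax(pts[, 3], 0), 20)
  dd <- sqrt(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - tz)^2)
  expect_true(all(dd < a$radius))

  expect_equal(unclass(instrument_probability_map(list(a, a, a), grid_spacing = 1)),
               unclass(map1))
  b <- mk(c(30, 0, 0), c(30, 0, 20))
  map2 <- instrument_probability_map(list(a, b), grid_spacing = 1)
  expect_equal(max(map2), 0.5)
})
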