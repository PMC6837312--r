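test_that("head models are deterministic and degenerate to the template at zero jitter", {
  spec0 <- default_cohort_spec(jitter_sd = 0)
  for (i in c(1, 5, 17)) {
    h <- make_head_model(spec0, i)
    expect_equal(h$nasion, spec0$head_template$nasion)
    expect_equal(h$foramen_left, spec0$head_template$foramen_left)
    expect_equal(h$foramen_right, spec0$head_template$foramen_right)
  }
  spec <- default_cohort_spec(jitter_sd = 1.5)
  h1 <- make_head_model(spec, 3)
  h2 <- make_head_model(spec, 3)
  expect_identical(h1, h2)
  expect_false(identical(h1$nasion, make_head_model(spec, 4)$nasion))
  ## nasion stays on the scalp sphere after jitter + re-projection
  expect_lt(abs(sqrt(sum((h1$nasion - h1$center)^2)) - h1$scalp_radius), 1e-9)
})

test_that("landmark jitter reproduces its Gaussian noise model", {
  parc <- parcellation(rbind(c(-30, 0, 0), c(30, 0, 0)), capture_radius = 5)
  spec <- cohort_spec(n_per_group = 400, parcellation = parc,
                      bundles = list(bundle_spec(1, 2, 1)),
                      jitter_sd = 2, seed = 99)
  nx <- vapply(1:1000, function(i) make_head_model(spec, i)$nasion[1], 0)
  expect_lt(abs(sd(nx) - 2) / 2, 0.10)
  fx <- vapply(1:1000, function(i) make_head_model(spec, i)$foramen_right[1], 0)
  expect_lt(abs(sd(fx) - 2) / 2, 0.10)
})

test_that("degenerate jitter pushing a foramen outside the scalp errors", {
  parc <- parcellation(rbind(c(-30, 0, 0), c(30, 0, 0)), capture_radius = 5)
  tpl <- head_model(scalp_radius = 20, foramen_left = c(-2, 3, 1),
                    foramen_right = c(2, 3, 1))
  spec <- cohort_spec(n_per_group = 2, parcellation = parc,
                      bundles = list(bundle_spec(1, 2, 1)),
                      head_template = tpl, jitter_sd = 15, seed = 4)
  expect_error(make_head_model(spec, 1), "degenerate head")
})

test_that("bundle generation honors counts, spread and waypoints", {
  parc <- parcellation(rbind(c(-40, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, -40, 0)),
                       capture_radius = 5)
  wp <- c(0, 0, 25)
  mk <- function(n, spread) cohort_spec(
    n_per_group = 2, parcellation = parc,
    bundles = list(bundle_spec(1, 2, n, waypoints = list(wp), spread_sd = spread)),
    jitter_sd = 0, seed = 8)
  head <- head_model()

  ## zero streamlines contribute nothing
  tr0 <- generate_tractogram(mk(0, 0), head, 1)
  expect_equal(n_streamlines(tr0), 0L)

  ## zero spread: 50 identical polylines through the waypoints
  tr <- generate_tractogram(mk(50, 0), head, 1)
  expect_equal(n_streamlines(tr), 50L)
  s1 <- streamline(tr, 1)
  for (i in c(2, 25, 50)) expect_equal(streamline(tr, i)$points, s1$points)
  expect_equal(s1$points[1, ], unname(parc$centroids[1, ]))
  expect_equal(s1$points[nrow(s1$points), ], unname(parc$centroids[2, ]))
  d_wp <- min(sqrt(colSums((t(s1$points) - wp)^2)))
  expect_lt(d_wp, 0.6)   # passes through the waypoint up to sampling density

  ## determinism in (spec, head, seed)
  tr_b <- generate_tractogram(mk(50, 0), head, 1)
  expect_identical(tr$points, tr_b$points)
})

test_that("FA samples and point spacing meet the generator contracts", {
  spec <- default_cohort_spec()
  tr <- generate_tractogram(spec, make_head_model(spec, 1), 42)
  expect_true(all(tr$fa > 0 & tr$fa < 1))
  clipped <- mean(tr$fa <= 1e-4 | tr$fa >= 1 - 1e-4)
  expect_lt(clipped, 0.01)
  sid <- rep.int(seq_along(tr$npts), tr$npts)
  d <- diff(tr$points)
  seg <- sqrt(rowSums(d * d))
  expect_lt(max(seg[sid[-1] == sid[-length(sid)]]), 1)
})

test_that("cohorts have three balanced groups and are seed-reproducible", {
  spec <- tiny_cohort_spec(seed = 5)
  co <- generate_cohort(spec)
  expect_length(co, 12L)
  groups <- vapply(co, function(x) x$group, "")
  expect_equal(as.vector(table(groups)[c("control", "left", "right")]),
               rep(4L, 3))
  co2 <- generate_cohort(tiny_cohort_spec(seed = 5))
  expect_equal(co[[7]]$points, co2[[7]]$points)
  expect_equal(co[[7]]$fa, co2[[7]]$fa)
  co3 <- generate_cohort(tiny_cohort_spec(seed = 6))
  expect_false(identical(co[[7]]$points, co3[[7]]$points))
})

test_that("a bundle routed along the instrument axis is almost entirely transected", {
  spec <- default_cohort_spec()
  head <- spec$head_template
  ins <- build_instrument(head, "right", radius = 2)
  axis_wp <- function(t) ins$entry + t * (ins$target - ins$entry)
  parc <- spec$parcellation
  bspec <- cohort_spec(
    n_per_group = 2, parcellation = parc,
    bundles = list(bundle_spec(7, 10, 200,
                               waypoints = list(axis_wp(0.35), axis_wp(0.55)),
                               spread_sd = 0.5, name = "near_axis")),
    head_template = head, jitter_sd = 0, seed = 31)
  tr <- generate_tractogram(bspec, head, 3)
  les <- apply_lesion(tr, ins)
  expect_gte(length(les$report$transected_ids) / n_streamlines(tr), 0.95)
})

test_that("planted effects modify only the targeted group's bundles", {
  spec <- tiny_cohort_spec()
  spec$effects <- list(list(group = "right", bundle = "callosal_ant",
                            nos_scale = 0.5))
  head <- make_head_model(spec, 1)
  tr_c <- generate_tractogram(spec, head, 9, group = "control")
  tr_r <- generate_tractogram(spec, head, 9, group = "right")
  n_c <- sum(tr_c$bundle == "callosal_ant")
  n_r <- sum(tr_r$bundle == "callosal_ant")
  expect_equal(n_r, as.integer(round(n_c * 0.5)))
})
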