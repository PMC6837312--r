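toy_parc <- function() parcellation(rbind(c(-40, 0, 0), c(40, 0, 0),
                                          c(0, 40, 0), c(0, -40, 0),
                                          c(0, 0, 40), c(0, 0, -40),
                                          c(25, 25, 0), c(-25, -25, 0)),
                                    capture_radius = 5)

straight_tract <- function(from, to, fa = 0.5, npts = 50) {
  t <- seq(0, 1, length.out = npts)
  pts <- cbind(from[1] + t * (to[1] - from[1]),
               from[2] + t * (to[2] - from[2]),
               from[3] + t * (to[3] - from[3]))
  list(points = pts, fa = rep(fa, npts))
}

bind_tract <- function(pieces, ...) {
  tractogram(do.call(rbind, lapply(pieces, `[[`, "points")),
             unlist(lapply(pieces, `[[`, "fa")),
             vapply(pieces, function(p) nrow(p$points), 0L), ...)
}

test_that("length filtering removes overlong streamlines at the stated cap", {
  long <- straight_tract(c(0, 0, 0), c(250, 0, 0))       # 250 mm
  short <- straight_tract(c(0, 0, 0), c(199.9, 0, 0))    # 199.9 mm
  tr <- bind_tract(list(long, short))
  kept <- filter_by_length(tr, 200)
  expect_equal(n_streamlines(kept), 1L)
  expect_equal(streamline_lengths(kept), 199.9, tolerance = 1e-9)

  ## finely sampled semicircle of radius 50: arc length ~ pi * 50 < 200
  theta <- seq(0, pi, length.out = 2000)
  semi <- tractogram(cbind(50 * cos(theta), 50 * sin(theta), 0),
                     rep(0.5, 2000), 2000L)
  expect_lt(abs(streamline_lengths(semi) - pi * 50), 0.01)
  expect_equal(n_streamlines(filter_by_length(semi, 200)), 1L)
  expect_equal(n_streamlines(filter_by_length(semi, 150)), 0L)
})

test_that("endpoint assignment respects capture radius and rejects loops", {
  parc <- toy_parc()
  ok <- straight_tract(c(-40, 1, 0), c(40, -1, 0))
  far <- straight_tract(c(-100, 90, 0), c(40, 0, 0))     # first endpoint unassigned
  loop <- straight_tract(c(-40, 1, 0), c(-41, -1, 0))    # both endpoints node 1
  tr <- bind_tract(list(ok, far, loop))
  qc <- endpoints_to_nodes(tr, parc)
  expect_equal(qc$accepted, c(TRUE, FALSE, FALSE))
  expect_equal(qc$reason, c("ok", "unassigned_endpoint", "same_node"))
  expect_equal(qc$node_a[1], 1L)
  expect_equal(qc$node_b[1], 2L)
})

test_that("matrix construction counts streamlines and accumulates mean FA", {
  parc <- toy_parc()
  empty <- tractogram(matrix(0, 0, 3), numeric(0), integer(0))
  m0 <- build_matrices(empty, parc)
  expect_true(all(m0$nos == 0) && all(m0$twfa == 0))

  pieces <- c(replicate(3, straight_tract(c(-40, 0, 0), c(40, 0, 0), fa = 0.5),
                        simplify = FALSE),
              list(straight_tract(c(0, 40, 0), c(0, -40, 0), fa = 0.3)))
  ## linearly varying FA 0.2 -> 0.6 over equally spaced points: mean 0.4
  lin <- straight_tract(c(0, 0, 40), c(0, 0, -40))
  lin$fa <- seq(0.2, 0.6, length.out = nrow(lin$points))
  tr <- bind_tract(c(pieces, list(lin)))
  m <- build_matrices(tr, parc)
  expect_equal(m$nos[1, 2], 3)
  expect_equal(m$twfa[1, 2], 1.5)
  expect_equal(m$nos[3, 4], 1)
  expect_equal(m$twfa[3, 4], 0.3)
  expect_equal(m$twfa[5, 6], 0.4)
  expect_equal(unclass(m$nos), t(unclass(m$nos)))
  expect_true(all(diag(m$nos) == 0) && all(diag(m$twfa) == 0))

  ## invariance to streamline order and point reversal
  rev_pieces <- lapply(c(pieces, list(lin)), function(p)
    list(points = p$points[nrow(p$points):1, ], fa = rev(p$fa)))
  tr2 <- bind_tract(rev_pieces[c(5, 3, 1, 4, 2)])
  m2 <- build_matrices(tr2, parc)
  expect_equal(unclass(m2$nos), unclass(m$nos))
  expect_equal(unclass(m2$twfa), unclass(m$twfa))
})

test_that("a planted bundle of 50 streamlines yields NOS exactly 50", {
  parc <- toy_parc()
  spec <- cohort_spec(n_per_group = 2, parcellation = parc,
                      bundles = list(bundle_spec(3, 7, 50, spread_sd = 0.5)),
                      jitter_sd = 0, seed = 2)
  tr <- generate_tractogram(spec, head_model(), 5)
  m <- build_matrices(tr, parc)
  expect_equal(m$nos[3, 7], 50)
})

test_that("lesioned NOS never exceeds the unlesioned NOS", {
  spec <- tiny_cohort_spec(seed = 12)
  head <- make_head_model(spec, 1)
  tr <- generate_tractogram(spec, head, 77)
  ins <- build_instrument(head, "right")
  les <- apply_lesion(tr, ins)$tractogram
  m_full <- build_matrices(tr, spec$parcellation)$nos
  m_les <- build_matrices(les, spec$parcellation)$nos
  expect_true(all(m_les <= m_full))
})

test_that("edge mask requires a strict majority in both groups", {
  n <- 5
  mk <- function(present) {
    m <- matrix(0, n, n)
    if (present) m[1, 2] <- m[2, 1] <- 3
    m[4, 5] <- m[5, 4] <- 1   # always-present edge
    m
  }
  ctrl <- lapply(c(TRUE, TRUE, TRUE, TRUE), mk)
  pat <- lapply(c(TRUE, TRUE, TRUE, FALSE), mk)
  mask <- group_edge_mask(ctrl, pat)
  expect_true(mask[1, 2] && mask[4, 5])
  ## exactly half of controls -> excluded (strict majority)
  ctrl_half <- lapply(c(TRUE, TRUE, FALSE, FALSE), mk)
  expect_false(group_edge_mask(ctrl_half, pat)[1, 2])
  expect_error(group_edge_mask(ctrl, list(matrix(0, 3, 3))), "mismatch")

  ## randomized presence vs exhaustive counting oracle
  set.seed(33)
  for (rep in 1:20) {
    cm <- replicate(5, rand_graph(n, 0.5) * sample(1:3, 1), simplify = FALSE)
    pm <- replicate(7, rand_graph(n, 0.5) * sample(1:3, 1), simplify = FALSE)
    mask <- group_edge_mask(cm, pm)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      nc <- sum(vapply(cm, function(m) m[i, j] > 0, TRUE))
      np <- sum(vapply(pm, function(m) m[i, j] > 0, TRUE))
      expect_identical(mask[i, j], nc > 5 / 2 && np > 7 / 2)
    }
  }
})

test_that("rank-Gaussian resampling preserves ranks and structural zeros", {
  set.seed(3)
  w <- matrix(0, 6, 6)
  ut <- which(upper.tri(w))
  nz <- sample(ut, 9)
  w[nz] <- runif(9, 0.1, 3)
  w <- w + t(w)
  g <- gaussian_resample(w, rng_seed = 41)
  expect_equal(unclass(g), t(unclass(g)))
  expect_true(all(g[setdiff(ut, nz)] == 0))
  expect_equal(cor(w[nz], g[nz], method = "spearman"), 1)
  ## resampling a gaussianized matrix keeps the rank structure
  g2 <- gaussian_resample(g, rng_seed = 42)
  expect_equal(rank(g2[nz]), rank(g[nz]))
  ## single nonzero edge becomes a standard normal draw
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 5
  g1 <- gaussian_resample(w1, rng_seed = 7)
  expect_equal(g1[1, 2], with_seed_value(7))
  expect_error(gaussian_resample(matrix(0, 4, 4)), "all-zero")
})

test_that("binarize respects masks and zero diagonals", {
  w <- matrix(2, 4, 4); diag(w) <- 0
  mask <- matrix(TRUE, 4, 4); mask[1, 2] <- mask[2, 1] <- FALSE
  a <- binarize(w, mask)
  expect_true(all(a %in% c(0, 1)))
  expect_equal(a[1, 2], 0)
  expect_equal(a[3, 4], 1)
  expect_true(all(diag(a) == 0))
})
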