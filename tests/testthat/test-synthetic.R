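test_that("geometry construction: sizes, connectivity, determinism, extent", {
  g <- make_geometry(4, 0)
  expect_equal(g$n_vertices, 8)
  expect_true(is_connected_set(g, which(g$masks$frontal_roi)))
  expect_true(is_connected_set(g, which(g$masks$parietal_roi)))
  expect_false(any(g$masks$frontal_roi & g$masks$parietal_roi))
  expect_true(all(g$edge_lengths > 0))

  expect_identical(make_geometry(20, 10, 1, seed = 5),
                   make_geometry(20, 10, 1, seed = 5))

  g2 <- make_geometry(100, 0, 1)
  f <- which(g2$masks$frontal_roi)
  expect_equal(max(dist(g2$coords[f, 1])), 9)  # 10 x 10 lattice, 1 mm

  expect_error(make_geometry(2, 0), "n_per_roi")
  expect_error(make_geometry(9, 0, spacing_mm = 0), "spacing_mm")
})

test_that("planted parcels are contiguous, cover the ROIs, and families band the axis", {
  for (seed in 1:5) {
    w <- make_world(seed = seed, n_per_roi = 64L, K = 4L, n_families = 2L)
    tr <- w$truth
    for (roi in c("frontal_roi", "parietal_roi")) {
      vids <- which(w$graph$masks[[roi]])
      expect_false(anyNA(tr$parcel_of[vids]))
      for (p in unique(tr$parcel_of[vids]))
        expect_true(is_connected_set(w$graph, which(tr$parcel_of == p)))
    }
    expect_true(all(is.na(tr$parcel_of[w$graph$masks$other])))
    expect_equal(tr$coupling, t(tr$coupling))
    expect_equal(diag(tr$coupling), rep(1, nrow(tr$coupling)))
  }
})

test_that("single parcel per ROI is the whole ROI", {
  g <- make_geometry(9, 0)
  tr <- plant_parcels(g, 1, 1, 1)
  expect_equal(unique(tr$parcel_of[g$masks$frontal_roi]), 1L)
  expect_equal(unique(tr$parcel_of[g$masks$parietal_roi]), 2L)
  expect_equal(diag(tr$coupling), c(1, 1))
})

test_that("paired coupling has a diagonal partner structure", {
  g <- make_geometry(36, 0)
  tr <- plant_parcels(g, 3, 3, 3, "paired")
  F <- tr$n_families
  cross <- tr$coupling[seq_len(F), F + seq_len(F)]
  expect_equal(apply(cross, 1, which.max), seq_len(F))
  expect_true(all(cross[row(cross) != col(cross)] < diag(cross)))
})

test_that("gradient coupling falls off strictly away from the matched band", {
  g <- make_geometry(64, 0)
  tr <- plant_parcels(g, 4, 4, 4, "gradient")
  F <- tr$n_families
  cross <- tr$coupling[seq_len(F), F + seq_len(F)]
  for (i in seq_len(F)) {
    r <- cross[i, ]
    expect_equal(which.max(r), i)
    if (i < F) expect_true(all(diff(r[i:F]) < 0))
    if (i > 1) expect_true(all(diff(r[1:i]) > 0))
  }
})

test_that("invalid planting arguments are rejected", {
  g <- make_geometry(9, 0)
  expect_error(plant_parcels(g, 100, 2, 1), "K_frontal")
  expect_error(plant_parcels(g, 2, 2, 3), "n_families")
  expect_error(plant_parcels(g, 2, 2, 2, a = 0.7, b = 0.5), "variance")
})

test_that("pure-noise simulation has near-zero cross correlations", {
  w <- make_world(seed = 1, n_per_roi = 9L, n_other = 0L, K = 1L,
                  n_families = 1L, a = 0, b = 0, T = 2000L)
  r <- cor(t(w$dat$subjects[[1]]$values))
  off <- abs(r[upper.tri(r)])
  expect_lt(max(off), 4 / sqrt(2000))
})

test_that("sample correlations match the closed-form model", {
  w <- make_world(seed = 3, n_per_roi = 16L, n_other = 0L, K = 2L,
                  n_families = 2L, a = 0.3, b = 0.4, T = 2000L)
  r <- cor(t(w$dat$subjects[[1]]$values))
  tr <- w$truth
  same_parcel <- outer(tr$parcel_of, tr$parcel_of, "==") &
    upper.tri(r)
  expect_equal(mean(r[same_parcel]), 0.7, tolerance = 0.05)

  # cross-ROI partner families: expected a * strong coupling
  fam <- tr$family_of[tr$parcel_of]
  F <- tr$n_families
  partner <- outer(fam, fam, function(x, y) y == x + F) # frontal x parietal
  strong <- max(tr$coupling[1, F + seq_len(F)])
  expect_equal(mean(r[partner]), 0.3 * strong, tolerance = 0.05)
})

test_that("simulation is bit-reproducible under a fixed configuration", {
  w1 <- make_world(seed = 11, T = 50L, n_nuisance = 2L)
  w2 <- make_world(seed = 11, T = 50L, n_nuisance = 2L)
  expect_identical(w1$dat, w2$dat)
})

test_that("expected connectome encodes the model algebra", {
  g <- make_geometry(16, 4)
  tr <- plant_parcels(g, 2, 2, 2, "paired", a = 0.3, b = 0.4)
  E <- expected_connectome(tr)$values
  v_same <- which(tr$parcel_of == 1)
  expect_equal(E[v_same[1], v_same[2]], 0.7)
  fam <- tr$family_of[tr$parcel_of]
  i <- which(fam == 1)[1]
  j <- which(fam == 2)[1]            # same ROI, different family: coupling 0
  expect_equal(E[i, j], 0.3 * tr$coupling[1, 2])
  k <- which(fam == 3)[1]            # cross-ROI partner family
  expect_equal(E[i, k], 0.3 * tr$coupling[1, 3])
  oth <- which(g$masks$other)[1]
  expect_equal(E[i, oth], 0)
  expect_equal(diag(E), rep(1, g$n_vertices))
})

test_that("empirical correlations converge to the expected connectome", {
  w <- make_world(seed = 2, n_per_roi = 12L, n_other = 4L, K = 2L,
                  n_families = 2L, a = 0.25, b = 0.45, T = 20000L)
  emp <- dense_connectome(w$dat$subjects[[1]])
  E <- expected_connectome(w$truth)
  expect_lt(max(abs(emp$values - E$values)), 0.05)
})
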