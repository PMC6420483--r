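test_that("ROI profiles subset the connectome and keep self-correlation", {
  set.seed(1)
  cn <- dense_connectome(timeseries_matrix(matrix(rnorm(10 * 30), 10, 30)))
  all_prof <- roi_profiles(cn, rep(TRUE, 10))
  expect_equal(all_prof$values, cn$values)

  one <- roi_profiles(cn, 4L)
  expect_equal(dim(one$values), c(1, 10))
  expect_equal(one$values[1, 4], 1)

  expect_error(roi_profiles(cn, logical(10)), "no vertices")
})

test_that("planted-parcel profiles are more similar within than across parcels", {
  g <- make_geometry(16, 4)
  tr <- plant_parcels(g, 2, 2, 2, a = 0.3, b = 0.4)
  E <- expected_connectome(tr)
  prof <- roi_profiles(E, g$masks$frontal_roi)
  S <- similarity_matrix(prof)
  pid <- tr$parcel_of[prof$roi_vertex_ids]
  same <- outer(pid, pid, "==") & upper.tri(S)
  diff <- !outer(pid, pid, "==") & upper.tri(S)
  expect_gt(min(S[same]), max(S[diff]))
})

test_that("similarity matrix equals the direct correlation formula", {
  P <- rbind(c(0.1, 0.5, -0.2, 0.8),
             c(0.0, 0.4, -0.1, 0.9),
             c(-0.6, 0.2, 0.7, -0.3))
  prof <- structure(list(values = P, roi_vertex_ids = 1:3,
                         hemi_vertex_ids = 1:4),
                    class = "connectivity_profiles")
  S <- similarity_matrix(prof)
  for (i in 1:3) for (j in 1:3) {
    x <- P[i, ] - mean(P[i, ]); y <- P[j, ] - mean(P[j, ])
    expect_equal(S[i, j], sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
                 tolerance = 1e-12)
  }
})

test_that("preference rule: min(S) - (max(S) - min(S)) on off-diagonal entries", {
  S1 <- matrix(c(1, 0.1, 0.5,
                 0.1, 1, 0.3,
                 0.5, 0.3, 1), 3, 3)
  expect_equal(default_preference(S1), 0.1 - (0.5 - 0.1))  # -0.3
  S2 <- matrix(c(1, -0.2, 0.9,
                 -0.2, 1, 0.4,
                 0.9, 0.4, 1), 3, 3)
  expect_equal(default_preference(S2), -0.2 - (0.9 - -0.2))  # -1.3
  expect_error(default_preference(matrix(c(1, 0.2, 0.2, 1), 2, 2)),
               "degenerate")
  # algebraic consequence: always below min(S)
  for (seed in 1:10) {
    set.seed(seed)
    S <- matrix(runif(16, -1, 1), 4, 4); S <- (S + t(S)) / 2; diag(S) <- 1
    expect_lt(default_preference(S), min(S[row(S) != col(S)]))
  }
})

test_that("affinity propagation solves small instances known in closed form", {
  # two points with high mutual similarity and a low preference: one cluster
  S2 <- matrix(c(0, 0.9, 0.9, 0), 2, 2)
  ap2 <- affinity_propagation(S2, preference = -1.3, jitter = FALSE)
  expect_equal(ap2$n_clusters, 1)
  bf2 <- brute_force_exemplars(S2, -1.3)
  expect_equal(net_similarity(S2, ap2, -1.3), net_similarity(S2, bf2, -1.3))

  # two tight pairs with negative cross-pair similarity and a preference
  # at which splitting is strictly optimal: one exemplar per pair
  S4 <- matrix(-0.5, 4, 4)
  S4[1, 2] <- S4[2, 1] <- 0.95
  S4[3, 4] <- S4[4, 3] <- 0.95
  diag(S4) <- 0
  ap4 <- affinity_propagation(S4, preference = -0.3, jitter = FALSE)
  expect_equal(ap4$n_clusters, 2)
  expect_equal(ap4$label_of, c(1, 1, 2, 2))
  bf4 <- brute_force_exemplars(S4, -0.3)
  expect_equal(bf4$n_clusters, 2)
  expect_equal(net_similarity(S4, ap4, -0.3), net_similarity(S4, bf4, -0.3))

  # a preference above every similarity makes every point an exemplar
  set.seed(9)
  S <- matrix(runif(36, -1, 0.8), 6, 6); S <- (S + t(S)) / 2; diag(S) <- 0
  apx <- affinity_propagation(S, preference = 1, jitter = FALSE)
  expect_equal(apx$n_clusters, 6)
  expect_equal(apx$exemplar_of, 1:6)
})

test_that("net similarity sums member-to-exemplar terms plus preferences", {
  S <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  singletons <- brute_force_exemplars(S, 1)   # preference above max
  expect_equal(singletons$n_clusters, 2)
  expect_equal(net_similarity(S, singletons, 1), 2)
  one <- brute_force_exemplars(S, -5)
  expect_equal(one$n_clusters, 1)
  expect_equal(net_similarity(S, one, -5), 0.2 - 5)
})

test_that("brute-force oracle matches the analytic two-point threshold", {
  for (s12 in c(-0.4, 0.1, 0.6)) {
    S <- matrix(c(0, s12, s12, 0), 2, 2)
    for (pref in c(s12 - 0.2, s12 + 0.2)) {
      bf <- brute_force_exemplars(S, pref)
      expect_equal(bf$n_clusters, if (pref < s12) 1L else 2L)
    }
  }
  # three mutually similar points collapse to one exemplar
  S3 <- matrix(0.9, 3, 3); diag(S3) <- 0
  expect_equal(brute_force_exemplars(S3, -1.3)$n_clusters, 1)
})

test_that("exemplars are self-assigned and clustering is permutation-equivariant", {
  set.seed(13)
  S <- matrix(runif(64, -1, 1), 8, 8); S <- (S + t(S)) / 2; diag(S) <- 1
  pref <- default_preference(S)
  ap <- affinity_propagation(S, pref, jitter = FALSE)
  expect_equal(ap$label_of[ap$exemplar_of], seq_len(ap$n_clusters))

  perm <- sample(8)
  Sp <- S[perm, perm]
  app <- affinity_propagation(Sp, pref, jitter = FALSE)
  expect_setequal(perm[app$exemplar_of], ap$exemplar_of)
  # membership structure is identical after undoing the permutation
  expect_equal(ari(app$label_of, ap$label_of[perm]), 1)
})

test_that("family structure survives a preference sweep at high SNR", {
  w <- make_world(seed = 5, n_per_roi = 64L, n_other = 16L, K = 6L,
                  n_families = 3L, a = 0.35, b = 0.35, T = 1500L)
  cl <- clean_timeseries(w$dat$subjects[[1]], detrend_order = 0L)
  cn <- dense_connectome(cl)
  fprof <- roi_profiles(cn, w$graph$masks$frontal_roi)
  pprof <- roi_profiles(cn, w$graph$masks$parietal_roi)
  Sf <- similarity_matrix(fprof)
  Sp <- similarity_matrix(pprof)
  p0 <- default_preference(Sf)
  ks <- c()
  for (mult in c(0.5, 1, 2)) {
    pf <- affinity_propagation(Sf, p0 * mult, vertex_ids = fprof$roi_vertex_ids)
    pp <- affinity_propagation(Sp, default_preference(Sp) * mult,
                               vertex_ids = pprof$roi_vertex_ids)
    ks <- c(ks, pf$n_clusters)
    M <- exemplar_matrix(cn, pf, pp)
    fam <- cut_branches(hierarchical_cluster(M, "frontal"), 3)
    expect_equal(ari(fam$branch_of, fam_of_exemplars(pf, w$truth)), 1)
  }
  expect_gte(length(unique(ks)), 2)  # the sweep does change the granularity
})
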