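# Shared fixtures: all synthetic, built in code at test time.

ari <- function(a, b) {
  r <- mclust::adjustedRandIndex(a, b)
  if (is.nan(r)) {
    # degenerate partitions (e.g. two all-singleton labelings): the index
    # is 0/0; fall back to exact partition agreement
    co <- function(x) {
      x <- as.integer(factor(x))
      outer(x, x, "==")
    }
    r <- if (identical(co(a), co(b))) 1 else 0
  }
  r
}

# a small planted world: geometry + truth + simulated data
make_world <- function(seed = 1L, n_per_roi = 36L, n_other = 9L, K = 2L,
                       n_families = 2L, coupling_spec = "paired",
                       a = 0.3, b = 0.4, T = 300L, n_subjects = 1L,
                       n_nuisance = 0L) {
  graph <- make_geometry(n_per_roi, n_other, 1, seed = seed)
  truth <- plant_parcels(graph, K, K, n_families, coupling_spec,
                         a = a, b = b, seed = seed + 1L)
  cfg <- synth_config(n_subjects, T, n_nuisance, seed = seed + 2L)
  dat <- simulate_subject_timeseries(graph, truth, cfg)
  list(graph = graph, truth = truth, cfg = cfg, dat = dat)
}

# is the subgraph induced by `vids` connected?
is_connected_set <- function(graph, vids) {
  e <- graph$edges[graph$edges[, 1] %in% vids & graph$edges[, 2] %in% vids,
                   , drop = FALSE]
  ig <- igraph::make_graph(t(matrix(match(as.vector(e), vids), ncol = 2)),
                           n = length(vids), directed = FALSE)
  igraph::components(ig)$no == 1
}

# a 1-D path graph as a surface_graph (spacing mm between neighbours)
path_graph <- function(n, spacing = 1) {
  coords <- cbind(ap = (seq_len(n) - 1) * spacing, dv = rep(0, n))
  edges <- cbind(seq_len(n - 1), 2:n)
  structure(list(
    n_vertices = n, coords = coords, edges = edges,
    edge_lengths = rep(spacing, n - 1),
    masks = list(hemisphere = rep(TRUE, n),
                 frontal_roi = rep(FALSE, n),
                 parietal_roi = rep(FALSE, n),
                 other = rep(TRUE, n)),
    spacing_mm = spacing, seed = NA_integer_
  ), class = "surface_graph")
}

# largest principal angle (radians) between the column spans of A and B,
# via the sine form (stable for near-identical subspaces)
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  resid <- qb - qa %*% crossprod(qa, qb)
  asin(min(1, max(svd(resid, nu = 0, nv = 0)$d)))
}

# planted family of each exemplar of a parcellation
fam_of_exemplars <- function(parc, truth)
  truth$family_of[truth$parcel_of[parc$exemplar_vertices]]

# ten high-SNR paired-family pipeline runs, computed once and shared by
# the family-recovery, pairing and gradient checks
.run_cache <- new.env(parent = emptyenv())
paired_family_runs <- function() {
  if (is.null(.run_cache$paired)) {
    .run_cache$paired <- lapply(1:10, function(s) {
      cfg <- pipeline_config(T = 2000L, a = 0.3, b = 0.4, n_subjects = 2L,
                             seed = 200L + s)
      run_pipeline(cfg, file.path(tempdir(), paste0("paired", s)))
    })
  }
  .run_cache$paired
}
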