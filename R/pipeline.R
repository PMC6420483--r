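# End-to-end orchestration: simulate (or load) -> preprocess ->
# parcellate both ROIs -> connectional-family hierarchy -> affinity and
# gradient summaries, with every intermediate artifact written to a run
# directory together with a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All stochastic stages
#' draw from explicit seeds derived from `seed`, so a configuration fixes
#' the run exactly.
#'
#' @param n_per_roi,n_other,spacing_mm Geometry of the synthetic surface.
#' @param K_frontal,K_parietal,n_families,coupling_spec,a,b Planted
#'   structure (see [plant_parcels()]).
#' @param n_subjects,T,n_nuisance Simulation sizes (see [synth_config()]).
#' @param detrend_order Polynomial detrending order.
#' @param sigma_mm Surface smoothing width; 0 (default) disables
#'   smoothing — planted parcels have sharp boundaries, so smoothing is
#'   only useful when emulating measurement blur deliberately.
#' @param migp_dim MIGP internal dimension (default `min(200, total T)`).
#' @param preference `"auto"` (the min(S) - (max(S) - min(S)) rule) or a
#'   numeric override.
#' @param damping,max_iter,conv_iter Affinity-propagation settings.
#' @param k_range Branch counts to export (default 2:9, clamped to the
#'   number of exemplars).
#' @param k_frontal_family,k_parietal_family Family level (branch count)
#'   per axis used for the affinity-matrix stage; defaults match the
#'   default planted family count. Analyses of real cortical data choose
#'   these by inspecting where branches disintegrate into single regions.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_roi = 100L, n_other = 50L,
                            spacing_mm = 1, K_frontal = 6L,
                            K_parietal = 6L, n_families = 3L,
                            coupling_spec = "paired", a = 0.25, b = 0.45,
                            n_subjects = 3L, T = 1000L, n_nuisance = 2L,
                            detrend_order = 2L, sigma_mm = 0,
                            migp_dim = NULL, preference = "auto",
                            damping = 0.9, max_iter = 1000L,
                            conv_iter = 100L, k_range = 2:9,
                            k_frontal_family = n_families,
                            k_parietal_family = n_families,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!identical(preference, "auto") && !is.numeric(preference))
    stop("preference must be \"auto\" or numeric")
  if (k_frontal_family > K_frontal || k_parietal_family > K_parietal)
    stop("family level exceeds the planted parcel count")
  if (n_families > min(K_frontal, K_parietal))
    stop("n_families must not exceed the parcel counts")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline into a directory
#'
#' Executes simulate -> preprocess -> parcellate -> hierarchy -> affinity
#' with the given configuration, writing every intermediate artifact
#' under `out_dir` plus `manifest.json` recording all resolved parameters
#' and seeds (no timestamps, so identical configurations give
#' byte-identical manifests). A stage failure aborts with the stage name;
#' artifacts of completed stages remain on disk.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Run directory (created if needed).
#' @return Invisible list with the in-memory artifacts (`graph`, `truth`,
#'   `connectome`, `frontal`, `parietal`, `exemplars`, `dendrograms`,
#'   `families`, `affinity`, `peaks`, `gradients`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  cat("pipeline run\n", file = logf)
  note <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  stage <- function(name, expr) {
    note("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    graph <- make_geometry(cfg$n_per_roi, cfg$n_other, cfg$spacing_mm,
                           seed = cfg$seed)
    truth <- plant_parcels(graph, cfg$K_frontal, cfg$K_parietal,
                           cfg$n_families, cfg$coupling_spec,
                           a = cfg$a, b = cfg$b, seed = cfg$seed + 1L)
    scfg <- synth_config(cfg$n_subjects, cfg$T, cfg$n_nuisance,
                         seed = cfg$seed + 2L)
    dat <- simulate_subject_timeseries(graph, truth, scfg)
    write_surface_graph(graph, file.path(out_dir, "graph"))
    jsonlite::write_json(
      list(parcel_of_0based = ifelse(is.na(truth$parcel_of), -1L,
                                     truth$parcel_of - 1L),
           family_of = truth$family_of, coupling = truth$coupling,
           variance_shares = as.list(truth$variance_shares),
           coupling_spec = truth$coupling_spec),
      file.path(out_dir, "ground_truth.json"), digits = NA)
    for (i in seq_along(dat$subjects))
      write_timeseries(dat$subjects[[i]],
                       file.path(out_dir, sprintf("sub%02d.tsv", i)))
    list(graph = graph, truth = truth, dat = dat)
  })

  # --- preprocess -----------------------------------------------------
  conn <- stage("preprocess", {
    cleaned <- lapply(seq_along(sim$dat$subjects), function(i) {
      ts <- clean_timeseries(sim$dat$subjects[[i]],
                             nuisance = sim$dat$nuisance[[i]],
                             detrend_order = cfg$detrend_order)
      if (cfg$sigma_mm > 0) ts <- smooth_on_graph(ts, sim$graph, cfg$sigma_mm)
      ts
    })
    grp <- migp_reduce(cleaned, internal_dim = cfg$migp_dim,
                       subject_order_seed = cfg$seed + 3L)
    note("migp dim: ", ncol(grp$values))
    cn <- dense_connectome(grp, sim$graph$masks$hemisphere)
    write_connectome(cn, file.path(out_dir, "connectome.tsv"))
    cn
  })

  # --- parcellate -----------------------------------------------------
  parcs <- stage("parcellate", {
    out <- list()
    for (roi in c("frontal", "parietal")) {
      prof <- roi_profiles(conn, sim$graph$masks[[paste0(roi, "_roi")]])
      S <- similarity_matrix(prof)
      pref <- if (identical(cfg$preference, "auto")) default_preference(S)
              else cfg$preference
      p <- affinity_propagation(S, pref, damping = cfg$damping,
                                max_iter = cfg$max_iter,
                                conv_iter = cfg$conv_iter,
                                seed = cfg$seed + 4L,
                                vertex_ids = prof$roi_vertex_ids)
      note(roi, ": ", p$n_clusters, " clusters, preference ", pref,
           ", converged ", p$converged)
      write_parcellation(p, file.path(out_dir, paste0("parcellation_", roi)))
      out[[roi]] <- p
    }
    out
  })

  # --- hierarchy ------------------------------------------------------
  hier <- stage("hierarchy", {
    M <- exemplar_matrix(conn, parcs$frontal, parcs$parietal)
    write_tsv_matrix(M$values, file.path(out_dir, "exemplar_matrix.tsv"))
    dendros <- list()
    families <- list()
    for (ax in c("frontal", "parietal")) {
      kfam <- cfg[[paste0("k_", ax, "_family")]]
      n_ex <- if (ax == "frontal") nrow(M$values) else ncol(M$values)
      if (kfam > n_ex)
        stop("family level k=", kfam, " exceeds the ", n_ex,
             " ", ax, " exemplars")
      d <- hierarchical_cluster(M, ax)
      write_dendrogram(d, file.path(out_dir, paste0("dendrogram_", ax)))
      for (k in intersect(cfg$k_range, seq_len(n_ex)))
        write_branches(cut_branches(d, k),
                       file.path(out_dir, sprintf("branches_%s_k%02d.csv",
                                                  ax, k)))
      dendros[[ax]] <- d
      families[[ax]] <- cut_branches(d, kfam)
    }
    list(M = M, dendros = dendros, families = families)
  })

  # --- affinity -------------------------------------------------------
  aff <- stage("affinity", {
    A <- branch_affinity_matrix(hier$M, hier$families$frontal,
                                hier$families$parietal)
    utils::write.csv(A$values, file.path(out_dir, "affinity_matrix.csv"),
                     row.names = FALSE)
    pk <- peak_connections(A)
    utils::write.csv(pk, file.path(out_dir, "peak_connections.csv"),
                     row.names = FALSE)
    grads <- list()
    for (ax in c(1L, 2L)) {
      seeds <- family_seed_exemplars(parcs$frontal, hier$families$frontal,
                                     sim$graph, axis = ax)
      grads[[c("anterior_posterior", "dorsal_ventral")[ax]]] <-
        if (length(seeds) >= 3)
          gradient_order_stat(conn, sim$graph, seeds,
                              sim$graph$masks$parietal_roi,
                              seed_axis = ax, target_axis = ax)
        else NULL
    }
    jsonlite::write_json(
      lapply(Filter(Negate(is.null), grads), function(g)
        list(seed_ids_0based = g$seed_ids - 1L,
             peak_vertices_0based = g$peak_vertices - 1L,
             rank_correlation = g$rank_correlation,
             degenerate = g$degenerate)),
      file.path(out_dir, "gradients.json"), auto_unbox = TRUE, digits = NA)
    list(A = A, peaks = pk, gradients = grads)
  })

  manifest <- list(
    package = "parcfam",
    version = as.character(utils::packageVersion("parcfam")),
    config = unclass(cfg),
    resolved = list(
      preference_frontal = parcs$frontal$preference,
      preference_parietal = parcs$parietal$preference,
      n_clusters_frontal = parcs$frontal$n_clusters,
      n_clusters_parietal = parcs$parietal$n_clusters,
      migp_dim = if (is.null(cfg$migp_dim)) "min(200, total T)" else cfg$migp_dim,
      seeds = list(geometry = cfg$seed, parcels = cfg$seed + 1L,
                   timeseries = cfg$seed + 2L, migp_order = cfg$seed + 3L,
                   ap_jitter = cfg$seed + 4L)
    ),
    artifacts = sort(setdiff(list.files(out_dir, recursive = TRUE),
                             "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(graph = sim$graph, truth = sim$truth, connectome = conn,
                 frontal = parcs$frontal, parietal = parcs$parietal,
                 exemplars = hier$M, dendrograms = hier$dendros,
                 families = hier$families, affinity = aff$A,
                 peaks = aff$peaks, gradients = aff$gradients,
                 manifest = manifest))
}

# one seed exemplar per branch: the member exemplar with the median
# position along `axis`; branches whose position duplicates an earlier
# one are dropped so that gradient seeds have distinct positions
family_seed_exemplars <- function(parc, fam, graph, axis) {
  seeds <- vapply(seq_len(fam$k), function(br) {
    ex <- fam$leaf_ids[fam$branch_of == br]
    pos <- graph$coords[ex, axis]
    ex[order(pos)][ceiling(length(ex) / 2)]
  }, integer(1))
  keep <- !duplicated(graph$coords[seeds, axis])
  seeds[keep]
}
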