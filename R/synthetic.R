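# Synthetic surface geometry and time series with planted connectivity
# structure: parcels, connectional families, cross-ROI couplings, axis
# gradients and nuisance signals. The closed-form expected connectome is
# the oracle every downstream stage is validated against.

#' Build a synthetic surface graph with two ROIs
#'
#' Constructs a surface-like vertex graph made of three rectangular
#' lattice patches: a frontal ROI, a parietal ROI and an optional block of
#' "rest of hemisphere" vertices. Coordinates are in mm; axis 1 is the
#' anterior--posterior axis (larger = more anterior) and axis 2 the
#' dorsal--ventral axis (larger = more dorsal). Edges connect 4-neighbour
#' lattice cells within a patch; each ROI is therefore connected.
#'
#' @param n_per_roi Number of vertices in each ROI (>= 4). The patch is the
#'   most square `r x c` lattice with `r * c = n_per_roi`.
#' @param n_other Number of non-ROI hemisphere vertices (>= 0).
#' @param spacing_mm Lattice spacing in mm (> 0).
#' @param seed Integer seed; the construction is deterministic, the seed is
#'   retained in the object for provenance.
#' @return A `surface_graph`: list with `n_vertices`, `coords` (n x 2,
#'   columns `ap`, `dv`), `edges` (m x 2 integer), `edge_lengths` (mm) and
#'   `masks` (logical vectors `hemisphere`, `frontal_roi`, `parietal_roi`,
#'   `other`).
#' @export
make_geometry <- function(n_per_roi, n_other = 50, spacing_mm = 1, seed = 1L) {
  if (n_per_roi < 4) stop("n_per_roi must be >= 4")
  if (n_other < 0) stop("n_other must be >= 0")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")

  roi_dims <- best_grid(n_per_roi)

  # parietal posterior (low ap), frontal anterior (high ap), 20 mm gap
  parietal <- lattice_patch(roi_dims[1], roi_dims[2], spacing_mm,
                            offset = c(0, 0))
  frontal <- lattice_patch(roi_dims[1], roi_dims[2], spacing_mm,
                           offset = c((roi_dims[2] + 20) * spacing_mm, 0))
  patches <- list(parietal = parietal, frontal = frontal)
  if (n_other > 0) {
    od <- best_grid(n_other)
    patches$other <- lattice_patch(od[1], od[2], spacing_mm,
                                   offset = c(0, -(od[1] + 20) * spacing_mm))
  }

  coords <- NULL
  edges <- NULL
  labels <- character(0)
  off <- 0L
  for (nm in names(patches)) {
    p <- patches[[nm]]
    coords <- rbind(coords, p$coords)
    if (nrow(p$edges) > 0) edges <- rbind(edges, p$edges + off)
    labels <- c(labels, rep(nm, nrow(p$coords)))
    off <- off + nrow(p$coords)
  }
  colnames(coords) <- c("ap", "dv")
  n <- nrow(coords)
  edge_lengths <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                                coords[edges[, 2], , drop = FALSE])^2))

  g <- structure(list(
    n_vertices = n,
    coords = coords,
    edges = edges,
    edge_lengths = edge_lengths,
    masks = list(
      hemisphere = rep(TRUE, n),
      frontal_roi = labels == "frontal",
      parietal_roi = labels == "parietal",
      other = labels == "other"
    ),
    spacing_mm = spacing_mm,
    seed = as.integer(seed)
  ), class = "surface_graph")
  g
}

# most square factorization r x c of n with r <= c
best_grid <- function(n) {
  r <- max(Filter(function(d) n %% d == 0, seq_len(floor(sqrt(n)))))
  c(r, n / r)
}

# a r x c lattice patch: coords + 4-neighbour edges, 1-based local indices
lattice_patch <- function(nr, nc, spacing, offset) {
  idx <- function(r, c) (c - 1L) * nr + r
  coords <- cbind(
    ap = rep(seq_len(nc) - 1L, each = nr) * spacing + offset[1],
    dv = rep(seq_len(nr), times = nc - 0L) * spacing - spacing + offset[2]
  )
  e <- list()
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (rr < nr) e[[length(e) + 1L]] <- c(idx(rr, cc), idx(rr + 1L, cc))
      if (cc < nc) e[[length(e) + 1L]] <- c(idx(rr, cc), idx(rr, cc + 1L))
    }
  }
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(0), 0, 2)
  list(coords = coords, edges = edges)
}

#' @export
print.surface_graph <- function(x, ...) {
  cat("surface_graph:", x$n_vertices, "vertices,", nrow(x$edges), "edges\n")
  cat("  frontal ROI:", sum(x$masks$frontal_roi),
      " parietal ROI:", sum(x$masks$parietal_roi),
      " other:", sum(x$masks$other), "\n")
  invisible(x)
}

#' Plant parcels, families and couplings on a surface graph
#'
#' Divides each ROI into `n_families` contiguous bands along an anatomical
#' axis, grows spatially contiguous parcels inside each band by
#' synchronized breadth-first region growing from seeded start vertices,
#' and builds a family-by-family coupling matrix of latent-signal
#' correlations.
#'
#' Two coupling specifications are provided. `"paired"` orders families
#' along the dorsal--ventral axis in both ROIs (same direction) and gives
#' each frontal family one strongest parietal partner (its band-order
#' match), emulating parallel dorsal--ventral pathways. `"gradient"` orders
#' frontal families from posterior to anterior and parietal families from
#' anterior to posterior and couples them with a banded fall-off,
#' emulating core--shell organization (regions progressively farther from
#' the central sulcus connect to each other).
#'
#' @param graph A `surface_graph`.
#' @param K_frontal,K_parietal Planted parcel counts per ROI.
#' @param n_families Families per ROI (`<= min(K_frontal, K_parietal)`).
#' @param coupling_spec `"paired"` or `"gradient"`.
#' @param strong Peak cross-ROI family coupling. Defaults: 0.8 (paired),
#'   0.5 (gradient); the gradient peak is lower so that the full coupling
#'   matrix stays positive semi-definite.
#' @param weak Off-partner coupling under `"paired"` (default 0.05).
#' @param decay Per-band multiplicative fall-off under `"gradient"`
#'   (default 0.3).
#' @param a,b Variance shares of the family and parcel latents
#'   (`a, b >= 0`, `a + b <= 1`); the remainder is i.i.d. vertex noise.
#' @param seed Integer seed for parcel-seed sampling.
#' @return A `ground_truth`: `parcel_of` (vertex -> global parcel id, NA
#'   outside the ROIs; frontal parcels come first), `family_of` (parcel ->
#'   global family id; frontal families `1..n_families`), `roi_of_parcel`,
#'   `coupling` (2`n_families` square, symmetric, unit diagonal),
#'   `variance_shares = c(a, b)`, and `axis_order` (family ids of each ROI
#'   in increasing-axis order, with the axis used).
#' @export
plant_parcels <- function(graph, K_frontal, K_parietal, n_families,
                          coupling_spec = c("paired", "gradient"),
                          strong = NULL, weak = 0.05, decay = 0.3,
                          a = 0.25, b = 0.45, seed = 1L) {
  coupling_spec <- match.arg(coupling_spec)
  if (is.null(strong)) strong <- if (coupling_spec == "paired") 0.8 else 0.5
  nf <- sum(graph$masks$frontal_roi)
  np <- sum(graph$masks$parietal_roi)
  if (K_frontal < 1 || K_frontal > nf) stop("K_frontal out of range for ROI")
  if (K_parietal < 1 || K_parietal > np) stop("K_parietal out of range for ROI")
  if (n_families < 1 || n_families > min(K_frontal, K_parietal))
    stop("n_families must be in 1..min(K_frontal, K_parietal)")
  if (a < 0 || b < 0 || a + b > 1) stop("variance shares must satisfy a,b >= 0, a+b <= 1")

  # families are contiguous coordinate bands: dorsal-ventral for "paired",
  # anterior-posterior for "gradient" (with the parietal order reversed so
  # anterior frontal pairs with posterior parietal)
  axis <- if (coupling_spec == "paired") 2L else 1L

  parcel_of <- rep(NA_integer_, graph$n_vertices)
  family_of <- integer(0)
  roi_of_parcel <- character(0)
  axis_order <- list()
  next_parcel <- 0L

  withr::with_seed(as.integer(seed), {
    for (roi in c("frontal", "parietal")) {
      mask <- graph$masks[[paste0(roi, "_roi")]]
      vids <- which(mask)
      K <- if (roi == "frontal") K_frontal else K_parietal
      fam_base <- if (roi == "frontal") 0L else n_families
      reverse <- (coupling_spec == "gradient" && roi == "parietal")

      # parcels per family, as even as possible
      per_fam <- rep(K %/% n_families, n_families)
      if (K %% n_families > 0) per_fam[seq_len(K %% n_families)] <-
          per_fam[seq_len(K %% n_families)] + 1L

      # bands are groups of whole coordinate levels along the axis, so
      # the families occupy disjoint axis ranges (gradients stay exact)
      ord <- vids[order(graph$coords[vids, axis], vids)]
      coordv <- graph$coords[ord, axis]
      u <- unique(coordv)
      if (length(u) < n_families)
        stop("fewer distinct axis coordinates than families")
      band_idx <- ceiling(match(coordv, u) * n_families / length(u))
      if (any(tabulate(band_idx, n_families) < per_fam))
        stop("ROI too small to hold ", K, " parcels in ", n_families,
             " bands")
      fam_rank <- if (reverse) rev(seq_len(n_families)) else seq_len(n_families)

      for (f in seq_len(n_families)) {
        band <- ord[band_idx == f]
        labs <- grow_parcels(graph, band, per_fam[f],
                             chunk_axis = 3L - axis)
        for (k in seq_len(per_fam[f])) {
          next_parcel <- next_parcel + 1L
          parcel_of[band[labs == k]] <- next_parcel
          family_of[next_parcel] <- fam_base + fam_rank[f]
          roi_of_parcel[next_parcel] <- roi
        }
      }
      axis_order[[roi]] <- fam_base + seq_len(n_families)
      if (reverse) axis_order[[roi]] <- rev(axis_order[[roi]])
    }
  })
  axis_order$axis <- axis

  coupling <- build_coupling(n_families, coupling_spec, strong, weak, decay)

  structure(list(
    parcel_of = parcel_of,
    family_of = family_of,
    roi_of_parcel = roi_of_parcel,
    coupling = coupling,
    variance_shares = c(a = a, b = b),
    axis_order = axis_order,
    coupling_spec = coupling_spec,
    n_families = n_families,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

# synchronized breadth-first region growing from K seeds inside `band`;
# ties broken by lowest vertex index; returns per-band-vertex labels 1..K.
# Seeds sit at the centroids of K even contiguous chunks of the band
# along `chunk_axis`, so planted parcels have comparable sizes, as
# cortical parcels do; clumped seeds would plant degenerate slivers whose
# connectivity signature no clustering could separate.
grow_parcels <- function(graph, band, K, chunk_axis = 1L) {
  if (K == 1) return(rep(1L, length(band)))
  adj <- adjacency_list(graph)
  pos <- integer(graph$n_vertices)
  pos[band] <- seq_along(band)
  lab <- rep(0L, length(band))
  ord <- band[order(graph$coords[band, chunk_axis], band)]
  chunk <- ceiling(seq_along(ord) * K / length(ord))
  seeds <- vapply(seq_len(K), function(k) {
    vs <- ord[chunk == k]
    ctr <- colMeans(graph$coords[vs, , drop = FALSE])
    d <- rowSums((graph$coords[vs, , drop = FALSE] -
                  matrix(ctr, length(vs), 2, byrow = TRUE))^2)
    vs[which.min(d)]
  }, numeric(1))
  seeds <- sort(as.integer(seeds))
  lab[pos[seeds]] <- seq_len(K)
  while (any(lab == 0L)) {
    frontier <- band[lab == 0L]
    assigned <- FALSE
    new_lab <- lab
    for (v in sort(frontier)) {
      nb <- adj[[v]]
      nb <- nb[nb %in% band]
      nb <- nb[lab[pos[nb]] > 0L]
      if (length(nb)) {
        new_lab[pos[v]] <- lab[pos[min(nb)]]
        assigned <- TRUE
      }
    }
    lab <- new_lab
    if (!assigned) {
      # disconnected remainder: attach to nearest labelled band vertex
      done <- band[lab > 0L]
      for (v in band[lab == 0L]) {
        d <- (graph$coords[done, 1] - graph$coords[v, 1])^2 +
          (graph$coords[done, 2] - graph$coords[v, 2])^2
        lab[pos[v]] <- lab[pos[done[which.min(d)]]]
      }
    }
  }
  lab
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n_vertices)
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  adj
}

# family coupling over 2F families: identity within each ROI, cross-ROI
# block R by spec; validated positive semi-definite
build_coupling <- function(F, spec, strong, weak, decay) {
  R <- if (spec == "paired") {
    matrix(weak, F, F) + diag(strong - weak, F)
  } else {
    strong * decay^abs(outer(seq_len(F), seq_len(F), "-"))
  }
  C <- rbind(cbind(diag(F), R), cbind(t(R), diag(F)))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("coupling matrix is not positive semi-definite; lower `strong`")
  C
}

#' Synthetic-data configuration
#'
#' @param n_subjects Subjects to simulate (>= 1).
#' @param T Timepoints per subject (>= 2).
#' @param n_nuisance Planted confound series per subject (>= 0); they
#'   emulate dominant non-neural signals (CSF/white-matter time courses).
#' @param nuisance_sd Standard deviation of the per-vertex nuisance
#'   loadings.
#' @param seed Integer seed; fixes all randomness of the simulation.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 3L, T = 1000L, n_nuisance = 2L,
                         nuisance_sd = 0.5, seed = 1L) {
  stopifnot(n_subjects >= 1, T >= 2, n_nuisance >= 0, nuisance_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), T = as.integer(T),
                 n_nuisance = as.integer(n_nuisance),
                 nuisance_sd = nuisance_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate multi-subject vertex time series
#'
#' For an ROI vertex in parcel \eqn{p} of family \eqn{f}, the signal is
#' \deqn{x_v(t) = \sqrt{a}\, g_f(t) + \sqrt{b}\, h_p(t) +
#'   \sqrt{1-a-b}\, \epsilon_v(t)}
#' where family latents \eqn{g} are mixed across ROIs so that their
#' population correlation matrix equals the planted coupling exactly,
#' parcel latents \eqn{h} and noise \eqn{\epsilon} are independent, and all
#' series are unit-variance Gaussian i.i.d. over time. Non-ROI vertices
#' carry pure noise. Planted nuisance series are added on top with
#' per-vertex Gaussian loadings drawn once per subject.
#'
#' @param graph A `surface_graph`.
#' @param truth A `ground_truth` from [plant_parcels()].
#' @param cfg A `synth_config`.
#' @return List with `subjects` (list of `timeseries_matrix`) and
#'   `nuisance` (list of `T x n_nuisance` matrices, one per subject).
#' @export
simulate_subject_timeseries <- function(graph, truth, cfg) {
  a <- truth$variance_shares[["a"]]
  b <- truth$variance_shares[["b"]]
  if (a + b > 1) stop("variance shares a + b exceed 1")
  n <- graph$n_vertices
  Tt <- cfg$T
  nfam <- nrow(truth$coupling)
  npar <- length(truth$family_of)

  # mixing root of the coupling: latents = Z %*% t(M), cov = M M' = C
  eg <- eigen(truth$coupling, symmetric = TRUE)
  M <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nfam)

  in_roi <- !is.na(truth$parcel_of)
  fam_v <- ifelse(in_roi, truth$family_of[truth$parcel_of], NA_integer_)

  subjects <- vector("list", cfg$n_subjects)
  nuisance <- vector("list", cfg$n_subjects)
  withr::with_seed(cfg$seed, {
    for (s in seq_len(cfg$n_subjects)) {
      G <- matrix(rnorm(Tt * nfam), Tt, nfam) %*% t(M)   # T x families
      H <- matrix(rnorm(Tt * npar), Tt, npar)            # T x parcels
      E <- matrix(rnorm(n * Tt), n, Tt)

      X <- sqrt(1 - ifelse(in_roi, a + b, 0)) * E
      X[in_roi, ] <- X[in_roi, ] +
        sqrt(a) * t(G[, fam_v[in_roi], drop = FALSE]) +
        sqrt(b) * t(H[, truth$parcel_of[in_roi], drop = FALSE])

      if (cfg$n_nuisance > 0) {
        N <- matrix(rnorm(Tt * cfg$n_nuisance), Tt, cfg$n_nuisance)
        L <- matrix(rnorm(n * cfg$n_nuisance, sd = cfg$nuisance_sd),
                    n, cfg$n_nuisance)
        X <- X + L %*% t(N)
        nuisance[[s]] <- N
      } else {
        nuisance[[s]] <- matrix(numeric(0), Tt, 0)
      }
      subjects[[s]] <- timeseries_matrix(X, seq_len(n),
                                         subject_id = paste0("sub", s))
    }
  })
  list(subjects = subjects, nuisance = nuisance)
}

#' Population connectome implied by the generative model
#'
#' Closed-form Pearson correlations of the noise-free limit of
#' [simulate_subject_timeseries()] (nuisance excluded, i.e. the
#' correlation structure after perfect confound removal): 1 on the
#' diagonal; `a + b` within a parcel; `a` across parcels of one family;
#' `a * coupling[f, g]` across families; 0 whenever a non-ROI vertex is
#' involved.
#'
#' @param truth A `ground_truth`.
#' @return A `dense_connectome` over all vertices.
#' @export
expected_connectome <- function(truth) {
  n <- length(truth$parcel_of)
  a <- truth$variance_shares[["a"]]
  b <- truth$variance_shares[["b"]]
  in_roi <- !is.na(truth$parcel_of)
  fam <- ifelse(in_roi, truth$family_of[truth$parcel_of], 0L)

  C <- matrix(0, n, n)
  roi <- which(in_roi)
  # across families (includes within-family via unit diagonal of coupling)
  C[roi, roi] <- a * truth$coupling[cbind(
    rep(fam[roi], times = length(roi)),
    rep(fam[roi], each = length(roi)))]
  same_parcel <- outer(truth$parcel_of[roi], truth$parcel_of[roi], "==")
  C[roi, roi][same_parcel] <- C[roi, roi][same_parcel] + b
  diag(C) <- 1
  dense_connectome_object(C, seq_len(n))
}
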