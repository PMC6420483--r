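# Large-scale organization summaries: branch-level affinity matrices,
# peak connections between branches, seed connectivity maps, and Spearman
# gradient statistics along anatomical axes.

#' Branch-level affinity matrix
#'
#' Entry (F, P) is the mean exemplar-matrix correlation over all frontal
#' exemplars in branch F and all parietal exemplars in branch P — the
#' average connectivity strength of the two connectional families. Raw
#' correlation coefficients are averaged by default; set
#' `fisher_z = TRUE` to average on the z scale and back-transform.
#'
#' @param M An `exemplar_matrix`.
#' @param fb,pb `branch_solution`s over the rows / columns of `M`.
#' @param fisher_z Average correlations on the Fisher z scale (default
#'   FALSE).
#' @return An `affinity_matrix`: `values`
#'   (n_frontal_branches x n_parietal_branches), plus both branch
#'   memberships.
#' @export
branch_affinity_matrix <- function(M, fb, pb, fisher_z = FALSE) {
  if (length(fb$branch_of) != nrow(M$values) ||
      length(pb$branch_of) != ncol(M$values))
    stop("branch solutions do not match the exemplar matrix")
  kf <- max(fb$branch_of)
  kp <- max(pb$branch_of)
  if (!setequal(unique(fb$branch_of), seq_len(kf)) ||
      !setequal(unique(pb$branch_of), seq_len(kp)))
    stop("empty branch in a branch solution")
  vals <- M$values
  if (fisher_z) vals <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
  A <- matrix(0, kf, kp)
  for (i in seq_len(kf)) for (j in seq_len(kp)) {
    A[i, j] <- mean(vals[fb$branch_of == i, pb$branch_of == j])
  }
  if (fisher_z) A <- tanh(A)
  structure(list(values = A, frontal_branches = fb$branch_of,
                 parietal_branches = pb$branch_of),
            class = "affinity_matrix")
}

#' Peak connections between branches
#'
#' For each frontal branch, the parietal branch with maximum affinity
#' (the arrows of a branch-connectivity diagram). Ties go to the lowest
#' branch id and are flagged.
#'
#' @param A An `affinity_matrix`.
#' @return Data frame with `frontal_branch`, `parietal_branch`, `tie`.
#' @export
peak_connections <- function(A) {
  V <- A$values
  if (length(V) == 0) stop("empty affinity matrix")
  peaks <- max.col(V, ties.method = "first")
  tie <- vapply(seq_len(nrow(V)), function(i)
    sum(V[i, ] >= V[i, peaks[i]] - 1e-15) > 1, logical(1))
  data.frame(frontal_branch = seq_len(nrow(V)),
             parietal_branch = peaks, tie = tie)
}

#' Seed connectivity map and its peak vertex
#'
#' The connectome row of a seed vertex restricted to a target ROI, with
#' the maximum-connectivity vertex (lowest vertex id on ties). If the
#' seed lies inside the target ROI its self-entry is excluded from the
#' argmax.
#'
#' @param conn A `dense_connectome`.
#' @param seed_vertex Vertex id of the seed (e.g. an exemplar).
#' @param target_roi Logical mask over connectome vertices or integer
#'   vertex ids.
#' @return List with `map` (named correlations over the target) and
#'   `peak` (vertex id).
#' @export
seed_peak_map <- function(conn, seed_vertex, target_roi) {
  si <- match(as.integer(seed_vertex), conn$vertex_ids)
  if (is.na(si)) stop("seed vertex outside the connectome")
  tid <- if (is.logical(target_roi)) conn$vertex_ids[target_roi]
         else as.integer(target_roi)
  ti <- match(tid, conn$vertex_ids)
  if (length(ti) == 0 || anyNA(ti)) stop("empty or invalid target ROI")
  map <- stats::setNames(conn$values[si, ti], tid)
  cand <- map
  cand[tid == seed_vertex] <- -Inf
  peak <- tid[which.max(cand)]
  list(map = map, peak = peak)
}

#' Gradient statistic along an anatomical axis
#'
#' For an ordered set of seed vertices, finds each seed's peak
#' connectivity vertex in the target ROI and computes the Spearman rank
#' correlation between the seeds' positions and the peaks' positions
#' along chosen coordinate axes. Under the documented axis orientation
#' (axis 1 increases towards anterior, axis 2 towards dorsal), a
#' core--shell organization — progressively more anterior frontal seeds
#' peaking at progressively more posterior parietal vertices — appears as
#' a rank correlation of -1 on the anterior--posterior axis, while a
#' same-direction dorsal--ventral progression appears as +1.
#'
#' @param conn A `dense_connectome`.
#' @param graph The `surface_graph` supplying vertex coordinates.
#' @param seed_ids Integer vertex ids of at least 3 seeds.
#' @param target_roi Target ROI mask or vertex ids.
#' @param seed_axis,target_axis Coordinate index (1 =
#'   anterior--posterior, 2 = dorsal--ventral) used for the seed and peak
#'   positions.
#' @return A `gradient_result`: `seed_ids`, `peak_vertices`,
#'   `seed_axis_pos`, `peak_axis_pos` (mm), `rank_correlation`, and
#'   `degenerate` (TRUE when all peaks coincide or either position set is
#'   constant, in which case the correlation is NA).
#' @export
gradient_order_stat <- function(conn, graph, seed_ids, target_roi,
                                seed_axis = 1L, target_axis = 1L) {
  seed_ids <- as.integer(seed_ids)
  if (length(seed_ids) < 3) stop("need at least 3 seeds")
  seed_pos <- graph$coords[seed_ids, seed_axis]
  if (anyDuplicated(seed_pos)) stop("seed axis positions must be distinct")
  peaks <- vapply(seed_ids, function(s)
    seed_peak_map(conn, s, target_roi)$peak, integer(1))
  peak_pos <- graph$coords[peaks, target_axis]
  degenerate <- length(unique(peaks)) == 1 || sd(peak_pos) == 0
  rho <- if (degenerate) NA_real_
         else cor(seed_pos, peak_pos, method = "spearman")
  structure(list(seed_ids = seed_ids, peak_vertices = peaks,
                 seed_axis_pos = seed_pos, peak_axis_pos = peak_pos,
                 rank_correlation = rho, degenerate = degenerate),
            class = "gradient_result")
}
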