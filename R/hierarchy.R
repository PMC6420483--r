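# Connectional families: the frontal-exemplar x parietal-exemplar
# connectivity matrix (fingerprints) and its hierarchical organization
# under Ward linkage on city-block distances.

#' Exemplar-to-exemplar connectivity matrix
#'
#' Entry (i, j) is the dense-connectome correlation between the vertex of
#' frontal exemplar i and the vertex of parietal exemplar j. Rows are the
#' parietal connectivity fingerprints of the frontal exemplars; columns
#' the frontal fingerprints of the parietal exemplars.
#'
#' @param conn A `dense_connectome`.
#' @param frontal,parietal `parcellation` objects whose
#'   `exemplar_vertices` lie in the connectome.
#' @return An `exemplar_matrix`: `values`, `row_ids` (frontal exemplar
#'   vertices), `col_ids` (parietal exemplar vertices).
#' @export
exemplar_matrix <- function(conn, frontal, parietal) {
  fi <- match(frontal$exemplar_vertices, conn$vertex_ids)
  pi <- match(parietal$exemplar_vertices, conn$vertex_ids)
  if (anyNA(fi) || anyNA(pi))
    stop("exemplar vertex outside the connectome")
  structure(list(values = conn$values[fi, pi, drop = FALSE],
                 row_ids = frontal$exemplar_vertices,
                 col_ids = parietal$exemplar_vertices),
            class = "exemplar_matrix")
}

#' @export
print.exemplar_matrix <- function(x, ...) {
  cat("exemplar_matrix:", nrow(x$values), "frontal x",
      ncol(x$values), "parietal exemplars\n")
  invisible(x)
}

#' Hierarchical clustering of exemplar fingerprints
#'
#' Pairwise city-block (Manhattan) distances between the rows (frontal
#' axis) or columns (parietal axis) of the exemplar matrix, agglomerated
#' with the Ward Lance--Williams recurrence applied directly to those
#' distances (`stats::hclust(method = "ward.D")`). Distances are computed
#' on the raw correlation values. A `"euclidean"` switch is provided for
#' comparison.
#'
#' @param M An `exemplar_matrix`.
#' @param axis `"frontal"` (cluster rows) or `"parietal"` (cluster
#'   columns).
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return A `connectional_dendrogram`: the underlying `hclust`, the
#'   merge table, `leaf_ids` (exemplar vertex ids) and `axis`.
#' @export
hierarchical_cluster <- function(M, axis = c("frontal", "parietal"),
                                 metric = c("manhattan", "euclidean")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  X <- if (axis == "frontal") M$values else t(M$values)
  ids <- if (axis == "frontal") M$row_ids else M$col_ids
  if (nrow(X) < 2) stop("need at least 2 items on the chosen axis")
  h <- hclust(dist(X, method = metric), method = "ward.D")
  structure(list(
    hclust = h,
    merges = data.frame(node_a = h$merge[, 1], node_b = h$merge[, 2],
                        height = h$height,
                        new_node = seq_len(nrow(h$merge))),
    leaf_ids = as.integer(ids),
    axis = axis,
    metric = metric
  ), class = "connectional_dendrogram")
}

#' @export
print.connectional_dendrogram <- function(x, ...) {
  cat("connectional_dendrogram (", x$axis, "): ",
      length(x$leaf_ids), " leaves, ", x$metric, "/Ward\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k branches
#'
#' Undoes the last k - 1 merges of the tree. Branch ids are numbered by
#' dendrogram leaf order (left to right), and `split_trace` reports which
#' branch of the (k-1)-branch solution divided to create this one.
#'
#' @param d A `connectional_dendrogram`.
#' @param k Branch count in `1..n_leaves`.
#' @return A `branch_solution`: `k`, `branch_of` (per leaf, named by
#'   exemplar vertex id), `split_trace` (NA for k = 1).
#' @export
cut_branches <- function(d, k) {
  n <- length(d$leaf_ids)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  branch_of <- relabel_by_leaf_order(cutree(d$hclust, k), d$hclust$order)
  split_trace <- NA_integer_
  if (k > 1) {
    prev <- relabel_by_leaf_order(cutree(d$hclust, k - 1), d$hclust$order)
    tab <- table(prev, branch_of)
    split_trace <- as.integer(rownames(tab)[rowSums(tab > 0) > 1])
  }
  structure(list(k = as.integer(k),
                 branch_of = stats::setNames(branch_of, d$leaf_ids),
                 split_trace = split_trace,
                 axis = d$axis,
                 leaf_ids = d$leaf_ids),
            class = "branch_solution")
}

# renumber cluster labels 1..k in order of first appearance along the
# dendrogram leaf order
relabel_by_leaf_order <- function(labels, order) {
  first <- labels[order][!duplicated(labels[order])]
  match(labels, first)
}
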