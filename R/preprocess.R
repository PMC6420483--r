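# Desk-scale functional preprocessing: detrending + nuisance regression,
# geodesic Gaussian smoothing on the surface graph, incremental group PCA
# across subjects, and the dense (vertex x vertex) connectome.

#' Time-series matrix container
#'
#' @param values Vertices x timepoints numeric matrix, no missing values.
#' @param vertex_ids Integer vertex ids aligned to a `surface_graph`.
#' @param subject_id Label, or `"group"` for a group-level matrix.
#' @return A `timeseries_matrix`.
#' @export
timeseries_matrix <- function(values, vertex_ids = seq_len(nrow(values)),
                              subject_id = "subject") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series contain missing values")
  if (length(vertex_ids) != nrow(values)) stop("vertex_ids do not match rows")
  if (anyDuplicated(vertex_ids)) stop("vertex_ids must be unique")
  structure(list(values = values, vertex_ids = as.integer(vertex_ids),
                 subject_id = subject_id), class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat("timeseries_matrix [", x$subject_id, "]: ", nrow(x$values),
      " vertices x ", ncol(x$values), " timepoints\n", sep = "")
  invisible(x)
}

dense_connectome_object <- function(values, vertex_ids) {
  structure(list(values = values, vertex_ids = as.integer(vertex_ids)),
            class = "dense_connectome")
}

#' @export
print.dense_connectome <- function(x, ...) {
  cat("dense_connectome:", nrow(x$values), "x", ncol(x$values), "vertices\n")
  invisible(x)
}

#' Remove drifts and nuisance signals, then normalize
#'
#' Each vertex row is residualized by ordinary least squares against
#' polynomial time trends up to `detrend_order` (order 0 = intercept only)
#' and the supplied nuisance series, then demeaned and scaled to unit
#' variance. Slow scanner drifts are removed by the polynomial terms;
#' confound time courses (e.g. the dominant CSF / white-matter signals) by
#' the nuisance regressors.
#'
#' @param ts A `timeseries_matrix`.
#' @param nuisance Optional timepoints x k matrix of nuisance series.
#' @param detrend_order Highest polynomial order to remove (>= 0,
#'   default 2).
#' @return A `timeseries_matrix` of standardized residuals. Vertices whose
#'   residual variance vanishes are set to all zeros with a warning and
#'   recorded in `attr(, "flagged")`.
#' @export
clean_timeseries <- function(ts, nuisance = NULL, detrend_order = 2L) {
  if (detrend_order < 0) stop("detrend_order must be >= 0")
  Tt <- ncol(ts$values)
  tt <- seq_len(Tt) / Tt
  D <- outer(tt, 0:detrend_order, "^")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != Tt) stop("nuisance series length must equal timepoints")
    D <- cbind(D, nuisance)
  }
  Q <- qr.Q(qr(D))
  resid <- ts$values - (ts$values %*% Q) %*% t(Q)

  s <- apply(resid, 1, sd)
  flagged <- which(s < 1e-12)
  if (length(flagged)) {
    warning(length(flagged), " vertex/vertices with zero residual variance set to 0")
    resid[flagged, ] <- 0
  }
  keep <- setdiff(seq_len(nrow(resid)), flagged)
  resid[keep, ] <- (resid[keep, ] - rowMeans(resid[keep, , drop = FALSE])) /
    s[keep]
  out <- timeseries_matrix(resid, ts$vertex_ids, ts$subject_id)
  attr(out, "flagged") <- ts$vertex_ids[flagged]
  out
}

#' Gaussian smoothing along the surface graph
#'
#' Convolves each timepoint with a Gaussian kernel on geodesic (shortest
#' path over edge lengths) distance, truncated at 3 sigma and
#' row-normalized, so every output value is a convex combination of input
#' values. A vertex disconnected from the rest keeps its own value.
#'
#' @param ts A `timeseries_matrix` over all graph vertices.
#' @param graph A `surface_graph`.
#' @param sigma_mm Kernel width in mm; 0 returns the input unchanged.
#' @return Smoothed `timeseries_matrix`.
#' @export
smooth_on_graph <- function(ts, graph, sigma_mm = 3) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(ts)
  if (nrow(ts$values) != graph$n_vertices)
    stop("time series rows must cover all graph vertices")
  D <- geodesic_distances(graph)
  W <- exp(-D^2 / (2 * sigma_mm^2))
  W[D > 3 * sigma_mm] <- 0
  W <- W / rowSums(W)   # diagonal is exp(0)=1, so rows never sum to 0
  timeseries_matrix(W %*% ts$values, ts$vertex_ids, ts$subject_id)
}

geodesic_distances <- function(graph) {
  ig <- igraph::make_graph(t(graph$edges), n = graph$n_vertices,
                           directed = FALSE)
  igraph::distances(ig, weights = graph$edge_lengths)
}

#' Incremental group PCA across subjects
#'
#' Approximates the principal subspace of the temporal concatenation of
#' all subjects without ever holding it in memory: a running vertices x d
#' approximation is temporally concatenated with each subject in turn and
#' replaced by its top `internal_dim` left singular vectors scaled by
#' their singular values. With `internal_dim` at least the total number of
#' timepoints no truncation occurs and the result spans the exact
#' concatenation PCA subspace.
#'
#' @param subjects List of `timeseries_matrix` sharing `vertex_ids`.
#' @param internal_dim Components retained (default
#'   `min(200, total timepoints)`); capped at the available rank with a
#'   warning.
#' @param subject_order_seed Seed for the random subject fold-in order.
#' @return A group `timeseries_matrix` (vertices x `internal_dim`,
#'   variance-weighted components).
#' @export
migp_reduce <- function(subjects, internal_dim = NULL,
                        subject_order_seed = 1L) {
  vid <- subjects[[1]]$vertex_ids
  for (s in subjects) if (!identical(s$vertex_ids, vid))
    stop("all subjects must share vertex_ids")
  total_T <- sum(vapply(subjects, function(s) ncol(s$values), integer(1)))
  if (is.null(internal_dim)) internal_dim <- min(200L, total_T)
  if (internal_dim < 1) stop("internal_dim must be >= 1")
  if (internal_dim > total_T) {
    warning("internal_dim exceeds total timepoints; capped at ", total_T)
    internal_dim <- total_T
  }
  ord <- withr::with_seed(as.integer(subject_order_seed),
                          sample(seq_along(subjects)))
  W <- NULL
  for (s in ord) {
    M <- cbind(W, subjects[[s]]$values)
    d <- min(internal_dim, ncol(M), nrow(M))
    sv <- svd(M, nu = d, nv = 0)
    W <- sv$u %*% diag(sv$d[seq_len(d)], d)
  }
  out <- timeseries_matrix(W, vid, subject_id = "group")
  attr(out, "subject_order") <- ord
  out
}

#' Dense connectome of the hemisphere
#'
#' Pearson correlation between every pair of masked vertex time courses.
#'
#' @param group_ts A `timeseries_matrix` (typically the MIGP group matrix).
#' @param hemisphere_mask Logical vector over the rows of `group_ts`, or
#'   integer vertex ids to keep; default all rows.
#' @return A `dense_connectome` (symmetric, unit diagonal, entries in
#'   \[-1, 1\]). Zero-variance rows get 0 off-diagonal correlations with a
#'   warning.
#' @export
dense_connectome <- function(group_ts, hemisphere_mask = NULL) {
  vals <- group_ts$values
  vid <- group_ts$vertex_ids
  if (!is.null(hemisphere_mask)) {
    keep <- if (is.logical(hemisphere_mask)) which(hemisphere_mask)
            else match(as.integer(hemisphere_mask), vid)
    if (length(keep) == 0 || anyNA(keep)) stop("empty or invalid hemisphere mask")
    vals <- vals[keep, , drop = FALSE]
    vid <- vid[keep]
  }
  if (ncol(vals) < 2) stop("need at least 2 timepoints/components")
  s <- apply(vals, 1, sd)
  zero <- which(s < 1e-14)
  if (length(zero)) {
    warning(length(zero), " zero-variance vertex/vertices: correlations set to 0")
    # placeholder ramps keep cor() defined; the rows are zeroed below
    vals[zero, ] <- matrix(seq_len(length(zero) * ncol(vals)),
                           length(zero), ncol(vals))
  }
  C <- cor(t(vals))
  if (length(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dense_connectome_object(C, vid)
}
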