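# Connectivity-based parcellation: whole-hemisphere connectivity profiles
# per ROI vertex, profile-similarity matrix, affinity propagation with the
# data-driven preference min(S) - (max(S) - min(S)), an exhaustive-search
# oracle, and clustering validation metrics.

#' Connectivity profiles of ROI vertices
#'
#' Extracts the ROI rows of the dense connectome over all hemisphere
#' columns. The self-correlation entry (value 1) of each ROI vertex is
#' retained.
#'
#' @param conn A `dense_connectome`.
#' @param roi_mask Logical vector over the connectome vertices, or integer
#'   vertex ids.
#' @return A `connectivity_profiles`: `values` (n_roi x n_hemi),
#'   `roi_vertex_ids`, `hemi_vertex_ids`.
#' @export
roi_profiles <- function(conn, roi_mask) {
  rows <- if (is.logical(roi_mask)) {
    if (length(roi_mask) != length(conn$vertex_ids))
      stop("logical roi_mask must match connectome vertices")
    which(roi_mask)
  } else {
    match(as.integer(roi_mask), conn$vertex_ids)
  }
  if (length(rows) == 0) stop("ROI mask selects no vertices")
  if (anyNA(rows)) stop("ROI mask contains vertices outside the connectome")
  structure(list(values = conn$values[rows, , drop = FALSE],
                 roi_vertex_ids = conn$vertex_ids[rows],
                 hemi_vertex_ids = conn$vertex_ids),
            class = "connectivity_profiles")
}

#' Profile-to-profile similarity matrix
#'
#' `S[i, j]` is the Pearson correlation between the connectivity profiles
#' of ROI vertices `i` and `j` (a symmetric cross-correlation matrix).
#' Constant profiles cannot be correlated; their similarities are set to
#' the minimum of the remaining entries, with a warning.
#'
#' @param profiles A `connectivity_profiles` with >= 2 rows.
#' @return Numeric n x n symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(profiles) {
  X <- profiles$values
  if (nrow(X) < 2) stop("need at least 2 profiles")
  s <- apply(X, 1, sd)
  const <- which(s < 1e-14)
  if (length(const)) {
    X[const, ] <- matrix(seq_len(length(const) * ncol(X)),
                         length(const), ncol(X))
  }
  S <- cor(t(X))
  S <- (S + t(S)) / 2
  if (length(const)) {
    warning(length(const), " constant profile(s); similarities set to matrix minimum")
    lo <- min(S[upper.tri(S)][is.finite(S[upper.tri(S)])])
    S[const, ] <- lo
    S[, const] <- lo
    diag(S) <- 1
  }
  S
}

#' Data-driven affinity-propagation preference
#'
#' Returns `min(S) - (max(S) - min(S))`, with the minimum and maximum
#' taken over the off-diagonal entries of the similarity matrix. The same
#' (flat) preference is used for every data point, expressing no prior
#' liking for any vertex to become an exemplar.
#'
#' @param S Symmetric similarity matrix.
#' @return Scalar preference, always below `min(S)`.
#' @export
default_preference <- function(S) {
  off <- S[row(S) != col(S)]
  lo <- min(off); hi <- max(off)
  if (!(hi > lo)) stop("degenerate similarity matrix: max(S) equals min(S)")
  lo - (hi - lo)
}

#' Affinity-propagation clustering with exemplar semantics
#'
#' Message-passing clustering on a similarity matrix: responsibilities
#' \eqn{r(i,k)} and availabilities \eqn{a(i,k)} are iterated with damping
#' until the exemplar set (points with \eqn{r(k,k)+a(k,k) > 0}) is stable
#' for `conv_iter` iterations or `max_iter` is reached. The preference is
#' placed on the diagonal. After convergence, exemplars are refined within
#' each cluster (the member maximizing the summed similarity to the
#' cluster), then the exemplar set is polished by a greedy ascent on the
#' net-similarity objective itself (single-exemplar add, drop and swap
#' moves until no move improves; `polish = FALSE` disables it). Message
#' passing is a heuristic maximizer of net similarity and can stall in
#' local optima near the one-cluster regime; the polish step removes
#' exactly those stalls without changing the objective. Finally every
#' point is assigned to the exemplar with the highest similarity, ties
#' going to the lowest exemplar index.
#'
#' A tiny seeded jitter (magnitude ~1e-12) is added to the similarities
#' by default to break the exact ties that make affinity propagation
#' oscillate on degenerate inputs; disable it when comparing against the
#' exhaustive oracle, whose ties are broken by the documented rule.
#'
#' @param S Symmetric similarity matrix (finite entries).
#' @param preference Scalar diagonal preference; default
#'   [default_preference()].
#' @param damping Message damping in \[0.5, 1).
#' @param max_iter,conv_iter Iteration limits.
#' @param jitter Add tie-breaking noise (default TRUE).
#' @param seed Seed for the jitter.
#' @param polish Greedy net-similarity ascent on the exemplar set after
#'   message passing (default TRUE).
#' @return A `parcellation`: `label_of` (point -> cluster id),
#'   `exemplar_of` (cluster id -> point index), `n_clusters`, `preference`,
#'   `converged`, `iterations`, and `vertex_ids` (caller-supplied point
#'   ids, default `1..n`). Cluster ids are ordered by exemplar index.
#' @param vertex_ids Optional ids for the points (default row indices).
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 1000L, conv_iter = 100L,
                                 jitter = TRUE, seed = 1L,
                                 polish = TRUE, vertex_ids = NULL) {
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (!all(is.finite(S))) stop("similarity matrix must be finite")
  n <- nrow(S)
  if (is.null(preference)) preference <- default_preference(S)
  if (is.null(vertex_ids)) vertex_ids <- seq_len(n)

  s <- S
  diag(s) <- preference
  if (jitter) {
    eps <- withr::with_seed(as.integer(seed),
                            matrix(rnorm(n * n), n, n))
    s <- s + eps * 1e-12 * (max(abs(s)) + 1)
  }

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  exemplars <- integer(0)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L

    # responsibilities
    AS <- A + s
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), i1)]
    AS[cbind(seq_len(n), i1)] <- -Inf
    m2 <- apply(AS, 1, max)
    Rnew <- s - m1
    Rnew[cbind(seq_len(n), i1)] <- s[cbind(seq_len(n), i1)] - m2
    R <- damping * R + (1 - damping) * Rnew

    # availabilities
    Rp <- pmax(R, 0)
    cs <- colSums(Rp)
    Anew <- rep(diag(R), each = n) +
      matrix(cs - diag(Rp), n, n, byrow = TRUE) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) && identical(ex, exemplars)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
      exemplars <- ex
    }
  }
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning current solution")
  if (length(exemplars) == 0)
    exemplars <- which.max(diag(R) + diag(A))

  sol <- assign_to_exemplars(S, exemplars, refine = TRUE)
  if (polish) {
    ex <- greedy_polish(S, sol$exemplars, preference)
    sol <- assign_to_exemplars(S, ex, refine = FALSE)
  }
  parcellation_object(sol$labels, sol$exemplars, vertex_ids,
                      preference = preference, converged = converged,
                      iterations = it, damping = damping)
}

# greedy ascent on the net-similarity objective over exemplar sets.
# Message passing is restarted-polished from three initial sets: its own
# solution plus the best one- and two-exemplar solutions (found by direct
# scan -- the few-cluster boundary is exactly where message passing is
# known to stall in local optima). Each start is ascended by steepest
# single-exemplar add / drop / swap moves until no move improves.
greedy_polish <- function(S, ex, preference, max_sweeps = 100L) {
  n <- nrow(S)
  value <- function(e) {
    v <- preference * length(e)
    non <- setdiff(seq_len(n), e)
    if (length(non))
      v <- v + sum(apply(S[non, e, drop = FALSE], 1, max))
    v
  }

  # best singleton: column sums without the diagonal
  v1 <- colSums(S) - diag(S) + preference
  best1 <- which.max(v1)

  # best pair by O(n^2) scan of vectorized column maxima
  best2 <- NULL
  if (n >= 2) {
    bv2 <- -Inf
    for (i in seq_len(n - 1)) {
      Smax <- pmax(S[, (i + 1):n, drop = FALSE], S[, i])
      vals <- colSums(Smax) - Smax[i, ] -
        Smax[cbind((i + 1):n, seq_len(n - i))] + 2 * preference
      j <- which.max(vals)
      if (vals[j] > bv2) { bv2 <- vals[j]; best2 <- c(i, i + j) }
    }
  }

  ascend <- function(cur) {
    cur <- sort(cur)
    cur_val <- value(cur)
    for (sweep in seq_len(max_sweeps)) {
      best_e <- NULL
      best_v <- cur_val + 1e-12
      if (length(cur) > 1) for (e in cur) {
        cand <- setdiff(cur, e)
        v <- value(cand)
        if (v > best_v) { best_v <- v; best_e <- cand }
      }
      for (j in setdiff(seq_len(n), cur)) {
        cand <- sort(c(cur, j))
        v <- value(cand)
        if (v > best_v) { best_v <- v; best_e <- cand }
        for (e in cur) {
          cand2 <- sort(c(setdiff(cur, e), j))
          v2 <- value(cand2)
          if (v2 > best_v) { best_v <- v2; best_e <- cand2 }
        }
      }
      if (is.null(best_e)) break
      cur <- best_e
      cur_val <- best_v
    }
    list(ex = cur, value = cur_val)
  }

  starts <- list(ex, best1)
  if (!is.null(best2)) starts <- c(starts, list(best2))
  res <- lapply(starts, ascend)
  res[[which.max(vapply(res, `[[`, numeric(1), "value"))]]$ex
}

# assignment by maximum similarity to an exemplar (lowest index on ties),
# with optional within-cluster exemplar refinement
assign_to_exemplars <- function(S, exemplars, refine = TRUE) {
  exemplars <- sort(exemplars)
  n <- nrow(S)
  pick <- function(ex) {
    sub <- S[, ex, drop = FALSE]
    lab <- ex[max.col(sub, ties.method = "first")]  # lowest exemplar on ties
    lab[ex] <- ex   # exemplars belong to themselves
    lab
  }
  lab <- pick(exemplars)
  if (refine) {
    newex <- sort(unique(vapply(exemplars, function(e) {
      members <- which(lab == e)
      if (length(members) == 1) return(members)
      insum <- colSums(S[members, members, drop = FALSE])
      members[which.max(insum)]
    }, integer(1))))
    lab <- pick(newex)
    exemplars <- newex
  }
  list(labels = lab, exemplars = exemplars)
}

parcellation_object <- function(labels, exemplars, vertex_ids,
                                preference = NA_real_, converged = NA,
                                iterations = NA_integer_,
                                damping = NA_real_) {
  exemplars <- sort(exemplars)
  label_of <- match(labels, exemplars)   # cluster ids ordered by exemplar index
  structure(list(
    label_of = label_of,
    exemplar_of = exemplars,
    exemplar_vertices = vertex_ids[exemplars],
    n_clusters = length(exemplars),
    vertex_ids = as.integer(vertex_ids),
    preference = preference,
    damping = damping,
    converged = converged,
    iterations = iterations
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", x$n_clusters, "clusters over",
      length(x$label_of), "vertices",
      if (isTRUE(x$converged)) "(converged)" else "", "\n")
  invisible(x)
}

#' Net similarity of a parcellation
#'
#' The affinity-propagation objective: sum over non-exemplar points of
#' their similarity to their exemplar, plus `preference` times the number
#' of exemplars.
#'
#' @param S Similarity matrix.
#' @param p A `parcellation` over the points of `S`.
#' @param preference Scalar preference.
#' @return Scalar net similarity.
#' @export
net_similarity <- function(S, p, preference) {
  ex <- p$exemplar_of
  idx <- seq_len(nrow(S))
  own <- ex[p$label_of]
  nonex <- setdiff(idx, ex)
  sum(S[cbind(nonex, own[nonex])]) + preference * length(ex)
}

#' Exhaustive-search exemplar oracle
#'
#' Enumerates every non-empty exemplar subset (n <= 12) and returns the
#' one maximizing the net similarity; ties are broken by fewer exemplars,
#' then by the lexicographically smallest set.
#'
#' @param S Similarity matrix.
#' @param preference Scalar preference.
#' @return A `parcellation` at the global optimum of [net_similarity()].
#' @export
brute_force_exemplars <- function(S, preference) {
  n <- nrow(S)
  if (n > 12) stop("exhaustive search limited to n <= 12")
  best <- NULL
  best_val <- -Inf
  tol <- 1e-12
  for (mask in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- preference * length(ex)
    nonex <- setdiff(seq_len(n), ex)
    if (length(nonex))
      val <- val + sum(apply(S[nonex, ex, drop = FALSE], 1, max))
    take <- if (is.null(best)) TRUE
      else if (val > best_val + tol) TRUE
      else if (val >= best_val - tol)
        length(ex) < length(best) ||
          (length(ex) == length(best) && lex_less(ex, best))
      else FALSE
    if (take) {
      best <- ex
      best_val <- val
    }
  }
  sol <- assign_to_exemplars(S, best, refine = FALSE)
  parcellation_object(sol$labels, sol$exemplars, seq_len(n),
                      preference = preference, converged = TRUE,
                      iterations = 0L)
}

lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Clustering validation metrics
#'
#' Davies--Bouldin index, mean silhouette, and a gap statistic for a
#' parcellation of connectivity profiles, all on Euclidean geometry over
#' the profile rows.
#'
#' * Davies--Bouldin: mean over clusters of
#'   \eqn{\max_{j \ne i} (\sigma_i + \sigma_j) / d(c_i, c_j)}, where
#'   \eqn{\sigma} is the mean distance to the cluster centroid (0 for
#'   singletons).
#' * Silhouette: mean over points of \eqn{(b - a)/\max(a, b)}; points in
#'   singleton clusters contribute 0.
#' * Gap: \eqn{\mathrm{mean}_r \log W_r^{ref} - \log W}, where \eqn{W} is
#'   the total within-cluster sum of squared distances to centroids and
#'   each reference draw is `n` points uniform in the per-dimension
#'   bounding box of the profiles, scored against the nearest observed
#'   centroid.
#'
#' @param profiles A `connectivity_profiles` (or plain matrix of points).
#' @param labels Integer cluster labels, or a `parcellation`.
#' @param gap_refs Number of reference draws (default 20).
#' @param seed Seed for the reference draws.
#' @return List with `davies_bouldin`, `silhouette`, `gap`.
#' @export
validation_metrics <- function(profiles, labels, gap_refs = 20L, seed = 1L) {
  X <- if (inherits(profiles, "connectivity_profiles")) profiles$values
       else as.matrix(profiles)
  if (inherits(labels, "parcellation")) labels <- labels$label_of
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")

  cent <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(X[labels == g, , drop = FALSE])))
  sigma <- vapply(seq_len(k), function(g) {
    rows <- which(labels == g)
    if (length(rows) < 2) return(0)
    mean(sqrt(rowSums((X[rows, , drop = FALSE] -
                       matrix(cent[g, ], length(rows), ncol(X), byrow = TRUE))^2)))
  }, numeric(1))

  dc <- as.matrix(dist(cent))
  db <- mean(vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(j)
      (sigma[i] + sigma[j]) / dc[i, j], numeric(1))), numeric(1)))

  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    same <- which(labels == labels[i])
    if (length(same) < 2) return(0)
    ai <- mean(D[i, setdiff(same, i)])
    bi <- min(vapply(setdiff(seq_len(k), labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1)))
    (bi - ai) / max(ai, bi)
  }, numeric(1))

  W <- sum(vapply(seq_len(nrow(X)), function(i)
    sum((X[i, ] - cent[labels[i], ])^2), numeric(1)))
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  wref <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(gap_refs), function(r) {
      Z <- matrix(runif(nrow(X) * ncol(X)), nrow(X)) *
        matrix(hi - lo, nrow(X), ncol(X), byrow = TRUE) +
        matrix(lo, nrow(X), ncol(X), byrow = TRUE)
      d2 <- vapply(seq_len(k), function(g)
        rowSums((Z - matrix(cent[g, ], nrow(Z), ncol(Z), byrow = TRUE))^2),
        numeric(nrow(Z)))
      sum(apply(matrix(d2, nrow(Z)), 1, min))
    }, numeric(1))
  })
  list(davies_bouldin = db,
       silhouette = mean(sil),
       gap = mean(log(wref)) - log(W))
}
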