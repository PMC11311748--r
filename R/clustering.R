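#' Agglomerative hierarchical clustering of prescriptions
#'
#' Runs standard agglomerative clustering on a precomputed Jaccard distance
#' matrix. With complete, average, or single linkage the merge heights are
#' non-decreasing from leaves to root.
#'
#' @param dist_matrix symmetric distance matrix with prescription-id dimnames
#'   (see [jaccard_distance_matrix()]).
#' @param linkage `"complete"` (default), `"average"`, or `"single"`.
#' @return a `stats::hclust` object (n - 1 merges over n leaves) with the
#'   linkage recorded in `$method`.
#' @export
hierarchical_cluster <- function(dist_matrix, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  check_distance_matrix(dist_matrix)
  if (nrow(dist_matrix) < 2L) abort_input("hierarchical clustering needs n >= 2")
  stats::hclust(stats::as.dist(dist_matrix), method = linkage)
}

check_distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort_input("distance matrix must be square")
  if (is.null(rownames(m))) abort_input("distance matrix must carry id dimnames")
  if (max(abs(m - t(m))) > 1e-12) abort_input("distance matrix must be symmetric")
  if (any(diag(m) != 0)) abort_input("distance matrix must have zero diagonal")
  invisible(m)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges, yielding the k-cluster partition.
#'
#' @param tree an `hclust` object from [hierarchical_cluster()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return a [cluster_assignment()] with `method = "hca_cut"`.
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) abort_parameter(sprintf("k must be in [1, %d], got %s", n, k))
  labels <- stats::cutree(tree, k = k)
  cluster_assignment(ids = tree$labels, labels = unname(labels[tree$labels]),
                     method = "hca_cut", seed = NA_integer_)
}

#' Cluster assignment container
#'
#' A labeled partition of prescriptions with provenance: the method that
#' produced it, k, and the random seed (if any).
#'
#' @param ids prescription ids, in corpus order.
#' @param labels integer cluster labels in `1..k`, one per id; every cluster
#'   must be non-empty.
#' @param method one of `"hca_cut"`, `"kmeans"`, `"planted"`, `"manual"`.
#' @param seed integer seed or `NA`.
#' @return an object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(ids, labels, method = "manual", seed = NA_integer_) {
  if (length(ids) != length(labels)) abort_input("ids and labels lengths differ")
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L)) abort_input("labels must be positive integers")
  k <- max(labels)
  if (!setequal(unique(labels), seq_len(k))) {
    abort_input("labels must cover 1..k with every cluster non-empty")
  }
  method <- match.arg(method, c("hca_cut", "kmeans", "planted", "manual"))
  structure(
    list(ids = as.character(ids), labels = labels, k = k, method = method,
         seed = if (is.na(seed)) NA_integer_ else as.integer(seed)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> n=%d k=%d method=%s seed=%s\n",
              length(x$ids), x$k, x$method,
              if (is.na(x$seed)) "none" else x$seed))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Classical (metric) MDS embedding of a distance matrix
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' (eigenvectors scaled by the square root of positive eigenvalues). Used as
#' the default feature space for k-means, since the pipeline's native
#' dissimilarity is a distance matrix, not a coordinate matrix.
#'
#' @param dist_matrix symmetric distance matrix with id dimnames.
#' @param dim number of dimensions to retain, or `NULL` (default) for all
#'   dimensions with positive eigenvalue. A request exceeding the positive
#'   eigenvalue count is clamped with a warning.
#' @return an object of class `mds_embedding`: list with `ids`, `points`
#'   (n x d matrix), and `eig` (all n eigenvalues).
#' @export
classical_mds <- function(dist_matrix, dim = NULL) {
  check_distance_matrix(dist_matrix)
  n <- nrow(dist_matrix)
  # the k = n - 1 request routinely exceeds the positive-eigenvalue count for
  # non-Euclidean dissimilarities; cmdscale warns and returns the valid columns
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist_matrix), k = n - 1L, eig = TRUE)
  )
  tol <- max(abs(fit$eig)) * 1e-9
  n_pos <- sum(fit$eig > tol)
  pts <- fit$points
  keep <- min(n_pos, ncol(pts))
  if (!is.null(dim)) {
    if (dim > keep) {
      warning(sprintf("requested dim=%d exceeds %d positive-eigenvalue dimensions; clamped",
                      dim, keep), call. = FALSE)
    }
    keep <- min(dim, keep)
  }
  pts <- pts[, seq_len(keep), drop = FALSE]
  structure(
    list(ids = rownames(dist_matrix), points = pts, eig = fit$eig),
    class = "mds_embedding"
  )
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' k-means partitioning with seeded initialization
#'
#' Lloyd's algorithm with Forgy initialization: the seed deterministically
#' selects k distinct data points as initial centroids, so one seed is one
#' run, mirroring a seed-sensitivity design. The within-cluster sum of
#' squares is non-increasing across iterations; an empty cluster is repaired
#' by re-seeding it with the point farthest from its current centroid, which
#' keeps k fixed.
#'
#' @param embedding an `mds_embedding` (see [classical_mds()]) or a plain
#'   numeric matrix with id rownames (e.g. raw binary herb vectors).
#' @param k number of clusters, `2 <= k <= n` (k = 1 is allowed and trivial).
#' @param seed integer RNG seed controlling initial centroid choice.
#' @param n_init number of initializations; run `r` uses seed `seed + r - 1`
#'   and the lowest-objective run wins (ties broken by the earlier seed).
#' @param max_iter maximum Lloyd iterations (default 300); convergence is an
#'   unchanged assignment.
#' @return a [cluster_assignment()] with `method = "kmeans"` and attributes
#'   `tot_withinss` (final objective), `wss_trace` (objective after each
#'   update), `iterations`, and `best_seed`.
#' @export
kmeans_partition <- function(embedding, k, seed, n_init = 1L, max_iter = 300L) {
  x <- if (inherits(embedding, "mds_embedding")) embedding$points else embedding
  if (!is.matrix(x)) abort_input("embedding must be an mds_embedding or a matrix")
  ids <- if (inherits(embedding, "mds_embedding")) embedding$ids else rownames(x)
  if (is.null(ids)) abort_input("embedding must carry ids")
  n <- nrow(x)
  if (k > n) abort_parameter(sprintf("k=%d exceeds n=%d", k, n))
  if (k < 1L) abort_parameter("k must be >= 1")
  if (n_init < 1L) abort_parameter("n_init must be >= 1")

  best <- NULL
  for (r in seq_len(n_init)) {
    run <- with_rng_seed(seed + r - 1L, lloyd_once(x, k, max_iter))
    if (is.null(best) || run$tot_withinss < best$tot_withinss - 1e-12) {
      best <- run
      best$seed <- seed + r - 1L
    }
  }
  out <- cluster_assignment(ids, best$labels, method = "kmeans", seed = best$seed)
  attr(out, "tot_withinss") <- best$tot_withinss
  attr(out, "wss_trace") <- best$trace
  attr(out, "iterations") <- best$iterations
  attr(out, "best_seed") <- best$seed
  out
}

# One seeded Lloyd run over coordinate matrix x. Assumes RNG already seeded.
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: farthest point from its own centroid becomes the
    # missing cluster's singleton seed
    repeat {
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (!length(empty)) break
      own <- d2[cbind(seq_len(n), new_labels)]
      donor_ok <- tabulate(new_labels, k)[new_labels] > 1L
      cand <- which(donor_ok)
      far <- cand[which.max(own[cand])]
      new_labels[far] <- empty[1L]
      centers[empty[1L], ] <- x[far, , drop = FALSE]
      d2[, empty[1L]] <- rowSums(sweep(x, 2L, x[far, ], "-")^2)
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    centers <- centroids_of(x, labels, k)
    trace <- c(trace, sum(sq_dist(x, centers)[cbind(seq_len(n), labels)]))
    if (converged || iter >= max_iter) break
  }
  list(labels = labels, tot_withinss = trace[length(trace)],
       trace = trace, iterations = iter)
}

sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

centroids_of <- function(x, labels, k) {
  c_new <- matrix(0, nrow = k, ncol = ncol(x))
  for (j in seq_len(k)) {
    c_new[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  c_new
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from merge heights, so ultrametric tree distances
#' reflect linkage distances.
#'
#' @param tree an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export the merge table of a dendrogram as TSV
#'
#' One row per internal node: its index, its two children (negative =
#' leaf index, positive = earlier merge), and the merge height.
#'
#' @param tree an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  df <- data.frame(
    node = seq_len(nrow(tree$merge)),
    child1 = tree$merge[, 1L],
    child2 = tree$merge[, 2L],
    height = tree$height
  )
  write_tsv_plain(df, path)
}

#' Export a cluster assignment as TSV
#'
#' Metadata (method, k, seed) goes in `#`-prefixed header lines, followed by
#' a two-column table prescription_id, cluster.
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  write_tsv_plain(
    data.frame(prescription_id = assignment$ids, cluster = assignment$labels),
    path,
    comment_lines = c(
      paste0("method=", assignment$method),
      paste0("k=", assignment$k),
      paste0("seed=", if (is.na(assignment$seed)) "none" else assignment$seed)
    )
  )
}
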