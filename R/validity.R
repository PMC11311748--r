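#' Silhouette widths and mean silhouette index
#'
#' For each prescription i with intra-cluster mean distance `a(i)` and
#' minimal mean distance to another cluster `b(i)`, the silhouette width is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, in `[-1, 1]`; higher values mean
#' a better fit to the assigned cluster. Members of singleton clusters get
#' `s(i) = 0` (the usual convention), logged when triggered.
#'
#' @param dist_matrix symmetric distance matrix with id dimnames; by default
#'   the pipeline passes Jaccard distances (set
#'   `silhouette_on = "embedding"` in the sweeps to use embedded Euclidean
#'   distances instead).
#' @param assignment a `cluster_assignment` over the same ids; `k >= 2`
#'   (the silhouette is undefined for a single cluster).
#' @return list with `widths` (named per-prescription silhouette widths) and
#'   `mean_silhouette`.
#' @export
silhouette_mean <- function(dist_matrix, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  check_distance_matrix(dist_matrix)
  if (!identical(sort(rownames(dist_matrix)), sort(assignment$ids))) {
    abort_input("assignment ids do not match distance matrix ids")
  }
  if (assignment$k < 2L) abort_validation("silhouette undefined for k < 2")
  m <- dist_matrix[assignment$ids, assignment$ids, drop = FALSE]
  lab <- assignment$labels
  n <- length(lab)
  sizes <- tabulate(lab, assignment$k)
  if (any(sizes == 1L)) {
    fn_log("debug", "singleton cluster(s) present; silhouette width 0 assigned")
  }
  # mean distance from each point to each cluster
  memb <- outer(lab, seq_len(assignment$k), "==") + 0
  sums <- m %*% memb
  widths <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1L) { widths[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min(sums[i, -ci] / sizes[-ci])
    widths[i] <- (b - a) / max(a, b)
  }
  names(widths) <- assignment$ids
  list(widths = widths, mean_silhouette = mean(widths))
}

#' Zero-overlap misclassification statistic
#'
#' Misclassification is the event that two prescriptions whose herb sets
#' share no herb (Jaccard coefficient zero) are assigned to the same
#' cluster. The count is over unordered pairs; the rate divides by all
#' `C(n, 2)` unordered prescription pairs, which makes achievable rates
#' integer multiples of `1 / C(n, 2)`.
#'
#' @param corpus a `prescription_corpus`.
#' @param assignment a `cluster_assignment` covering the corpus.
#' @return list with `count` (integer pair count), `rate` (fraction of all
#'   pairs), and `rate_percent`.
#' @export
misclassification_rate <- function(corpus, assignment) {
  stopifnot(inherits(corpus, "prescription_corpus"),
            inherits(assignment, "cluster_assignment"))
  ids <- prescription_ids(corpus)
  if (!identical(sort(ids), sort(assignment$ids))) {
    abort_input("assignment does not cover the corpus")
  }
  n <- length(ids)
  if (n < 2L) abort_input("misclassification needs n >= 2")
  m <- to_incidence(corpus, "herb")[assignment$ids, , drop = FALSE]
  inter <- tcrossprod(m)
  same <- outer(assignment$labels, assignment$labels, "==")
  zero_j <- inter == 0
  count <- sum(zero_j[upper.tri(zero_j)] & same[upper.tri(same)])
  pairs <- choose(n, 2)
  list(count = as.integer(count), rate = count / pairs,
       rate_percent = 100 * count / pairs)
}

#' Validity report for one assignment
#'
#' Bundles the silhouette summary and the misclassification statistic.
#'
#' @param corpus a `prescription_corpus`.
#' @param dist_matrix distance matrix over the corpus.
#' @param assignment a `cluster_assignment`.
#' @return object of class `validity_report`.
#' @export
validity_report <- function(corpus, dist_matrix, assignment) {
  sil <- silhouette_mean(dist_matrix, assignment)
  mis <- misclassification_rate(corpus, assignment)
  structure(
    list(widths = sil$widths, mean_silhouette = sil$mean_silhouette,
         misclassified_pairs = mis$count, misclassification_rate = mis$rate,
         misclassification_rate_percent = mis$rate_percent,
         k = assignment$k, seed = assignment$seed),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "<validity_report> k=%d seed=%s mean silhouette=%.3f misclassified pairs=%d (%.2f%%)\n",
    x$k, if (is.na(x$seed)) "none" else x$seed, x$mean_silhouette,
    x$misclassified_pairs, x$misclassification_rate_percent
  ))
  invisible(x)
}

run_kmeans_stage <- function(corpus, dist_matrix, k, seed, n_init,
                             kmeans_mode = c("embedding", "binary"),
                             silhouette_on = c("jaccard", "embedding")) {
  kmeans_mode <- match.arg(kmeans_mode)
  silhouette_on <- match.arg(silhouette_on)
  emb <- classical_mds(dist_matrix)
  feats <- if (kmeans_mode == "embedding") emb else {
    m <- to_incidence(corpus, "herb") + 0
    m
  }
  asg <- kmeans_partition(feats, k = k, seed = seed, n_init = n_init)
  sil_d <- if (silhouette_on == "jaccard") dist_matrix else {
    as.matrix(stats::dist(emb$points))
  }
  list(assignment = asg, report = validity_report(corpus, sil_d, asg))
}

#' Sensitivity sweep over the number of clusters
#'
#' Runs k-means once per k (or best of `n_init` seeded starts) with the
#' initial centroid positions fixed by the same seed, and tabulates the mean
#' silhouette and misclassification statistic per k.
#'
#' @param corpus a `prescription_corpus`.
#' @param k_range integer vector of cluster counts (e.g. `3:8`), all within
#'   `[2, n]`.
#' @param seed the fixed RNG seed.
#' @param n_init initializations per k (seed, seed+1, ...; best objective wins).
#' @param kmeans_mode feature space for k-means: `"embedding"` (classical MDS
#'   of the Jaccard distances, default) or `"binary"` (raw herb vectors).
#' @param silhouette_on distances used by the silhouette: `"jaccard"`
#'   (default) or `"embedding"`.
#' @return a `sensitivity_table`: data.frame with columns `k`, `seed`,
#'   `mean_silhouette`, `misclassified_pairs`, `misclassification_rate_percent`,
#'   with the per-row assignments in `attr(, "assignments")`.
#' @export
sweep_k <- function(corpus, k_range, seed, n_init = 1L,
                    kmeans_mode = "embedding", silhouette_on = "jaccard") {
  n <- n_prescriptions(corpus)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > n)) {
    abort_parameter(sprintf("k_range must lie within [2, %d]", n))
  }
  d <- jaccard_distance_matrix(corpus)
  rows <- lapply(k_range, function(k) {
    run_kmeans_stage(corpus, d, k, seed, n_init, kmeans_mode, silhouette_on)
  })
  build_sensitivity_table(rows, k = k_range, seed = rep(seed, length(k_range)))
}

#' Sensitivity sweep over random seeds
#'
#' Runs k-means once per seed with k fixed, tabulating validity statistics so
#' the influence of the initial centroid positions can be assessed.
#'
#' @inheritParams sweep_k
#' @param k the fixed number of clusters.
#' @param seeds integer vector of RNG seeds, one run per seed.
#' @return a `sensitivity_table` (one row per seed).
#' @export
sweep_seeds <- function(corpus, k, seeds, n_init = 1L,
                        kmeans_mode = "embedding", silhouette_on = "jaccard") {
  if (!length(seeds)) abort_parameter("seeds must be non-empty")
  n <- n_prescriptions(corpus)
  if (k < 2L || k > n) abort_parameter(sprintf("k must lie within [2, %d]", n))
  d <- jaccard_distance_matrix(corpus)
  rows <- lapply(seeds, function(s) {
    run_kmeans_stage(corpus, d, k, s, n_init, kmeans_mode, silhouette_on)
  })
  build_sensitivity_table(rows, k = rep(as.integer(k), length(seeds)),
                          seed = as.integer(seeds))
}

build_sensitivity_table <- function(rows, k, seed) {
  tab <- data.frame(
    k = k,
    seed = seed,
    mean_silhouette = vapply(rows, function(r) r$report$mean_silhouette, 1),
    misclassified_pairs = vapply(rows, function(r) r$report$misclassified_pairs, 1L),
    misclassification_rate_percent =
      vapply(rows, function(r) r$report$misclassification_rate_percent, 1)
  )
  attr(tab, "assignments") <- lapply(rows, `[[`, "assignment")
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

#' Export a sensitivity table as TSV
#' @param table a `sensitivity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_table <- function(table, path) {
  write_tsv_plain(as.data.frame(table), path)
}

#' Stable cores across a set of cluster assignments
#'
#' A stable core is a maximal set of prescriptions that are co-clustered in
#' every supplied assignment, i.e. a connected component of the intersection
#' of the co-clustering equivalence relations. Since each assignment is a
#' partition, two prescriptions are in the same core exactly when their label
#' vectors across all assignments coincide; the cores always partition the
#' corpus.
#'
#' @param assignments list of at least two `cluster_assignment`s over the
#'   same ids.
#' @return list of character vectors (prescription-id sets), ordered by
#'   decreasing size then first id.
#' @export
stable_cores <- function(assignments) {
  if (length(assignments) < 2L) abort_input("need at least two assignments")
  ids <- assignments[[1L]]$ids
  labmat <- vapply(assignments, function(a) {
    stopifnot(inherits(a, "cluster_assignment"))
    if (!identical(sort(a$ids), sort(ids))) abort_input("assignments cover different id sets")
    a$labels[match(ids, a$ids)]
  }, integer(length(ids)))
  key <- apply(labmat, 1L, paste, collapse = "|")
  cores <- split(ids, key)
  cores <- unname(cores)
  first <- vapply(cores, function(s) min(match(s, ids)), 1L)
  cores[order(-vapply(cores, length, 1L), first)]
}
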