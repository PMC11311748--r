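# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own vectorized code paths: set operations
# and double loops only, so they can certify the fast implementations.

# Random small corpus built directly from long-format vectors.
random_corpus <- function(n = 10, n_herbs = 12, n_inds = 6, seed = 1,
                          with_indications = TRUE) {
  set.seed(seed)
  pid <- character(0); tid <- character(0); kind <- character(0)
  for (i in seq_len(n)) {
    herbs <- sample(paste0("H", seq_len(n_herbs)), sample(1:min(6, n_herbs), 1))
    pid <- c(pid, rep(sprintf("P-%d", i), length(herbs)))
    tid <- c(tid, herbs)
    kind <- c(kind, rep("herb", length(herbs)))
    if (with_indications && n_inds > 0) {
      inds <- sample(paste0("S", seq_len(n_inds)), sample(0:min(3, n_inds), 1))
      if (length(inds)) {
        pid <- c(pid, rep(sprintf("P-%d", i), length(inds)))
        tid <- c(tid, inds)
        kind <- c(kind, rep("indication", length(inds)))
      }
    }
  }
  suppressWarnings(prescription_corpus(pid, tid, kind))
}

random_assignment <- function(corpus, k, seed = 1) {
  set.seed(seed)
  ids <- prescription_ids(corpus)
  repeat {
    labels <- sample.int(k, length(ids), replace = TRUE)
    if (length(unique(labels)) == k) break
  }
  cluster_assignment(ids, labels)
}

oracle_jaccard <- function(a, b) {
  length(intersect(unique(a), unique(b))) / length(union(unique(a), unique(b)))
}

oracle_distance_matrix <- function(corpus) {
  ids <- prescription_ids(corpus)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- 1 - oracle_jaccard(corpus$herbs[[ids[i]]],
                                              corpus$herbs[[ids[j]]])
  }
  m
}

oracle_misclassification <- function(corpus, assignment) {
  ids <- assignment$ids
  n <- length(ids)
  count <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- assignment$labels[i] == assignment$labels[j]
    zero <- oracle_jaccard(corpus$herbs[[ids[i]]], corpus$herbs[[ids[j]]]) == 0
    if (same && zero) count <- count + 1L
  }
  list(count = count, rate = count / choose(n, 2))
}

oracle_silhouette <- function(dist_matrix, labels) {
  n <- length(labels)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { widths[i] <- 0; next }
    a <- mean(dist_matrix[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dist_matrix[i, which(labels == cl)]))
    }
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# Naive agglomerative clustering: merge the closest pair of clusters under
# the given linkage until one remains; returns merge heights in order.
oracle_agglomerate_heights <- function(d, linkage = "complete") {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  link <- switch(linkage, complete = max, single = min, average = mean)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dd <- link(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive k-partition minimum of the k-means objective for small n.
oracle_best_wss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 4e6)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    labels <- (code %/% k^(0:(n - 1))) %% k + 1
    if (length(unique(labels)) != k) next
    wss <- 0
    for (j in seq_len(k)) {
      pts <- x[labels == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr, "-")^2)
    }
    best <- min(best, wss)
  }
  best
}

# Corpus + assignment engineered to contain exactly C(m,2) + m*r
# zero-Jaccard co-clustered pairs among n prescriptions: m mutually disjoint
# "isolate" prescriptions and r common-herb prescriptions share cluster 1;
# every non-isolate contains the common herb H0.
engineered_misclassification <- function(n, m, r) {
  stopifnot(m + r <= n)
  pid <- character(0); tid <- character(0)
  for (i in seq_len(n)) {
    herbs <- if (i <= m) paste0("ISO", i) else c("H0", paste0("U", i))
    pid <- c(pid, rep(sprintf("P-%d", i), length(herbs)))
    tid <- c(tid, herbs)
  }
  corpus <- suppressWarnings(
    prescription_corpus(pid, tid, rep("herb", length(tid)))
  )
  labels <- c(rep(1L, m + r), rep(2L, n - m - r))
  list(corpus = corpus,
       assignment = cluster_assignment(prescription_ids(corpus), labels),
       expected_count = choose(m, 2) + m * r)
}

tmp_corpus_file <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
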