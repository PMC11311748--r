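fixture_4pt <- function() {
  d <- matrix(0.9, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["C", "D"] <- d["D", "C"] <- 0.2
  diag(d) <- 0
  d
}

test_that("complete-linkage agglomeration matches the hand-executed fixture", {
  tree <- hierarchical_cluster(fixture_4pt(), "complete")
  expect_equal(tree$height, c(0.1, 0.2, 0.9))
  # first merge joins A,B; second joins C,D
  expect_setequal(tree$labels[-tree$merge[1, ]], c("A", "B"))
  expect_setequal(tree$labels[-tree$merge[2, ]], c("C", "D"))

  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  t2 <- hierarchical_cluster(two)
  expect_equal(t2$height, 0.4)
  expect_error(hierarchical_cluster(two[1, 1, drop = FALSE]),
               class = "formulanet_input_error")
})

test_that("merge heights are monotone and match a naive agglomeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    m <- matrix(stats::runif(n * n), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("P", 1:n), paste0("P", 1:n))
    for (linkage in c("complete", "average", "single")) {
      tree <- hierarchical_cluster(d, linkage)
      expect_true(all(diff(tree$height) >= -1e-12))
      expect_equal(tree$height, oracle_agglomerate_heights(d, linkage),
                   tolerance = 1e-12)
    }
  }
})

test_that("cutting a dendrogram yields nested partitions of the right size", {
  tree <- hierarchical_cluster(fixture_4pt())
  expect_equal(cut_dendrogram(tree, 1)$labels, rep(1L, 4))
  expect_equal(sort(cut_dendrogram(tree, 4)$labels), 1:4)
  cut2 <- cut_dendrogram(tree, 2)
  expect_equal(cut2$k, 2)
  lab <- stats::setNames(cut2$labels, cut2$ids)
  expect_equal(lab[["A"]], lab[["B"]])
  expect_equal(lab[["C"]], lab[["D"]])
  expect_false(lab[["A"]] == lab[["C"]])
  expect_error(cut_dendrogram(tree, 5), class = "formulanet_parameter_error")

  d <- jaccard_distance_matrix(random_corpus(12, seed = 4, with_indications = FALSE))
  tr <- hierarchical_cluster(d)
  for (k in 2:11) {
    finer <- cut_dendrogram(tr, k + 1)$labels
    coarser <- cut_dendrogram(tr, k)$labels
    # refinement: points sharing a finer cluster share the coarser one
    expect_true(all(tapply(coarser, finer, function(v) length(unique(v))) == 1))
  }
})

test_that("classical MDS reproduces symmetric configurations and Euclidean inputs", {
  two <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  e2 <- classical_mds(two)
  expect_equal(ncol(e2$points), 1)
  expect_equal(unname(sort(abs(e2$points[, 1]))), c(0.5, 0.5))

  three <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(three) <- 0
  e3 <- classical_mds(three)
  expect_equal(unname(as.matrix(stats::dist(e3$points))), unname(three),
               tolerance = 1e-8)

  set.seed(8)
  x <- matrix(stats::rnorm(20 * 3), 20, 3, dimnames = list(paste0("P", 1:20), NULL))
  d <- as.matrix(stats::dist(x))
  emb <- classical_mds(d)
  expect_equal(as.matrix(stats::dist(emb$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_warning(classical_mds(d, dim = 19), "clamped")
})

test_that("seeded k-means is deterministic and recovers separated blobs", {
  set.seed(10)
  blob <- function(cx, cy, n) cbind(stats::rnorm(n, cx, 0.05), stats::rnorm(n, cy, 0.05))
  x <- rbind(blob(0, 0, 4), blob(5, 0, 4), blob(0, 5, 4))
  rownames(x) <- paste0("P", 1:12)
  truth <- rep(1:3, each = 4)
  for (seed in c(1, 7, 42, 999)) {
    a <- kmeans_partition(x, 3, seed = seed)
    b <- kmeans_partition(x, 3, seed = seed)
    expect_identical(a$labels, b$labels)
    expect_equal(adjusted_rand_index(a$labels, truth), 1)
    expect_true(all(diff(attr(a, "wss_trace")) <= 1e-10))
  }
  one <- kmeans_partition(x, 1, seed = 1)
  ctr <- colMeans(x)
  expect_equal(attr(one, "tot_withinss"), sum(sweep(x, 2, ctr, "-")^2))
  expect_error(kmeans_partition(x, 13, seed = 1),
               class = "formulanet_parameter_error")
})

test_that("best-of-seeds k-means attains the exhaustive-partition optimum", {
  set.seed(21)
  x <- matrix(stats::rnorm(10 * 2), 10, 2)
  rownames(x) <- paste0("P", 1:10)
  best <- kmeans_partition(x, 3, seed = 1, n_init = 25)
  expect_equal(attr(best, "tot_withinss"), oracle_best_wss(x, 3),
               tolerance = 1e-9)
})

test_that("k-means agrees with stats::kmeans on well-separated data", {
  set.seed(33)
  x <- rbind(matrix(stats::rnorm(10, 0, 0.1), 5, 2),
             matrix(stats::rnorm(10, 10, 0.1), 5, 2))
  rownames(x) <- paste0("P", 1:10)
  mine <- kmeans_partition(x, 2, seed = 3)
  ref <- stats::kmeans(x, 2, nstart = 5)
  expect_equal(adjusted_rand_index(mine$labels, unname(ref$cluster)), 1)
  expect_equal(attr(mine, "tot_withinss"), ref$tot.withinss, tolerance = 1e-9)
})

test_that("block-structured corpora are recovered exactly by both methods", {
  spec <- synthetic_spec(n_clusters = 4, prescriptions_per_cluster = 5,
                         p_core = 1, p_shared = 0, p_noise = 0, seed = 77)
  syn <- generate_corpus(spec)
  d <- jaccard_distance_matrix(syn$corpus)
  for (linkage in c("complete", "average", "single")) {
    hc <- cut_dendrogram(hierarchical_cluster(d, linkage), 4)
    expect_equal(adjusted_rand_index(hc, syn$labels), 1)
  }
  km <- kmeans_partition(classical_mds(d), 4, seed = 1, n_init = 10)
  expect_equal(adjusted_rand_index(km, syn$labels), 1)
})

test_that("newick and merge-table exports are readable and consistent", {
  d <- jaccard_distance_matrix(random_corpus(8, seed = 6, with_indications = FALSE))
  tree <- hierarchical_cluster(d)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, rownames(d))
  mt <- withr::local_tempfile(fileext = ".tsv")
  write_merge_table(tree, mt)
  tab <- utils::read.delim(mt)
  expect_equal(nrow(tab), nrow(d) - 1)
  expect_equal(tab$height, tree$height, tolerance = 1e-9)
})
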