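test_that("silhouette is 1 for perfectly separated clusters and errors for k < 2", {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  dimnames(d) <- list(paste0("P", 1:6), paste0("P", 1:6))
  asg <- cluster_assignment(paste0("P", 1:6), rep(1:2, each = 3))
  expect_equal(silhouette_mean(d, asg)$mean_silhouette, 1)
  expect_error(silhouette_mean(d, cluster_assignment(paste0("P", 1:6), rep(1, 6))),
               class = "formulanet_validation_error")
})

test_that("silhouette matches brute force and cluster::silhouette to 1e-12", {
  for (seed in 1:6) {
    corp <- random_corpus(n = 12, seed = seed, with_indications = FALSE)
    d <- jaccard_distance_matrix(corp)
    k <- sample(2:4, 1)
    asg <- random_assignment(corp, k, seed = seed + 100)
    mine <- silhouette_mean(d, asg)
    expect_equal(mine$mean_silhouette, oracle_silhouette(d, asg$labels),
                 tolerance = 1e-12)
    sil <- cluster::silhouette(asg$labels, dmatrix = d)
    # cluster:: also uses width 0 for singletons
    expect_equal(unname(mine$widths), unname(sil[, "sil_width"]),
                 tolerance = 1e-12)
  }
})

test_that("singleton clusters get silhouette width zero", {
  d <- jaccard_distance_matrix(random_corpus(5, seed = 2, with_indications = FALSE))
  asg <- cluster_assignment(rownames(d), c(1, 1, 1, 1, 2))
  w <- silhouette_mean(d, asg)$widths
  expect_equal(unname(w[5]), 0)
})

test_that("misclassification counts zero-overlap co-clustered pairs exactly", {
  # all singletons: no co-clustered pairs
  corp <- random_corpus(6, seed = 3, with_indications = FALSE)
  singletons <- cluster_assignment(prescription_ids(corp), 1:6)
  expect_equal(misclassification_rate(corp, singletons)$count, 0)

  # every pair shares a herb: rate 0 for every assignment
  shared <- suppressWarnings(prescription_corpus(
    rep(paste0("P-", 1:5), each = 2),
    as.vector(rbind(rep("H0", 5), paste0("H", 1:5))),
    rep("herb", 10)
  ))
  for (seed in 1:3) {
    asg <- random_assignment(shared, 2, seed)
    expect_equal(misclassification_rate(shared, asg)$count, 0)
  }
})

test_that("misclassification equals the brute-force oracle and is quantized", {
  for (seed in 1:10) {
    n <- sample(5:15, 1)
    corp <- random_corpus(n, seed = seed, with_indications = FALSE)
    asg <- random_assignment(corp, sample(2:4, 1), seed + 50)
    mine <- misclassification_rate(corp, asg)
    oracle <- oracle_misclassification(corp, asg)
    expect_identical(mine$count, oracle$count)
    expect_equal(mine$rate, oracle$rate)
    # quantization: integer multiple of 1 / C(n,2)
    expect_equal(mine$rate * choose(n, 2), round(mine$rate * choose(n, 2)))
  }
})

test_that("splitting clusters never increases the misclassification count", {
  set.seed(14)
  for (rep in 1:5) {
    corp <- random_corpus(12, seed = rep * 3, with_indications = FALSE)
    ids <- prescription_ids(corp)
    coarse <- random_assignment(corp, 2, rep)
    # refine: split cluster 1 arbitrarily into two
    labels <- coarse$labels
    in1 <- which(labels == 1)
    if (length(in1) >= 2) {
      labels[in1[seq_len(ceiling(length(in1) / 2))]] <- 3L
      fine <- cluster_assignment(ids, labels)
      expect_lte(misclassification_rate(corp, fine)$count,
                 misclassification_rate(corp, coarse)$count)
    }
  }
})

test_that("the percentage convention maps pair counts to printed rates at n = 43", {
  cases <- list(c(m = 1, r = 2, pct = 0.22), c(m = 4, r = 20, pct = 9.52),
                c(m = 8, r = 13, pct = 14.62), c(m = 1, r = 14, pct = 1.55))
  for (cs in cases) {
    eng <- engineered_misclassification(43, cs[["m"]], cs[["r"]])
    got <- misclassification_rate(eng$corpus, eng$assignment)
    expect_identical(got$count, as.integer(eng$expected_count))
    expect_equal(round(got$rate_percent, 2), cs[["pct"]])
  }
})

test_that("sweep over k covers the grid and finds zero misclassification at true K", {
  spec <- synthetic_spec(n_clusters = 4, prescriptions_per_cluster = 6,
                         p_core = 1, p_shared = 0, p_noise = 0, seed = 5)
  syn <- generate_corpus(spec)
  tab <- sweep_k(syn$corpus, 3:8, seed = 11, n_init = 5)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$k, 3:8)
  expect_equal(tab$misclassified_pairs[tab$k == 4], 0)
  expect_error(sweep_k(syn$corpus, 1:4, seed = 1),
               class = "formulanet_parameter_error")
})

test_that("sweep over seeds is deterministic per seed", {
  syn <- generate_corpus(synthetic_spec(n_clusters = 3, prescriptions_per_cluster = 5,
                                        seed = 8))
  tab <- sweep_seeds(syn$corpus, k = 3, seeds = c(7, 7, 21))
  expect_equal(nrow(tab), 3)
  expect_equal(tab[1, -2], tab[2, -2], ignore_attr = TRUE)
  asgs <- attr(tab, "assignments")
  expect_identical(asgs[[1]]$labels, asgs[[2]]$labels)
  expect_error(sweep_seeds(syn$corpus, 3, integer(0)),
               class = "formulanet_parameter_error")
})

test_that("stable cores intersect co-clustering relations", {
  ids <- c("A", "B", "C", "D")
  p1 <- cluster_assignment(ids, c(1, 1, 2, 2))
  p2 <- cluster_assignment(ids, c(1, 1, 1, 2))
  cores <- stable_cores(list(p1, p2))
  expect_setequal(lapply(cores, sort), list(c("A", "B"), "C", "D"))

  # identical partitions: cores are the clusters themselves
  cores2 <- stable_cores(list(p1, p1))
  expect_setequal(lapply(cores2, sort), list(c("A", "B"), c("C", "D")))

  # cores always partition the id set
  set.seed(31)
  corp <- random_corpus(10, seed = 31, with_indications = FALSE)
  asgs <- lapply(1:4, function(s) random_assignment(corp, 3, s))
  cores3 <- stable_cores(asgs)
  expect_setequal(unlist(cores3), prescription_ids(corp))
  expect_equal(anyDuplicated(unlist(cores3)), 0)

  p3 <- cluster_assignment(c("A", "B", "C", "E"), c(1, 1, 2, 2))
  expect_error(stable_cores(list(p1, p3)), class = "formulanet_input_error")
  expect_error(stable_cores(list(p1)), class = "formulanet_input_error")
})
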