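#' Specification for a planted-partition synthetic prescription corpus
#'
#' The generator emulates the statistical shape of a classical multi-herb
#' prescription corpus: a handful of prescription groups, each drawing most
#' of its herbs from a group-specific pool, plus a small pool of globally
#' shared high-frequency (tonifying) herbs present across groups, a low rate
#' of out-of-pool noise herbs, and group-specific indication profiles with
#' two globally shared indications (the fever/deficiency pattern) so that
#' subnetwork comparisons have non-trivial common major nodes.
#'
#' Defaults give 5 clusters x 9 prescriptions = 45 prescriptions over a
#' 69-herb universe (5 pools of 8 + 4 shared + 25 noise-only herbs) and 22
#' indication tokens (5 pools of 4 + 2 shared), comparable in size and
#' density to a small classical formulary.
#'
#' @param n_clusters number of planted groups.
#' @param prescriptions_per_cluster integer, scalar or one per cluster.
#' @param herb_pool_size herbs in each cluster-specific pool (pools are
#'   pairwise disjoint and disjoint from the shared pool).
#' @param shared_herb_pool_size globally shared herbs.
#' @param extra_herbs additional herbs that only ever appear as noise.
#' @param p_core inclusion probability of each own-pool herb.
#' @param p_shared inclusion probability of each shared-pool herb.
#' @param p_noise inclusion probability of each out-of-pool herb (other
#'   clusters' pools and the extra herbs).
#' @param indication_pool_size indications in each cluster-specific pool.
#' @param shared_indications globally shared indications.
#' @param p_indication inclusion probability of each own-pool indication.
#' @param p_shared_indication inclusion probability of each shared
#'   indication; the default makes the shared indications the most frequent
#'   tokens overall.
#' @param seed integer RNG seed; the whole corpus is drawn from one stream
#'   seeded here, herbs then indications, prescription by prescription in
#'   cluster order.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 5L,
                           prescriptions_per_cluster = 9L,
                           herb_pool_size = 8L,
                           shared_herb_pool_size = 4L,
                           extra_herbs = 25L,
                           p_core = 0.7,
                           p_shared = 0.6,
                           p_noise = 0.02,
                           indication_pool_size = 4L,
                           shared_indications = 2L,
                           p_indication = 0.6,
                           p_shared_indication = 0.7,
                           seed = 20240701L) {
  probs <- c(p_core = p_core, p_shared = p_shared, p_noise = p_noise,
             p_indication = p_indication, p_shared_indication = p_shared_indication)
  if (any(probs < 0 | probs > 1)) abort_parameter("probabilities must lie in [0, 1]")
  if (n_clusters < 1L) abort_parameter("n_clusters must be >= 1")
  sizes <- rep_len(as.integer(prescriptions_per_cluster), n_clusters)
  if (any(sizes < 1L)) abort_parameter("each cluster needs >= 1 prescription")
  if (herb_pool_size < 1L && shared_herb_pool_size < 1L && extra_herbs < 1L) {
    abort_parameter("herb universe is empty")
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         prescriptions_per_cluster = sizes,
         herb_pool_size = as.integer(herb_pool_size),
         shared_herb_pool_size = as.integer(shared_herb_pool_size),
         extra_herbs = as.integer(extra_herbs),
         p_core = p_core, p_shared = p_shared, p_noise = p_noise,
         indication_pool_size = as.integer(indication_pool_size),
         shared_indications = as.integer(shared_indications),
         p_indication = p_indication,
         p_shared_indication = p_shared_indication,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic corpus with planted cluster structure
#'
#' Herb tokens are labelled `H1..Hm` with the shared pool first (so `H1` is a
#' globally frequent herb), then the cluster pools, then the noise-only
#' herbs; indications are `S1..Sq` with the shared indications first. Each
#' prescription's herb set is resampled (up to 1000 attempts) until
#' non-empty. The same spec and seed always reproduce the same corpus.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `corpus` (a `prescription_corpus`), `labels` (a
#'   `cluster_assignment` of the planted groups, `method = "planted"`), and
#'   `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  kc <- spec$n_clusters
  shared_h <- if (spec$shared_herb_pool_size)
    paste0("H", seq_len(spec$shared_herb_pool_size)) else character(0)
  pool_h <- lapply(seq_len(kc), function(g) {
    if (!spec$herb_pool_size) return(character(0))
    start <- spec$shared_herb_pool_size + (g - 1L) * spec$herb_pool_size
    paste0("H", start + seq_len(spec$herb_pool_size))
  })
  n_named <- spec$shared_herb_pool_size + kc * spec$herb_pool_size
  extra_h <- if (spec$extra_herbs)
    paste0("H", n_named + seq_len(spec$extra_herbs)) else character(0)

  shared_s <- if (spec$shared_indications)
    paste0("S", seq_len(spec$shared_indications)) else character(0)
  pool_s <- lapply(seq_len(kc), function(g) {
    if (!spec$indication_pool_size) return(character(0))
    start <- spec$shared_indications + (g - 1L) * spec$indication_pool_size
    paste0("S", start + seq_len(spec$indication_pool_size))
  })

  draw <- function(tokens, p) tokens[stats::runif(length(tokens)) < p]

  pid <- character(0); tid <- character(0); kind <- character(0)
  planted <- integer(0)
  idx <- 0L
  for (g in seq_len(kc)) {
    others <- c(unlist(pool_h[-g]), extra_h)
    for (j in seq_len(spec$prescriptions_per_cluster[g])) {
      idx <- idx + 1L
      p_id <- sprintf("P-%d", idx)
      herbs <- character(0)
      for (attempt in seq_len(1000L)) {
        herbs <- c(draw(pool_h[[g]], spec$p_core),
                   draw(shared_h, spec$p_shared),
                   draw(others, spec$p_noise))
        if (length(herbs)) break
      }
      if (!length(herbs)) {
        abort_parameter("infeasible spec: empty herb set after 1000 resampling attempts")
      }
      inds <- c(draw(shared_s, spec$p_shared_indication),
                draw(pool_s[[g]], spec$p_indication))
      pid <- c(pid, rep(p_id, length(herbs) + length(inds)))
      tid <- c(tid, herbs, inds)
      kind <- c(kind, rep("herb", length(herbs)), rep("indication", length(inds)))
      planted <- c(planted, g)
    }
  }
  corpus <- suppressWarnings(prescription_corpus(pid, tid, kind))
  labels <- cluster_assignment(prescription_ids(corpus), planted,
                               method = "planted", seed = spec$seed)
  list(corpus = corpus, labels = labels, spec = spec)
}

#' Write a synthetic corpus bundle to disk
#'
#' Emits the long-format corpus table, a planted-labels TSV, and the spec as
#' YAML, so simulated studies are fully reconstructible.
#'
#' @param bundle result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus_path <- file.path(dir, "corpus.tsv")
  labels_path <- file.path(dir, "planted_labels.tsv")
  spec_path <- file.path(dir, "spec.yaml")
  write_corpus(bundle$corpus, corpus_path)
  write_assignment(bundle$labels, labels_path)
  yaml::write_yaml(unclass(bundle$spec), spec_path)
  invisible(c(corpus_path, labels_path, spec_path))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two partitions of the same prescriptions,
#' corrected for chance: 1 for identical partitions (up to relabeling),
#' around 0 for independent ones; can be negative.
#'
#' @param labels_a,labels_b `cluster_assignment`s over the same ids, or bare
#'   label vectors of equal length.
#' @return numeric in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (inherits(labels_a, "cluster_assignment") && inherits(labels_b, "cluster_assignment")) {
    if (!identical(sort(labels_a$ids), sort(labels_b$ids))) {
      abort_input("assignments cover different id sets")
    }
    b <- labels_b$labels[match(labels_a$ids, labels_b$ids)]
    a <- labels_a$labels
  } else {
    a <- labels_a; b <- labels_b
    if (length(a) != length(b)) abort_input("label vectors differ in length")
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(length(a), 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Study-shaped synthetic stand-in corpus
#'
#' A deterministic synthetic corpus sized like a small classical formulary
#' (43 prescriptions in 4 planted groups, a 69-herb universe, 22 indication
#' tokens). This is generated data for exercising the pipeline at realistic
#' scale; it is not a transcription of any historical source.
#'
#' @param seed RNG seed.
#' @return list with `corpus`, `labels`, `spec` (see [generate_corpus()]).
#' @export
synthetic_study_corpus <- function(seed = 20240702L) {
  spec <- synthetic_spec(
    n_clusters = 4L,
    prescriptions_per_cluster = c(11L, 11L, 11L, 10L),
    herb_pool_size = 10L,
    shared_herb_pool_size = 4L,
    extra_herbs = 25L,
    indication_pool_size = 5L,
    shared_indications = 2L,
    seed = seed
  )
  generate_corpus(spec)
}
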