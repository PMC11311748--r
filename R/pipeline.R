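#' Build and validate a pipeline configuration
#'
#' Exactly one data source must be given: a long-format corpus file
#' (`input`) or a synthetic-corpus spec (`synthetic`). All remaining
#' parameters control the analysis stages.
#'
#' @param input path to a long-format corpus file, or `NULL`.
#' @param synthetic a [synthetic_spec()] (or plain list of its arguments), or
#'   `NULL`.
#' @param output_dir directory for all artifacts.
#' @param linkage hierarchical linkage (`"complete"`, `"average"`, `"single"`).
#' @param kmeans_mode `"embedding"` or `"binary"` feature space.
#' @param k the headline number of clusters for the reported k-means
#'   partition and the subnetworks.
#' @param k_range integer vector for the k sweep.
#' @param seeds integer seeds; the first is the fixed seed of the k sweep and
#'   the headline run, all of them feed the seed sweep.
#' @param n_init initializations per k-means run.
#' @param min_freq,top_n threshold for subnetwork comparison (both `NULL`
#'   uses the half-of-smaller-cluster default).
#' @param silhouette_on `"jaccard"` or `"embedding"`.
#' @param log_level `"debug"`, `"info"`, `"warn"`, or `"silent"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            output_dir = "formulanet-out",
                            linkage = "complete",
                            kmeans_mode = "embedding",
                            k = 6L, k_range = 3:8,
                            seeds = c(123L, 12345L, 148L, 371L, 2024L),
                            n_init = 1L,
                            min_freq = NULL, top_n = NULL,
                            silhouette_on = "jaccard",
                            log_level = "info") {
  if (is.null(input) == is.null(synthetic)) {
    abort_parameter("exactly one of `input` or `synthetic` must be given")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    synthetic <- do.call(synthetic_spec, as.list(synthetic))
  }
  structure(
    list(input = input, synthetic = synthetic, output_dir = output_dir,
         linkage = match.arg(linkage, c("complete", "average", "single")),
         kmeans_mode = match.arg(kmeans_mode, c("embedding", "binary")),
         k = as.integer(k), k_range = as.integer(k_range),
         seeds = as.integer(seeds), n_init = as.integer(n_init),
         min_freq = min_freq, top_n = top_n,
         silhouette_on = match.arg(silhouette_on, c("jaccard", "embedding")),
         log_level = match.arg(log_level, c("debug", "info", "warn", "silent"))),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments (a
#'   `synthetic` mapping becomes a [synthetic_spec()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_input(paste0("no such config file: ", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full prescription-mining analysis
#'
#' Orchestrates every stage: corpus load or simulation, Jaccard distance
#' matrix, hierarchical clustering with dendrogram export, MDS embedding,
#' headline k-means partition, k-range and seed sensitivity sweeps with
#' stable cores, the full herb-indication network, per-cluster subnetworks,
#' and pairwise subnetwork comparisons. All artifacts are written to the
#' output directory with a `manifest.json` carrying SHA-256 checksums;
#' rerunning with the same config reproduces byte-identical TSV/JSON
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a result bundle: list with `corpus`, `distance`,
#'   `dendrogram`, `assignment`, `sweep_k`, `sweep_seeds`, `stable_cores`,
#'   `network`, `subnetworks`, `comparisons`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  old <- options(formulanet.log_level = config$log_level)
  on.exit(options(old))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  artifacts <- character(0)
  stage <- function(name, expr) {
    fn_log("info", "stage ", name)
    tryCatch(expr, error = function(e) {
      fn_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "formulanet_stage_error")
    })
  }

  planted <- NULL
  corpus <- stage("corpus", {
    if (!is.null(config$input)) {
      read_corpus(config$input)
    } else {
      syn <- generate_corpus(config$synthetic)
      planted <- syn$labels
      syn_paths <- write_synthetic_bundle(syn, out("synthetic"))
      artifacts <- c(artifacts, syn_paths)
      syn$corpus
    }
  })
  n <- n_prescriptions(corpus)
  seed0 <- config$seeds[1L]

  d <- stage("distance", {
    dm <- jaccard_distance_matrix(corpus)
    write_distance_matrix(dm, out("distance.tsv"))
    artifacts <- c(artifacts, out("distance.tsv"))
    dm
  })

  tree <- stage("hierarchical", {
    tr <- hierarchical_cluster(d, linkage = config$linkage)
    write_newick(tr, out("dendrogram.newick"))
    write_merge_table(tr, out("merges.tsv"))
    artifacts <- c(artifacts, out("dendrogram.newick"), out("merges.tsv"))
    tr
  })

  headline <- stage("kmeans", {
    res <- run_kmeans_stage(corpus, d, config$k, seed0, config$n_init,
                            config$kmeans_mode, config$silhouette_on)
    write_assignment(res$assignment, out("assignment_kmeans.tsv"))
    hca_cut <- cut_dendrogram(tree, config$k)
    write_assignment(hca_cut, out("assignment_hca.tsv"))
    artifacts <- c(artifacts, out("assignment_kmeans.tsv"), out("assignment_hca.tsv"))
    res
  })

  tab_k <- stage("sweep_k", {
    tk <- sweep_k(corpus, config$k_range, seed0, config$n_init,
                  config$kmeans_mode, config$silhouette_on)
    write_sensitivity_table(tk, out("sensitivity_k.tsv"))
    artifacts <- c(artifacts, out("sensitivity_k.tsv"))
    tk
  })

  tab_s <- stage("sweep_seeds", {
    ts <- sweep_seeds(corpus, config$k, config$seeds, config$n_init,
                      config$kmeans_mode, config$silhouette_on)
    write_sensitivity_table(ts, out("sensitivity_seeds.tsv"))
    artifacts <- c(artifacts, out("sensitivity_seeds.tsv"))
    ts
  })

  cores <- stage("stable_cores", {
    cs <- stable_cores(attr(tab_s, "assignments"))
    core_df <- data.frame(
      core = rep(seq_along(cs), vapply(cs, length, 1L)),
      prescription_id = unlist(cs)
    )
    write_tsv_plain(core_df, out("stable_cores.tsv"))
    artifacts <- c(artifacts, out("stable_cores.tsv"))
    cs
  })

  net <- stage("network", {
    nt <- build_hi_network(corpus)
    write_network(nt, out("network_edges.tsv"), out("network_nodes.tsv"),
                  out("network.graphml"))
    artifacts <- c(artifacts, out("network_edges.tsv"), out("network_nodes.tsv"),
                    out("network.graphml"))
    nt
  })

  subnets <- stage("subnetworks", {
    asg <- headline$assignment
    sn <- lapply(seq_len(asg$k), function(lbl) extract_subnetwork(corpus, asg, lbl))
    names(sn) <- paste0("K", seq_len(asg$k))
    for (lbl in names(sn)) {
      ep <- out(sprintf("subnetwork_%s_edges.tsv", lbl))
      np <- out(sprintf("subnetwork_%s_nodes.tsv", lbl))
      write_network(sn[[lbl]], ep, np, NULL)
      artifacts <- c(artifacts, ep, np)
    }
    sn
  })

  comparisons <- stage("comparisons", {
    pairs <- utils::combn(names(subnets), 2, simplify = FALSE)
    cmp <- lapply(pairs, function(pr) {
      compare_subnetworks(subnets[[pr[1L]]], subnets[[pr[2L]]],
                          min_freq = config$min_freq, top_n = config$top_n)
    })
    names(cmp) <- vapply(pairs, paste, "", collapse = "-")
    cmp_df <- data.frame(
      pair = names(cmp),
      min_freq = vapply(cmp, function(x) x$min_freq %||% NA_integer_, 1),
      common_major_herbs = vapply(cmp, function(x)
        paste(x$common_major_herbs, collapse = ","), ""),
      common_major_indications = vapply(cmp, function(x)
        paste(x$common_major_indications, collapse = ","), "")
    )
    write_tsv_plain(cmp_df, out("subnetwork_comparisons.tsv"))
    artifacts <- c(artifacts, out("subnetwork_comparisons.tsv"))
    cmp
  })

  report <- stage("report", {
    rep <- list(
      n_prescriptions = n,
      n_herb_tokens = length(token_ids(corpus, "herb")),
      n_indication_tokens = length(token_ids(corpus, "indication")),
      k = config$k,
      seed = seed0,
      headline_mean_silhouette = headline$report$mean_silhouette,
      headline_misclassified_pairs = headline$report$misclassified_pairs,
      headline_misclassification_percent =
        round(headline$report$misclassification_rate_percent, 2),
      sweep_k = as.data.frame(tab_k),
      sweep_seeds = as.data.frame(tab_s),
      planted_ari = if (!is.null(planted))
        adjusted_rand_index(headline$assignment, planted)
    )
    jsonlite::write_json(rep, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    artifacts <- c(artifacts, out("report.json"))
    rep
  })

  manifest <- stage("manifest", {
    rel <- substring(artifacts, nchar(file.path(config$output_dir, "")) + 1L)
    mf <- list(artifacts = data.frame(
      path = rel,
      sha256 = vapply(artifacts, function(p) digest::digest(file = p, algo = "sha256"), ""),
      row.names = NULL
    ))
    jsonlite::write_json(mf, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    mf
  })

  invisible(list(
    corpus = corpus, planted = planted, distance = d, dendrogram = tree,
    assignment = headline$assignment, headline_report = headline$report,
    sweep_k = tab_k, sweep_seeds = tab_s, stable_cores = cores,
    network = net, subnetworks = subnets, comparisons = comparisons,
    report = report, manifest = manifest
  ))
}
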