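#' Build a bipartite herb-indication co-occurrence network
#'
#' Herb and indication tokens become nodes; a herb and an indication are
#' connected when at least one member prescription contains both. Node
#' frequency is the number of member prescriptions containing the token; edge
#' weight is the number of member prescriptions containing both endpoints.
#' There are no herb-herb or indication-indication edges, every edge weight
#' is at least 1 and at most the smaller endpoint frequency, and the total
#' edge weight equals the sum over member prescriptions of
#' `|herbs| * |indications|`.
#'
#' @param corpus a `prescription_corpus`.
#' @param members prescription ids to include, or `NULL` (default) for the
#'   whole corpus.
#' @return object of class `hi_network`: list with `members`, `nodes`
#'   (data.frame: `token_id`, `name`, `kind`, `frequency`; only tokens
#'   appearing in at least one member), and `edges` (data.frame: `herb_id`,
#'   `indication_id`, `weight`), both deterministically ordered.
#' @export
build_hi_network <- function(corpus, members = NULL) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  all_ids <- prescription_ids(corpus)
  if (is.null(members)) members <- all_ids
  members <- as.character(members)
  if (!length(members)) abort_input("member set is empty")
  unknown <- setdiff(members, all_ids)
  if (length(unknown)) {
    abort_input(paste0("unknown prescription id(s): ", paste(unknown, collapse = ", ")))
  }
  h <- to_incidence(corpus, "herb")[members, , drop = FALSE]
  s <- to_incidence(corpus, "indication")[members, , drop = FALSE]
  hfreq <- colSums(h)
  sfreq <- colSums(s)
  w <- crossprod(h, s) # herbs x indications co-membership counts

  nodes <- rbind(
    data.frame(token_id = colnames(h), kind = "herb", frequency = unname(hfreq),
               stringsAsFactors = FALSE),
    data.frame(token_id = colnames(s), kind = "indication", frequency = unname(sfreq),
               stringsAsFactors = FALSE)
  )
  nodes <- nodes[nodes$frequency > 0, , drop = FALSE]
  nodes$name <- corpus$tokens$name[match(nodes$token_id, corpus$tokens$token_id)]
  nodes <- nodes[order(nodes$kind, -nodes$frequency, nodes$token_id),
                 c("token_id", "name", "kind", "frequency")]
  rownames(nodes) <- NULL

  nz <- which(w > 0, arr.ind = TRUE)
  edges <- data.frame(
    herb_id = rownames(w)[nz[, 1L]],
    indication_id = colnames(w)[nz[, 2L]],
    weight = as.integer(w[nz]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$weight, edges$herb_id, edges$indication_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  structure(list(members = members, nodes = nodes, edges = edges),
            class = "hi_network")
}

#' @export
print.hi_network <- function(x, ...) {
  cat(sprintf("<hi_network> %d prescriptions, %d herb + %d indication nodes, %d edges\n",
              length(x$members), sum(x$nodes$kind == "herb"),
              sum(x$nodes$kind == "indication"), nrow(x$edges)))
  invisible(x)
}

#' Extract the subnetwork of one cluster
#'
#' Builds the herb-indication network restricted to the prescriptions of one
#' cluster. Across all clusters of a partition, subnetwork edge weights sum
#' to the full-network edge weights.
#'
#' @param corpus a `prescription_corpus`.
#' @param assignment a `cluster_assignment` over the corpus.
#' @param cluster_label cluster label in `1..k`.
#' @return an `hi_network`.
#' @export
extract_subnetwork <- function(corpus, assignment, cluster_label) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!cluster_label %in% assignment$labels) {
    abort_parameter(paste0("no such cluster label: ", cluster_label))
  }
  build_hi_network(corpus, members = assignment$ids[assignment$labels == cluster_label])
}

node_frequencies <- function(net, kind) {
  sel <- net$nodes$kind == kind
  stats::setNames(net$nodes$frequency[sel], net$nodes$token_id[sel])
}

#' Common major nodes of two subnetworks
#'
#' Tokens of one kind that are "major" (frequent) in both networks: either
#' those whose frequency reaches `min_freq` in both, or those among the
#' `top_n` most frequent of that kind in both (frequency descending, ties by
#' token id). Exactly one threshold mode must be given.
#'
#' @param net_a,net_b `hi_network` objects.
#' @param kind `"herb"` or `"indication"`.
#' @param min_freq minimum appearance frequency required in both networks.
#' @param top_n rank cutoff applied within each network.
#' @return character vector of token ids, ordered by the smaller of the two
#'   frequencies (descending), then token id.
#' @export
common_major_nodes <- function(net_a, net_b, kind = c("herb", "indication"),
                               min_freq = NULL, top_n = NULL) {
  kind <- match.arg(kind)
  if (is.null(min_freq) == is.null(top_n)) {
    abort_parameter("give exactly one of min_freq or top_n")
  }
  fa <- node_frequencies(net_a, kind)
  fb <- node_frequencies(net_b, kind)
  major <- function(f) {
    if (!is.null(min_freq)) return(names(f)[f >= min_freq])
    ord <- order(-f, names(f))
    names(f)[ord][seq_len(min(top_n, length(f)))]
  }
  common <- intersect(major(fa), major(fb))
  if (!length(common)) return(character(0))
  key <- pmin(fa[common], fb[common])
  common[order(-key, common)]
}

#' Compare two cluster subnetworks
#'
#' Computes the common major herbs and common major indications of two
#' subnetworks. The default threshold is `min_freq = ceiling(m / 2)` where
#' `m` is the smaller member count: a token must appear in at least half of
#' the smaller group's prescriptions in both groups.
#'
#' @param net_a,net_b `hi_network` objects.
#' @param min_freq,top_n threshold passed to [common_major_nodes()]; if both
#'   are `NULL` the half-of-smaller-cluster default is used.
#' @return object of class `subnetwork_comparison` with elements
#'   `common_major_herbs`, `common_major_indications`, `min_freq`, `top_n`.
#' @export
compare_subnetworks <- function(net_a, net_b, min_freq = NULL, top_n = NULL) {
  if (is.null(min_freq) && is.null(top_n)) {
    min_freq <- ceiling(min(length(net_a$members), length(net_b$members)) / 2)
  }
  structure(
    list(
      common_major_herbs = common_major_nodes(net_a, net_b, "herb",
                                              min_freq = min_freq, top_n = top_n),
      common_major_indications = common_major_nodes(net_a, net_b, "indication",
                                                    min_freq = min_freq, top_n = top_n),
      min_freq = min_freq, top_n = top_n,
      members_a = net_a$members, members_b = net_b$members
    ),
    class = "subnetwork_comparison"
  )
}

#' @export
print.subnetwork_comparison <- function(x, ...) {
  cat("<subnetwork_comparison>",
      if (!is.null(x$min_freq)) sprintf("min_freq=%d", x$min_freq)
      else sprintf("top_n=%d", x$top_n), "\n")
  cat("  common major herbs:      ", paste(x$common_major_herbs, collapse = ", "), "\n")
  cat("  common major indications:", paste(x$common_major_indications, collapse = ", "), "\n")
  invisible(x)
}

#' Convert an `hi_network` to an igraph bipartite graph
#' @param net an `hi_network`.
#' @return an `igraph` graph with vertex attributes `kind`, `frequency`,
#'   `name` (token id), `label` (display name) and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hi_network"))
  vertices <- data.frame(
    name = net$nodes$token_id, kind = net$nodes$kind,
    frequency = net$nodes$frequency, label = net$nodes$name,
    type = net$nodes$kind == "indication",
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = net$edges$herb_id, to = net$edges$indication_id,
                      weight = net$edges$weight, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export network tables and GraphML
#'
#' Writes the edge list (`herb_id`, `indication_id`, `weight`), the node
#' table (`token_id`, `kind`, `frequency`), and a GraphML file for downstream
#' renderers. Scaling of node sizes and edge thickness is left to the
#' renderer; raw frequencies and weights are the contract.
#'
#' @param net an `hi_network`.
#' @param edges_path,nodes_path,graphml_path output paths (any may be `NULL`
#'   to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, edges_path = NULL, nodes_path = NULL,
                          graphml_path = NULL) {
  out <- character(0)
  if (!is.null(edges_path)) {
    write_tsv_plain(net$edges, edges_path)
    out <- c(out, edges_path)
  }
  if (!is.null(nodes_path)) {
    write_tsv_plain(net$nodes[, c("token_id", "kind", "frequency")], nodes_path)
    out <- c(out, nodes_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
    out <- c(out, graphml_path)
  }
  invisible(out)
}

#' Force-directed layout for an `hi_network`
#'
#' Convenience export of Fruchterman-Reingold coordinates with a fixed seed:
#' heavier (more co-occurring) pairs land closer. Coordinates are for
#' plotting only and are not a stable contract of the data model.
#'
#' @param net an `hi_network`.
#' @param seed RNG seed for the layout.
#' @return data.frame with `token_id`, `kind`, `x`, `y`.
#' @export
hi_layout <- function(net, seed = 1L) {
  g <- as_igraph(net)
  xy <- with_rng_seed(seed, igraph::layout_with_fr(g, weights = igraph::E(g)$weight))
  data.frame(token_id = igraph::V(g)$name, kind = igraph::V(g)$kind,
             x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
}
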