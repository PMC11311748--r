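#' Jaccard coefficient between two token sets
#'
#' `J(X, Y) = |X intersect Y| / |X union Y|`: the fraction of all herbs used
#' in either prescription that the two prescriptions share. 1 iff the sets
#' are equal, 0 iff they are disjoint.
#'
#' @param set_a,set_b character vectors (treated as sets; duplicates ignored).
#' @return similarity in `[0, 1]`.
#' @details Both sets empty is a 0/0 form and raises an error rather than
#'   returning a convention value; valid corpora guarantee non-empty herb
#'   sets so the case never arises in the pipeline.
#' @examples
#' jaccard_coefficient(c("H1", "H12", "H15"), c("H1", "H12", "H42")) # 0.5
#' @export
jaccard_coefficient <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) abort_input("Jaccard coefficient undefined: both sets empty")
  length(intersect(a, b)) / u
}

#' Jaccard distance between two token sets
#'
#' `d(X, Y) = 1 - J(X, Y)`; a metric on finite sets.
#'
#' @inheritParams jaccard_coefficient
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(set_a, set_b) 1 - jaccard_coefficient(set_a, set_b)

#' Pairwise Jaccard distance matrix over a corpus
#'
#' Computes all pairwise Jaccard distances between prescriptions' herb sets
#' (optionally indication or combined sets), as the dissimilarity input for
#' hierarchical clustering, MDS embedding, and silhouette computation.
#'
#' @param corpus a `prescription_corpus`.
#' @param on which token sets to compare: `"herb"` (default; clustering is
#'   based on the similarity of constituent herbs), `"indication"`, or
#'   `"combined"` (union of both kinds).
#' @return a symmetric numeric matrix with zero diagonal, prescription ids as
#'   dimnames, entries `1 - J` in `[0, 1]`.
#' @export
jaccard_distance_matrix <- function(corpus, on = c("herb", "indication", "combined")) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  on <- match.arg(on)
  m <- switch(on,
    herb = to_incidence(corpus, "herb"),
    indication = to_incidence(corpus, "indication"),
    combined = cbind(to_incidence(corpus, "herb"), to_incidence(corpus, "indication"))
  )
  sizes <- rowSums(m)
  if (any(sizes == 0)) {
    abort_validation(paste0(
      "empty token set(s) for: ",
      paste(rownames(m)[sizes == 0], collapse = ", ")
    ))
  }
  inter <- tcrossprod(m)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Write a distance matrix as TSV
#'
#' Square layout with a leading id column and id header, values printed to 10
#' significant digits, so identical matrices produce byte-identical files.
#'
#' @param dist_matrix symmetric matrix with id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist_matrix, path) {
  ids <- rownames(dist_matrix)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("prescription_id", ids), collapse = "\t"), con, sep = "\n")
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], sprintf("%.10g", dist_matrix[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path input path.
#' @return symmetric numeric matrix with id dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  m
}
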