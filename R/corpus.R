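#' Construct a prescription corpus
#'
#' A prescription corpus holds an ordered set of prescriptions, each with a
#' set of herb tokens and a set of indication tokens, plus a token registry.
#' Prescription order is stable and defines the row order of every matrix
#' derived downstream; token first-appearance order defines column order.
#'
#' @param prescription_id character vector, one entry per prescription-token
#'   pair (long format).
#' @param token_id character vector of token identifiers (conventionally
#'   `H*` for herbs and `S*` for indications, but IDs are treated as opaque).
#' @param token_kind character vector, each `"herb"` or `"indication"`.
#' @param prescription_name optional display names (recycled per id; first
#'   non-missing value wins).
#' @param token_name optional token display names.
#' @return An object of class `prescription_corpus`: a list with elements
#'   `prescriptions` (data.frame: `prescription_id`, `name`), `herbs` and
#'   `indications` (named lists of sorted token-id character vectors), and
#'   `tokens` (data.frame: `token_id`, `name`, `kind`).
#' @details Duplicate (prescription, token) pairs collapse to one set element.
#'   A token used with two kinds raises a consistency error; a prescription
#'   with no herb tokens raises a validation error naming it (herb vectors
#'   drive all clustering). Prescriptions with no indications are accepted
#'   with a logged warning: they contribute no herb-indication edges.
#' @examples
#' corp <- prescription_corpus(
#'   prescription_id = c("P-1", "P-1", "P-2"),
#'   token_id = c("H1", "S13", "H1"),
#'   token_kind = c("herb", "indication", "herb")
#' )
#' corpus_summary(corp)$n_prescriptions
#' @export
prescription_corpus <- function(prescription_id, token_id, token_kind,
                                prescription_name = NULL, token_name = NULL) {
  n <- length(prescription_id)
  if (length(token_id) != n || length(token_kind) != n) {
    abort_format("prescription_id, token_id and token_kind must have equal length")
  }
  prescription_id <- as.character(prescription_id)
  token_id <- as.character(token_id)
  token_kind <- as.character(token_kind)
  if (!all(token_kind %in% c("herb", "indication"))) {
    bad <- unique(token_kind[!token_kind %in% c("herb", "indication")])
    abort_format(paste0("unknown token_kind value(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(prescription_id) || anyNA(token_id)) {
    abort_format("missing prescription_id or token_id")
  }

  # token registry, kind consistency, first-appearance order
  tok_first <- !duplicated(token_id)
  tokens <- data.frame(
    token_id = token_id[tok_first],
    name = NA_character_,
    kind = token_kind[tok_first],
    stringsAsFactors = FALSE
  )
  kind_map <- stats::setNames(tokens$kind, tokens$token_id)
  mismatch <- token_kind != kind_map[token_id]
  if (any(mismatch)) {
    abort_consistency(paste0(
      "token(s) used with more than one kind: ",
      paste(unique(token_id[mismatch]), collapse = ", ")
    ))
  }
  if (!is.null(token_name)) {
    nm <- as.character(token_name)
    keep <- !is.na(nm) & !duplicated(token_id)
    tokens$name[match(token_id[keep], tokens$token_id)] <- nm[keep]
  }
  tokens$name <- ifelse(is.na(tokens$name), tokens$token_id, tokens$name)

  pres_ids <- unique(prescription_id)
  pres_names <- pres_ids
  if (!is.null(prescription_name)) {
    pn <- as.character(prescription_name)
    first <- tapply(seq_len(n), prescription_id, min)[pres_ids]
    pres_names <- ifelse(is.na(pn[first]), pres_ids, pn[first])
  }

  split_kind <- function(kind) {
    sel <- token_kind == kind
    sets <- lapply(pres_ids, function(p) {
      sort(unique(token_id[sel & prescription_id == p]))
    })
    names(sets) <- pres_ids
    sets
  }
  herbs <- split_kind("herb")
  indications <- split_kind("indication")

  empty_herbs <- pres_ids[vapply(herbs, length, 1L) == 0L]
  if (length(empty_herbs)) {
    abort_validation(paste0(
      "prescription(s) with no herb tokens: ", paste(empty_herbs, collapse = ", ")
    ))
  }
  no_ind <- pres_ids[vapply(indications, length, 1L) == 0L]
  if (length(no_ind)) {
    fn_log("warn", "prescription(s) with no indications (no H-I edges): ",
           paste(no_ind, collapse = ", "))
  }

  structure(
    list(
      prescriptions = data.frame(prescription_id = pres_ids, name = pres_names,
                                 stringsAsFactors = FALSE),
      herbs = herbs,
      indications = indications,
      tokens = tokens
    ),
    class = "prescription_corpus"
  )
}

#' @export
print.prescription_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat(sprintf(
    "<prescription_corpus> %d prescriptions, %d herb tokens, %d indication tokens\n",
    s$n_prescriptions, s$n_herbs, s$n_indications
  ))
  invisible(x)
}

#' Number of prescriptions in a corpus
#' @param corpus a `prescription_corpus`.
#' @return integer count.
#' @export
n_prescriptions <- function(corpus) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  nrow(corpus$prescriptions)
}

#' Prescription identifiers in corpus order
#' @param corpus a `prescription_corpus`.
#' @return character vector.
#' @export
prescription_ids <- function(corpus) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  corpus$prescriptions$prescription_id
}

#' Token identifiers of one kind, in registry (first-appearance) order
#' @param corpus a `prescription_corpus`.
#' @param kind `"herb"` or `"indication"`.
#' @return character vector.
#' @export
token_ids <- function(corpus, kind = c("herb", "indication")) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  kind <- match.arg(kind)
  corpus$tokens$token_id[corpus$tokens$kind == kind]
}

#' Read a long-format prescription corpus file
#'
#' Expects a delimited table with header columns `prescription_id`,
#' `token_id`, `token_kind` and optionally `prescription_name`, `token_name`.
#' A `dosage` column, if present, is ignored with a warning. Files are read
#' as UTF-8.
#'
#' @param path file path.
#' @param delimiter field delimiter; `NULL` (default) auto-detects tab vs
#'   comma from the header line.
#' @return a [prescription_corpus].
#' @export
read_corpus <- function(path, delimiter = NULL) {
  if (!file.exists(path)) abort_input(paste0("no such file: ", path))
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          encoding = "UTF-8", colClasses = "character")
  required <- c("prescription_id", "token_id", "token_kind")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_format(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if ("dosage" %in% names(df)) {
    warning("dosage column present; dosages are excluded from the analysis",
            call. = FALSE)
  }
  prescription_corpus(
    prescription_id = df$prescription_id,
    token_id = df$token_id,
    token_kind = df$token_kind,
    prescription_name = if ("prescription_name" %in% names(df)) df$prescription_name,
    token_name = if ("token_name" %in% names(df)) df$token_name
  )
}

#' Write a corpus in the long format accepted by [read_corpus()]
#'
#' Rows are emitted in corpus order, herbs before indications within each
#' prescription, tokens sorted by id, so write/read round-trips are exact.
#'
#' @param corpus a `prescription_corpus`.
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, delimiter = "\t") {
  stopifnot(inherits(corpus, "prescription_corpus"))
  ids <- prescription_ids(corpus)
  rows <- do.call(rbind, lapply(ids, function(p) {
    toks <- c(corpus$herbs[[p]], corpus$indications[[p]])
    data.frame(prescription_id = p, token_id = toks, stringsAsFactors = FALSE)
  }))
  rows$token_kind <- corpus$tokens$kind[match(rows$token_id, corpus$tokens$token_id)]
  rows$prescription_name <- corpus$prescriptions$name[
    match(rows$prescription_id, corpus$prescriptions$prescription_id)]
  rows$token_name <- corpus$tokens$name[match(rows$token_id, corpus$tokens$token_id)]
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = delimiter), con, sep = "\n")
  writeLines(do.call(paste, c(unname(rows), sep = delimiter)), con, sep = "\n")
  invisible(path)
}

#' Binary incidence matrix of a corpus
#'
#' Rows follow corpus order; columns follow token-registry order for the
#' requested kind. Entry (i, j) is 1 iff prescription i contains token j.
#'
#' @param corpus a `prescription_corpus`.
#' @param kind `"herb"` or `"indication"`.
#' @return an integer 0/1 matrix with prescription ids as rownames and token
#'   ids as colnames.
#' @export
to_incidence <- function(corpus, kind = c("herb", "indication")) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  kind <- match.arg(kind)
  ids <- prescription_ids(corpus)
  if (!length(ids)) abort_input("empty corpus")
  cols <- token_ids(corpus, kind)
  sets <- if (kind == "herb") corpus$herbs else corpus$indications
  m <- matrix(0L, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (p in ids) m[p, sets[[p]]] <- 1L
  m
}

#' Build a corpus from wide binary incidence matrices
#'
#' Convenience constructor for data already vectorized as presence/absence
#' matrices (prescriptions in rows, tokens in columns).
#'
#' @param herb_matrix binary matrix with prescription rownames and herb-token
#'   colnames; every row must contain at least one 1.
#' @param indication_matrix optional binary matrix over the same rows.
#' @return a [prescription_corpus].
#' @export
corpus_from_incidence <- function(herb_matrix, indication_matrix = NULL) {
  if (is.null(rownames(herb_matrix)) || is.null(colnames(herb_matrix))) {
    abort_format("herb_matrix must have prescription rownames and token colnames")
  }
  if (!all(herb_matrix %in% c(0, 1))) abort_format("incidence entries must be 0/1")
  long <- which(herb_matrix == 1, arr.ind = TRUE)
  pid <- rownames(herb_matrix)[long[, 1L]]
  tid <- colnames(herb_matrix)[long[, 2L]]
  kind <- rep("herb", length(pid))
  if (!is.null(indication_matrix)) {
    if (!identical(rownames(indication_matrix), rownames(herb_matrix))) {
      abort_consistency("indication_matrix rows must match herb_matrix rows")
    }
    if (!all(indication_matrix %in% c(0, 1))) abort_format("incidence entries must be 0/1")
    il <- which(indication_matrix == 1, arr.ind = TRUE)
    pid <- c(pid, rownames(indication_matrix)[il[, 1L]])
    tid <- c(tid, colnames(indication_matrix)[il[, 2L]])
    kind <- c(kind, rep("indication", nrow(il)))
  }
  ord <- order(match(pid, rownames(herb_matrix)))
  prescription_corpus(pid[ord], tid[ord], kind[ord])
}

#' Summarize a corpus
#'
#' @param corpus a `prescription_corpus`.
#' @return a list with `n_prescriptions`, `n_herbs`, `n_indications`, and
#'   `token_frequency` (data.frame: `token_id`, `kind`, `frequency` = number
#'   of prescriptions containing the token, sorted by frequency descending
#'   then token id).
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  freq_of <- function(kind) {
    m <- to_incidence(corpus, kind)
    data.frame(token_id = colnames(m), kind = kind, frequency = unname(colSums(m)),
               stringsAsFactors = FALSE)
  }
  tf <- rbind(freq_of("herb"), freq_of("indication"))
  tf <- tf[order(-tf$frequency, tf$token_id), , drop = FALSE]
  rownames(tf) <- NULL
  list(
    n_prescriptions = n_prescriptions(corpus),
    n_herbs = length(token_ids(corpus, "herb")),
    n_indications = length(token_ids(corpus, "indication")),
    token_frequency = tf
  )
}
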