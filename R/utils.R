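# Internal helpers: classed conditions, seeded RNG isolation, structured
# logging, and deterministic table writers shared across modules.

fn_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "formulanet_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_format      <- function(msg) fn_abort(msg, "formulanet_format_error")
abort_consistency <- function(msg) fn_abort(msg, "formulanet_consistency_error")
abort_validation  <- function(msg) fn_abort(msg, "formulanet_validation_error")
abort_parameter   <- function(msg) fn_abort(msg, "formulanet_parameter_error")
abort_input       <- function(msg) fn_abort(msg, "formulanet_input_error")

# Run `expr` under a given RNG seed without disturbing the caller's RNG
# stream (the global .Random.seed is restored on exit).
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_parameter("`seed` must be a single non-missing number")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

fn_log <- function(level = c("info", "debug", "warn"), ..., verbosity = getOption("formulanet.log_level", "info")) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, silent = 4L)
  if (ranks[[level]] < ranks[[match.arg(verbosity, names(ranks))]]) return(invisible(NULL))
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [", toupper(level), "] ", ...)
  message(msg)
  invisible(NULL)
}

# write.table wrapper producing byte-stable TSVs: no quoting surprises,
# fixed "\n" EOL, numbers preformatted by the caller where precision matters.
write_tsv_plain <- function(df, path, comment_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comment_lines)) {
    writeLines(paste0("# ", comment_lines), con, sep = "\n")
  }
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
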