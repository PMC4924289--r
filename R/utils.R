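# internal validation helpers -------------------------------------------

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("frbpipe_format_error",
                                             "frbpipe_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("frbpipe_validation_error",
                                             "frbpipe_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("frbpipe_config_error",
                                             "frbpipe_error")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_validation(name, " must be a single value in [0, 1], got ",
                    deparse(substitute(x)))
  x
}

# deterministic TSV writer used for every tabular output so that reruns
# are byte-identical
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
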