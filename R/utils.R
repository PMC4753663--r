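# Internal helpers: seeding, assertions, stage-tagged errors, tsv io.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-component substream seed derived from a global seed.
# Adding component n+1 never reshuffles components 1..n because each
# component draws from its own stream. Kept below 2^31 - 1.
substream <- function(seed, stream, index = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  h <- (h * 48271 + as.numeric(stream) * 7919) %% m
  h <- (h * 48271 + as.numeric(index)) %% m
  as.integer(h)
}

ferm_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Stage-tagged error used by run_pipeline so the CLI can map failures to
# exit code 3 and name the failing stage.
ferm_stage_error <- function(stage, message) {
  structure(
    class = c("ferm_stage_error", "error", "condition"),
    list(message = sprintf("[stage:%s] %s", stage, message), call = NULL,
         stage = stage)
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Read or write a tab-delimited table with a header row
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] fixing
#' the conventions used by every table this package emits: tab separator,
#' header, no quoting, no row names.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
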