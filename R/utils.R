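# Internal helpers: error conditions, seed substreams, TSV conventions.

cond_classes <- c(
  config = "hepmeta_config_error",
  format = "hepmeta_format_error",
  processing = "hepmeta_processing_error",
  data = "hepmeta_data_error",
  generation = "hepmeta_generation_error",
  quantification = "hepmeta_quantification_error"
)

hep_stop <- function(type, msg, ...) {
  msg <- sprintf(msg, ...)
  stop(structure(
    class = c(cond_classes[[type]], "hepmeta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
hep_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

# Derive a reproducible 32-bit substream seed from a base seed and a stream
# name, so each artifact (expression, gmt, slide, ...) can be regenerated
# independently of the others.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Uniform TSV writers so repeated runs are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
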