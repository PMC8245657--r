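`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant identifier
#'
#' @param transcript_id,cds_position,ref,alt vectors describing variants.
#' @return character `transcript:pos:ref:alt` keys.
#' @export
variantId <- function(transcript_id, cds_position, ref, alt) {
  paste(transcript_id, cds_position, ref, alt, sep = ":")
}

# tab-separated writer with fixed float formatting (6 significant digits)
# so outputs are byte-identical across runs and platforms
.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", na = "NA")
  invisible(path)
}

.assertCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# derive a stream-specific child seed from a base seed, kept < 2^31
.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

.logMsg <- function(level, ...) {
  lev <- getOption("neoprofiler.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[lev]] <= ranks[[level]])
    message("[", level, "] ", ...)
  invisible(NULL)
}
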