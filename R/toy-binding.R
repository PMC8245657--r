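.pkgCache <- new.env(parent = emptyenv())

# frozen 20x11 base position-weight matrix shipped as a text asset
.toyWeights <- function() {
  if (is.null(.pkgCache$toyW)) {
    path <- system.file("extdata", "toy_binding_weights.tsv",
                        package = "neoprofiler")
    df <- read.delim(path, check.names = FALSE)
    W <- as.matrix(df[, -1, drop = FALSE])
    rownames(W) <- df[[1]]
    .pkgCache$toyW <- W[AA_ALPHABET, , drop = FALSE]
  }
  .pkgCache$toyW
}

#' Deterministic matrix-based peptide--HLA binding model
#'
#' A reproducible stand-in for an external HLA class I affinity predictor.
#' Each allele defines a position-weight matrix: a fixed 20x11 base matrix
#' shipped with the package, row-rotated by an arithmetic hash of the
#' allele name (no randomness at prediction time). A peptide scores the
#' anchor-weighted mean of its per-position weights (positions 2 and the
#' C-terminus weigh 3x, the classic class I anchor positions), and the
#' score `s` in `[0, 1]` maps monotonically onto IC50 nM as
#' `50000 * exp(-6 s)`, i.e. onto `(0, 50000]` with stronger scores giving
#' lower IC50. Same peptide and allele always give the same IC50, on any
#' platform.
#'
#' @param peptides character vector of peptides (length 8-11, standard
#'   residues only).
#' @param allele a single HLA allele name.
#' @return numeric vector of IC50 values in nM.
#' @examples
#' toyBindingModel(c("SIINFEKLM", "SIINFEKLV"), "HLA-A*02:01")
#' @export
toyBindingModel <- function(peptides, allele) {
  if (length(allele) != 1L || is.na(allele) || !nzchar(allele))
    stop("allele name must be a single non-empty string", call. = FALSE)
  if (length(peptides) == 0L) return(numeric(0))
  lens <- nchar(peptides)
  if (any(is.na(peptides)) || any(lens < 8L | lens > 11L))
    stop("peptides must be 8-11 residues long", call. = FALSE)
  chars <- strsplit(peptides, "")
  if (!all(unlist(chars) %in% AA_ALPHABET))
    stop("peptide contains a non-standard residue", call. = FALSE)
  W <- .toyWeights()
  rot <- sum(utf8ToInt(allele) * seq_len(nchar(allele))) %% 20L
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    idx <- matrix(match(unlist(chars[sel]), AA_ALPHABET),
                  ncol = L, byrow = TRUE)
    idx <- ((idx - 1L + rot) %% 20L) + 1L
    m <- rep(1, L); m[2L] <- 3; m[L] <- 3
    w <- matrix(W[cbind(as.vector(idx), rep(seq_len(L), each = length(sel)))],
                ncol = L)
    s <- as.vector(w %*% m) / sum(m)
    out[sel] <- 50000 * exp(-6 * s)
  }
  out
}

#' Affinity predictor objects
#'
#' A predictor is a function `f(peptides, allele)` returning IC50 nM (with
#' `NA` for unresolved pairs) plus a `predictor_id` attribute.
#' `toyPredictor()` wraps [toyBindingModel]; `tablePredictor()` wraps an
#' affinity lookup read with [readAffinityTable].
#'
#' @param affinities an `AffinityTable` from [readAffinityTable].
#' @return a predictor function.
#' @export
toyPredictor <- function() {
  f <- function(peptides, allele) toyBindingModel(peptides, allele)
  attr(f, "predictor_id") <- "toy-pwm-v1"
  f
}

#' @rdname toyPredictor
#' @export
tablePredictor <- function(affinities) {
  stopifnot(inherits(affinities, "AffinityTable"))
  f <- function(peptides, allele) affinityLookup(affinities, peptides, allele)
  attr(f, "predictor_id") <- "affinity-table"
  f
}
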