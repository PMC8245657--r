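#' Read / write allele-count tables
#'
#' Tab-separated, one row per site, columns `transcript_id`,
#' `cds_position`, `ref`, `alt`, `tumor_ref`, `tumor_alt`, `normal_ref`,
#' `normal_alt`. The reader validates every row (non-negative integer
#' counts, single-base ref, alt a base or `INS`/`DEL`) and names the
#' offending line in its error; it never silently coerces.
#'
#' @param path file path.
#' @param sites data.frame of allele-count sites (extra columns such as
#'   `site_type` are dropped on write).
#' @return `readAlleleCounts` returns the validated data.frame;
#'   `writeAlleleCounts` the path, invisibly.
#' @export
readAlleleCounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = c(
    transcript_id = "character", cds_position = "integer",
    ref = "character", alt = "character", tumor_ref = "integer",
    tumor_alt = "integer", normal_ref = "integer", normal_alt = "integer"))
  .assertCols(df, c("transcript_id", "cds_position", "ref", "alt",
                    "tumor_ref", "tumor_alt", "normal_ref", "normal_alt"),
              "allele-count file")
  countCols <- c("tumor_ref", "tumor_alt", "normal_ref", "normal_alt")
  for (col in countCols) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0L)
    if (length(bad))
      stop("invalid ", col, " at line ", bad[1] + 1L, " of ", path,
           call. = FALSE)
  }
  bad <- which(is.na(df$cds_position) | df$cds_position < 1L)
  if (length(bad))
    stop("invalid cds_position at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  bad <- which(!df$ref %in% c("A", "C", "G", "T") |
               !df$alt %in% c("A", "C", "G", "T", INDEL_TOKENS))
  if (length(bad))
    stop("invalid ref/alt at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  df
}

#' @rdname readAlleleCounts
#' @export
writeAlleleCounts <- function(sites, path) {
  cols <- c("transcript_id", "cds_position", "ref", "alt", "tumor_ref",
            "tumor_alt", "normal_ref", "normal_alt")
  .assertCols(sites, cols, "allele-count table")
  .writeTsv(sites[, cols], path)
}

#' Read / write RNA read-count tables
#'
#' Tab-separated `variant_id`, `covering`, `mutant` counts per mutated
#' position.
#'
#' @param path file path.
#' @param counts data.frame (`variant_id`, `covering`, `mutant`).
#' @return the data.frame / the path.
#' @export
readRnaCounts <- function(path) {
  df <- read.delim(path, colClasses = c(variant_id = "character",
                                        covering = "integer",
                                        mutant = "integer"))
  .assertCols(df, c("variant_id", "covering", "mutant"),
              "RNA read-count file")
  bad <- which(is.na(df$covering) | df$covering < 0L |
               is.na(df$mutant) | df$mutant < 0L)
  if (length(bad))
    stop("negative or missing read count at line ", bad[1] + 1L, " of ",
         path, call. = FALSE)
  df
}

#' @rdname readRnaCounts
#' @export
writeRnaCounts <- function(counts, path) {
  .assertCols(counts, c("variant_id", "covering", "mutant"),
              "RNA read-count table")
  .writeTsv(counts[, c("variant_id", "covering", "mutant")], path)
}

#' Read / write HLA class I genotypes
#'
#' Tab-separated `patient_id`, `alleles` (comma-separated allele names,
#' at most 6 per patient).
#'
#' @param path file path.
#' @param genotypes named list of character vectors (names are patient
#'   ids).
#' @return named list of allele vectors / the path.
#' @export
readHlaGenotypes <- function(path) {
  df <- read.delim(path, colClasses = "character")
  .assertCols(df, c("patient_id", "alleles"), "HLA genotype file")
  out <- lapply(strsplit(df$alleles, ","), trimws)
  names(out) <- df$patient_id
  if (any(lengths(out) > 6L))
    stop("a patient may carry at most 6 HLA class I alleles", call. = FALSE)
  out
}

#' @rdname readHlaGenotypes
#' @export
writeHlaGenotypes <- function(genotypes, path) {
  df <- data.frame(patient_id = names(genotypes),
                   alleles = vapply(genotypes, paste, "", collapse = ","))
  .writeTsv(df, path)
}

#' Read an affinity table (NetMHC-like TSV dialect)
#'
#' Tab-separated columns `allele`, `peptide`, `ic50_nm`. Duplicate
#' (peptide, allele) rows are resolved by keeping the minimum IC50 with a
#' logged warning — conservative toward calling a peptide a binder; in
#' strict mode conflicting duplicates are an error. Missing pairs looked
#' up later return `NA`, never 0.
#'
#' @param path file path.
#' @param strict error on conflicting duplicate rows (default FALSE).
#' @return an `AffinityTable` object usable with [tablePredictor] and
#'   [affinityLookup].
#' @export
readAffinityTable <- function(path, strict = FALSE) {
  df <- read.delim(path, colClasses = c(allele = "character",
                                        peptide = "character",
                                        ic50_nm = "numeric"))
  .assertCols(df, c("allele", "peptide", "ic50_nm"), "affinity table")
  if (anyNA(df$ic50_nm))
    stop("non-numeric IC50 in ", path, call. = FALSE)
  key <- paste(df$peptide, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    conflicting <- tapply(df$ic50_nm, key, function(v) length(unique(v)) > 1)
    if (strict && any(conflicting))
      stop("conflicting duplicate affinity rows in ", path, call. = FALSE)
    .logMsg("warn", sum(duplicated(key)),
            " duplicate affinity row(s); keeping the minimum IC50")
    keep <- order(df$ic50_nm)
    df <- df[keep, , drop = FALSE]
    df <- df[!duplicated(paste(df$peptide, df$allele, sep = "\r")), ,
             drop = FALSE]
  }
  obj <- list(ic50 = setNames(df$ic50_nm,
                              paste(df$peptide, df$allele, sep = "\r")))
  class(obj) <- "AffinityTable"
  obj
}

#' @rdname readAffinityTable
#' @param affinities an `AffinityTable`.
#' @param peptides,allele pairs to resolve.
#' @export
affinityLookup <- function(affinities, peptides, allele) {
  stopifnot(inherits(affinities, "AffinityTable"))
  unname(affinities$ic50[paste(peptides, allele, sep = "\r")])
}

#' @rdname readAffinityTable
#' @param table data.frame with `allele`, `peptide`, `ic50_nm` (written
#'   as-is).
#' @export
writeAffinityTable <- function(table, path) {
  .assertCols(table, c("allele", "peptide", "ic50_nm"), "affinity table")
  .writeTsv(table[, c("allele", "peptide", "ic50_nm")], path)
}

#' Write / read classified variants as minimal VCF 4.2
#'
#' CHROM is the transcript id and POS the 1-based CDS coordinate (the
#' pipeline's coordinate system), REF/ALT the bases or `INS`/`DEL`
#' tokens (written as symbolic `<INS>`/`<DEL>` alleles). Class, Fisher p,
#' VAFs, gene and amino-acid change travel in INFO `key=value` pairs and
#' round-trip exactly. The writer sorts by CHROM then POS (logging when
#' input was unsorted).
#'
#' @param variants classified variant data.frame.
#' @param path file path.
#' @return `writeVariantsVcf` the path invisibly; `readVariantsVcf` the
#'   variant data.frame.
#' @export
writeVariantsVcf <- function(variants, path) {
  .assertCols(variants, c("transcript_id", "cds_position", "ref", "alt",
                          "mutation_class", "fisher_p", "tumor_vaf",
                          "normal_vaf", "gene_symbol"), "variant table")
  ord <- order(variants$transcript_id, variants$cds_position)
  if (!identical(ord, seq_len(nrow(variants))))
    .logMsg("info", "sorting variants by transcript and position for VCF")
  v <- variants[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neoprofiler",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class\">",
    "##INFO=<ID=FP,Number=1,Type=Float,Description=\"Fisher exact p-value\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor VAF\">",
    "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal VAF\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino-acid change ref/pos/alt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(v)) {
    aac <- ifelse(is.na(v$ref_aa), ".",
                  paste0(v$ref_aa, v$protein_position, v$alt_aa))
    alt <- ifelse(v$alt %in% INDEL_TOKENS, paste0("<", v$alt, ">"), v$alt)
    info <- sprintf("CLASS=%s;FP=%s;TVAF=%s;NVAF=%s;GENE=%s;AAC=%s",
                    v$mutation_class, sprintf("%.6g", v$fisher_p),
                    sprintf("%.6g", v$tumor_vaf),
                    sprintf("%.6g", v$normal_vaf), v$gene_symbol, aac)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    v$transcript_id, v$cds_position,
                    variantId(v$transcript_id, v$cds_position, v$ref, v$alt),
                    v$ref, alt, info)
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeVariantsVcf
#' @export
readVariantsVcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF file: ", path, call. = FALSE)
  body <- lines[!startsWith(lines, "#")]
  cols <- c("transcript_id", "cds_position", "ref", "alt", "mutation_class",
            "fisher_p", "tumor_vaf", "normal_vaf", "gene_symbol", "ref_aa",
            "alt_aa", "protein_position", "variant_id")
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    out$cds_position <- integer(0)
    out$fisher_p <- out$tumor_vaf <- out$normal_vaf <- numeric(0)
    out$protein_position <- integer(0)
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 8L))
    stop("malformed VCF body line in ", path, call. = FALSE)
  f <- do.call(rbind, f)
  infoGet <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  alt <- gsub("[<>]", "", f[, 5])
  info <- f[, 8]
  aac <- infoGet(info, "AAC")
  aaRef <- ifelse(aac == ".", NA_character_, sub("^(.)[0-9]+.$", "\\1", aac))
  aaAlt <- ifelse(aac == ".", NA_character_, sub("^.[0-9]+(.)$", "\\1", aac))
  aaPos <- ifelse(aac == ".", NA_character_,
                  sub("^.([0-9]+).$", "\\1", aac))
  data.frame(
    transcript_id = f[, 1], cds_position = as.integer(f[, 2]),
    ref = f[, 4], alt = alt,
    mutation_class = infoGet(info, "CLASS"),
    fisher_p = as.numeric(infoGet(info, "FP")),
    tumor_vaf = as.numeric(infoGet(info, "TVAF")),
    normal_vaf = as.numeric(infoGet(info, "NVAF")),
    gene_symbol = infoGet(info, "GENE"),
    ref_aa = aaRef, alt_aa = aaAlt,
    protein_position = as.integer(aaPos),
    variant_id = f[, 3])
}

#' Write mutant/wildtype peptides as FASTA
#'
#' One record per peptide and its wildtype counterpart; headers encode
#' the source variant, window start and peptide length
#' (`variant|start|length|MUT` / `...|WT`). Written with
#' [Biostrings::writeXStringSet].
#'
#' @param records neoantigen record data.frame (see [neoantigenLoad]).
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writePeptidesFasta <- function(records, path) {
  .assertCols(records, c("variant_id", "start", "length", "sequence",
                         "wildtype_sequence"), "record table")
  u <- records[!duplicated(records[, c("variant_id", "start", "length")]), ,
               drop = FALSE]
  seqs <- Biostrings::AAStringSet(c(rbind(u$sequence,
                                          u$wildtype_sequence)))
  hdr <- sprintf("%s|%d|%d", u$variant_id, u$start, u$length)
  names(seqs) <- c(rbind(paste0(hdr, "|MUT"), paste0(hdr, "|WT")))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a synthetic cohort directory
#'
#' Per patient: allele counts (`<id>.counts.tsv`), RNA read counts
#' (`<id>.rna.tsv`) and ground truth (`<id>.truth.tsv`); cohort-wide: HLA
#' genotypes (`hla.tsv`) and a flat key-value manifest (`cohort.yaml`)
#' listing patient ids and subtypes.
#'
#' @param cohort list of [SyntheticPatient-class] objects.
#' @param dir directory (created if needed).
#' @return `writeCohortDir` the directory invisibly; `readCohortDir` the
#'   list of patients.
#' @export
writeCohortDir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    id <- patientId(p)
    writeAlleleCounts(alleleCounts(p), file.path(dir,
                                                 paste0(id, ".counts.tsv")))
    writeRnaCounts(rnaReadCounts(p), file.path(dir, paste0(id, ".rna.tsv")))
    .writeTsv(trueVariants(p), file.path(dir, paste0(id, ".truth.tsv")))
  }
  writeHlaGenotypes(setNames(lapply(cohort, hlaAlleles),
                             vapply(cohort, patientId, "")),
                    file.path(dir, "hla.tsv"))
  manifest <- list(patients = vapply(cohort, patientId, ""),
                   subtypes = vapply(cohort, subtype, ""))
  yaml::write_yaml(manifest, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' @rdname writeCohortDir
#' @export
readCohortDir <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  hla <- readHlaGenotypes(file.path(dir, "hla.tsv"))
  lapply(seq_along(manifest$patients), function(i) {
    id <- manifest$patients[i]
    counts <- read.delim(file.path(dir, paste0(id, ".counts.tsv")))
    truth <- read.delim(file.path(dir, paste0(id, ".truth.tsv")),
                        colClasses = c(variant_id = "character",
                                       transcript_id = "character",
                                       ref = "character",
                                       alt = "character"))
    new("SyntheticPatient", patientId = id, subtype = manifest$subtypes[i],
        trueVariants = truth,
        alleleCounts = counts,
        rnaReadCounts = readRnaCounts(file.path(dir,
                                                paste0(id, ".rna.tsv"))),
        hlaAlleles = hla[[id]])
  })
}
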