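CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense",
                        "splice_acceptor_donor", "intronic", "utr",
                        "codon_deletion", "frameshift", "other")

#' Read a FASTQ file or character vector with strict validation
#'
#' @param fastq path to a FASTQ file, or a character vector of FASTQ lines.
#' @return character vector of read sequences.
#' @keywords internal
read_fastq_sequences <- function(fastq) {
  lines <- if (length(fastq) == 1 && file.exists(fastq)) readLines(fastq) else fastq
  if (length(lines) == 0) return(character(0))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record at line ",
         4 * (length(lines) %/% 4) + 1, ")")
  idx <- seq(1, length(lines), by = 4)
  bad_hdr <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_hdr))
    stop("malformed FASTQ: header does not start with '@' at line ", bad_hdr[1])
  bad_sep <- idx[!startsWith(lines[idx + 2], "+")]
  if (length(bad_sep))
    stop("malformed FASTQ: separator does not start with '+' at line ",
         bad_sep[1] + 2)
  bad_q <- idx[nchar(lines[idx + 1]) != nchar(lines[idx + 3])]
  if (length(bad_q))
    stop("malformed FASTQ: quality length differs from sequence length at line ",
         bad_q[1] + 3)
  lines[idx + 1]
}

#' Count reads against a designed variant library by exact matching
#'
#' Reads are trimmed to the window between the two primer flanks (a full
#' primer match at each end is required) and exact-matched against the
#' designed sequences of one guide library. Reads that fail primer trimming
#' or match no design are tallied in the `unmatched` attribute.
#'
#' @param fastq FASTQ path or character vector of FASTQ lines.
#' @param library variant library restricted, or restrictable, to one guide.
#' @param guide which guide library to match against.
#' @param primer5,primer3 primer sequences used for trimming.
#' @return data.frame `variant_id`, `guide`, `count` for every library
#'   entry of the guide (zeros included), with attribute `unmatched`
#'   (list: `n_primer_fail`, `n_no_match`).
#' @export
count_reads <- function(fastq, library, guide = "g1",
                        primer5 = "ACGTACGTAC", primer3 = "GTCAGTCAGT") {
  lib <- library[library$guide == guide, ]
  if (nrow(lib) == 0) stop("library has no entries for guide ", guide)
  if (any(is.na(lib$designed_sequence)) || any(lib$designed_sequence == ""))
    stop("every library record needs a designed sequence")
  reads <- read_fastq_sequences(fastq)

  ok5 <- startsWith(reads, primer5)
  ok3 <- endsWith(reads, primer3)
  primer_ok <- ok5 & ok3
  trimmed <- substring(reads[primer_ok], nchar(primer5) + 1,
                       nchar(reads[primer_ok]) - nchar(primer3))
  hit <- match(trimmed, lib$designed_sequence)
  tab <- table(factor(lib$variant_id[hit[!is.na(hit)]],
                      levels = lib$variant_id))
  out <- data.frame(variant_id = lib$variant_id, guide = guide,
                    count = as.integer(tab))
  attr(out, "unmatched") <- list(n_primer_fail = sum(!primer_ok),
                                 n_no_match = sum(is.na(hit)))
  out
}

#' Drop low-abundance variants from a count table
#'
#' Within each guide, variants whose total read count summed over
#' replicates and timepoints is less than or equal to `threshold` are
#' removed (for that guide only). Idempotent.
#'
#' @param counts long count table.
#' @param threshold total-count threshold; the boundary is inclusive
#'   (a total exactly equal to `threshold` is removed).
#' @return filtered count table; attribute `dropped` lists the removed
#'   (variant_id, guide) pairs with their totals.
#' @export
filter_low_abundance <- function(counts, threshold = 10) {
  key <- paste(counts$variant_id, counts$guide)
  totals <- tapply(counts$count, key, sum)
  drop_keys <- names(totals)[totals <= threshold]
  keep <- !(key %in% drop_keys)
  out <- counts[keep, ]
  rownames(out) <- NULL
  dropped <- do.call(rbind, strsplit(drop_keys, " "))
  attr(out, "dropped") <- if (length(drop_keys))
    data.frame(variant_id = dropped[, 1], guide = dropped[, 2],
               total = as.integer(totals[drop_keys]))
  else
    data.frame(variant_id = character(0), guide = character(0),
               total = integer(0))
  for (a in c("days")) attr(out, a) <- attr(counts, a)
  out
}

## ---- TSV readers / writers -------------------------------------------------

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
}

#' Write / read the long-format count table
#'
#' Tab-delimited with header `variant_id guide replicate day count`;
#' row order is canonicalised on read so the table is order-independent.
#'
#' @param counts long count table.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  check_columns(counts, c("variant_id", "guide", "replicate", "day", "count"),
                "count table")
  write.table(counts[, c("variant_id", "guide", "replicate", "day", "count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("variant_id", "guide", "replicate", "day", "count"),
                "count table")
  if (!is.numeric(df$count) || any(df$count != as.integer(df$count)))
    stop("count table contains non-integer counts")
  if (any(df$count < 0)) stop("count table contains negative counts")
  df$count <- as.integer(df$count)
  key <- paste(df$variant_id, df$guide, df$replicate, df$day)
  if (anyDuplicated(key))
    stop("duplicate (variant_id, guide, replicate, day) entries in count table")
  df <- df[order(df$guide, df$variant_id, df$replicate, df$day), ]
  rownames(df) <- NULL
  df
}

#' Write / read the library annotation sidecar
#'
#' @param library library table from [variant_library()] merged with
#'   variant annotations.
#' @param variants variant table from [enumerate_variants()].
#' @param path file path.
#' @export
write_annotation_tsv <- function(library, variants, path) {
  ann <- merge(library[, c("variant_id", "guide", "exon", "pam_codon_flag")],
               variants[, c("variant_id", "consequence")], by = "variant_id")
  ann <- ann[order(ann$guide, ann$variant_id),
             c("variant_id", "consequence", "exon", "guide", "pam_codon_flag")]
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("variant_id", "consequence", "exon", "guide",
                      "pam_codon_flag"), "annotation table")
  bad <- setdiff(unique(df$consequence), CONSEQUENCE_LEVELS)
  if (length(bad))
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(df$variant_id, df$guide)))
    stop("duplicate (variant_id, guide) entries in annotation table")
  df$pam_codon_flag <- as.logical(df$pam_codon_flag)
  df
}

#' Write / read the variant library as VCF 4.2
#'
#' Positions are 1-based (VCF convention); reading rejects any record with
#' position 0, the tell-tale of a 0-based half-open convention.
#'
#' @param variants variant table from [enumerate_variants()].
#' @param path file path (plain-text .vcf).
#' @export
write_library_vcf <- function(variants, path) {
  check_columns(variants, c("variant_id", "contig", "pos", "ref", "alt",
                            "consequence"), "variant table")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", variants$contig[1], ">"),
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tCSQ=%s",
                  variants$contig, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, variants$consequence)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_library_vcf
#' @export
read_library_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  if (any(pos < 1))
    stop("VCF positions must be 1-based (found position ", min(pos),
         "); 0-based coordinates are rejected")
  csq <- sub("^CSQ=", "", fix$INFO)
  data.frame(variant_id = fix$ID, contig = fix$CHROM, pos = pos,
             ref = fix$REF, alt = fix$ALT, consequence = csq)
}

#' Read / write generic schema-checked analysis tables
#'
#' Covers the truth-set, in-silico score, cancer-variant and mutation-rate
#' tables. Missing values are written as `.` and read back as `NA`.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what, numeric_cols = character(0)) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  check_columns(df, required, what)
  for (cl in intersect(numeric_cols, names(df))) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df
}

#' @rdname write_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- read_tsv_checked(path, c("variant_id", "label"), "truth-set table")
  bad <- setdiff(unique(df$label), c("positive", "negative"))
  if (length(bad)) stop("unknown truth label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$variant_id)) stop("duplicate variant_id in truth-set table")
  df
}

#' @rdname write_tsv
#' @export
read_scores_tsv <- function(path) {
  read_tsv_checked(path, "variant_id", "score table",
                   numeric_cols = c("sift", "polyphen2", "revel", "cadd",
                                    "spliceai"))
}

#' @rdname write_tsv
#' @export
read_cancer_tsv <- function(path) {
  df <- read_tsv_checked(path, c("sample", "variant_id", "cancer_type",
                                 "driver_flag"), "cancer variant table")
  df$driver_flag <- as.logical(df$driver_flag)
  df
}

#' @rdname write_tsv
#' @export
read_rate_table_tsv <- function(path) {
  df <- read_tsv_checked(path, c("context", "alt", "rate"), "rate table",
                         numeric_cols = "rate")
  if (any(df$rate <= 0)) stop("mutation rates must be positive")
  if (anyDuplicated(paste(df$context, df$alt)))
    stop("duplicate (context, alt) entries in rate table")
  df
}

#' Read ATOM coordinates from a PDB file
#'
#' @param path PDB file path.
#' @return data.frame `resno`, `resid`, `elety`, `x`, `y`, `z` (ATOM
#'   records only).
#' @export
read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM",
                 c("resno", "resid", "elety", "x", "y", "z")]
  rownames(at) <- NULL
  at
}

#' Write / read a results object as JSON
#'
#' @param x list of results (numbers, vectors, small tables).
#' @param path file path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
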