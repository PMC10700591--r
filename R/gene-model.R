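#' @importFrom stats aggregate chisq.test coef complete.cases cor median
#'   p.adjust pnorm poisson.test predict pt quantile rbeta rlnorm rnbinom
#'   rnorm rpois runif setNames var
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

## codon -> amino acid, standard genetic code (Biostrings's table, "*" = stop)
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(genetic_code()[codons], collapse = "")
}

#' Build a toy multi-exon gene model
#'
#' Generates a random coding sequence split across exons, together with the
#' intronic flanks that a saturation genome editing (SGE) library would
#' mutagenise (25 bp upstream and 15 bp downstream of each exon by default).
#' The translated CDS contains no premature stop codon and exon phases are
#' consistent with cumulative exon lengths.
#'
#' @param exon_count number of coding exons.
#' @param exon_lengths integer vector of exon lengths in nucleotides; their
#'   sum must be divisible by 3.
#' @param phases optional integer vector of exon phases (0/1/2). When given
#'   they are validated against the cumulative exon lengths; when `NULL`
#'   they are derived.
#' @param intron5_length,intron3_length length of the upstream / downstream
#'   intronic flank included per exon.
#' @param seed integer seed; the gene is deterministic given the seed.
#' @return an object of class `sge_gene`: exon table (length, phase, CDS and
#'   contig coordinates), CDS string, per-exon sequences and flanks, and the
#'   concatenated toy contig.
#' @export
make_gene <- function(exon_count, exon_lengths, phases = NULL,
                      intron5_length = 25, intron3_length = 15, seed = 1) {
  if (length(exon_lengths) != exon_count)
    stop("exon_lengths must have length exon_count")
  if (any(exon_lengths <= 0))
    stop("exon lengths must be positive")
  total <- sum(exon_lengths)
  if (total %% 3 != 0)
    stop("sum of coding exon lengths must be divisible by 3")
  derived <- c(0, cumsum(exon_lengths)[-exon_count]) %% 3
  if (is.null(phases)) {
    phases <- derived
  } else {
    if (!all(phases %in% 0:2)) stop("phases must be in {0,1,2}")
    if (!all(phases == derived))
      stop("invalid phase chain: phases must equal cumulative exon lengths mod 3 (expected ",
           paste(derived, collapse = ","), ")")
  }

  set.seed(seed)
  n_codon <- total / 3
  sense <- setdiff(names(genetic_code()), STOP_CODONS)
  codons <- sample(sense, n_codon, replace = TRUE)
  codons[1] <- "ATG"
  ## adjacent identical codons make single-codon deletions ambiguous
  ## (deleting either yields the same sequence); avoid them
  for (i in seq_len(n_codon)[-1]) {
    while (codons[i] == codons[i - 1])
      codons[i] <- sample(sense, 1)
  }
  cds <- paste(codons, collapse = "")

  starts <- cumsum(c(1, exon_lengths[-exon_count]))
  exon_seq <- substring(cds, starts, starts + exon_lengths - 1)
  flank5 <- vapply(seq_len(exon_count), function(i)
    paste(sample(BASES, intron5_length, replace = TRUE), collapse = ""), "")
  flank3 <- vapply(seq_len(exon_count), function(i)
    paste(sample(BASES, intron3_length, replace = TRUE), collapse = ""), "")

  block_len <- intron5_length + exon_lengths + intron3_length
  block_start <- cumsum(c(1, block_len[-exon_count]))
  exon_start_contig <- block_start + intron5_length
  contig <- paste0(flank5, exon_seq, flank3, collapse = "")

  exons <- data.frame(
    exon = seq_len(exon_count),
    length = exon_lengths,
    phase = phases,
    cds_start = starts,
    cds_end = starts + exon_lengths - 1,
    contig_start = exon_start_contig,
    contig_end = exon_start_contig + exon_lengths - 1
  )
  structure(list(
    exons = exons, cds = cds, exon_seq = exon_seq,
    flank5 = flank5, flank3 = flank3,
    intron5_length = intron5_length, intron3_length = intron3_length,
    contig = contig, contig_name = "toy_contig", seed = seed
  ), class = "sge_gene")
}

#' @export
print.sge_gene <- function(x, ...) {
  cat("sge_gene:", nrow(x$exons), "exons,", nchar(x$cds), "coding nt,",
      "contig", nchar(x$contig), "nt\n")
  invisible(x)
}

consequence_of_snv <- function(cds, cds_pos, alt) {
  codon_idx <- (cds_pos - 1) %/% 3 + 1
  within <- (cds_pos - 1) %% 3 + 1
  codon <- substring(cds, (codon_idx - 1) * 3 + 1, codon_idx * 3)
  new_codon <- codon
  substring(new_codon, within, within) <- alt
  gc <- genetic_code()
  aa_ref <- gc[[codon]]
  aa_alt <- gc[[new_codon]]
  if (aa_alt == aa_ref) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else if (aa_ref == "*") "other"
  else "missense"
}

#' Enumerate the designed variant library of a toy gene
#'
#' Produces every coding SNV (three alternatives per coding base), every
#' in-frame single-codon deletion, and every intronic SNV within the flank
#' window. Consequences use the standard genetic code; intronic SNVs within
#' the canonical 2 bp of an exon boundary are labelled splice
#' acceptor/donor.
#'
#' @param gene an `sge_gene`.
#' @return data.frame with one row per variant: `variant_id`, `contig`,
#'   `pos`, `ref`, `alt` (VCF-style, 1-based), `exon`, `cds_pos` (NA for
#'   non-coding), `consequence`, and `codon_index` for codon deletions.
#' @export
enumerate_variants <- function(gene) {
  stopifnot(inherits(gene, "sge_gene"))
  ex <- gene$exons
  gc3 <- genetic_code()
  out <- list()

  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    ## coding SNVs
    for (off in seq_len(e$length)) {
      cds_pos <- e$cds_start + off - 1
      pos <- e$contig_start + off - 1
      ref <- substring(gene$contig, pos, pos)
      for (alt in setdiff(BASES, ref)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, ref = ref, alt = alt, exon = e$exon,
          cds_pos = cds_pos,
          consequence = consequence_of_snv(gene$cds, cds_pos, alt),
          codon_index = NA_integer_
        )
      }
    }
    ## intronic SNVs in the flank windows (acceptor side 5', donor side 3')
    up_start <- e$contig_start - gene$intron5_length
    for (pos in seq(up_start, e$contig_start - 1)) {
      ref <- substring(gene$contig, pos, pos)
      dist <- e$contig_start - pos  # 1 or 2 => canonical splice acceptor
      csq <- if (dist <= 2 && e$exon > 1) "splice_acceptor_donor" else "intronic"
      ## exon 1's upstream flank is promoter-side, keep "intronic" label
      for (alt in setdiff(BASES, ref)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, ref = ref, alt = alt, exon = e$exon,
          cds_pos = NA_integer_, consequence = csq,
          codon_index = NA_integer_
        )
      }
    }
    for (pos in seq(e$contig_end + 1, e$contig_end + gene$intron3_length)) {
      ref <- substring(gene$contig, pos, pos)
      dist <- pos - e$contig_end  # 1 or 2 => canonical splice donor
      csq <- if (dist <= 2 && e$exon < nrow(ex)) "splice_acceptor_donor" else "intronic"
      for (alt in setdiff(BASES, ref)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, ref = ref, alt = alt, exon = e$exon,
          cds_pos = NA_integer_, consequence = csq,
          codon_index = NA_integer_
        )
      }
    }
  }

  ## in-frame single-codon deletions (codons fully inside one exon use VCF
  ## left-anchored representation: ref = anchor base + codon)
  n_codon <- nchar(gene$cds) / 3
  for (ci in seq_len(n_codon)) {
    cds_start <- (ci - 1) * 3 + 1
    hit <- which(ex$cds_start <= cds_start & ex$cds_end >= cds_start + 2)
    if (length(hit) != 1) next  # codon split across exons: not designed
    e <- ex[hit, ]
    pos <- e$contig_start + (cds_start - e$cds_start) - 1  # anchor base
    if (pos < 1) next
    ref <- substring(gene$contig, pos, pos + 3)
    alt <- substring(ref, 1, 1)
    out[[length(out) + 1L]] <- data.frame(
      pos = pos, ref = ref, alt = alt, exon = e$exon,
      cds_pos = cds_start, consequence = "codon_deletion",
      codon_index = ci
    )
  }

  v <- do.call(rbind, out)
  v$contig <- gene$contig_name
  v$variant_id <- sprintf("%s_%d_%s_%s", v$contig, v$pos, v$ref, v$alt)
  if (anyDuplicated(v$variant_id))
    v <- v[!duplicated(v$variant_id), ]
  rownames(v) <- NULL
  v[, c("variant_id", "contig", "pos", "ref", "alt", "exon", "cds_pos",
        "consequence", "codon_index")]
}

## choose a synonymous single-base edit of the codon starting at cds
## position `cds_start`; returns list(pos_in_codon, alt) or NULL
synonymous_edit <- function(codon) {
  gc3 <- genetic_code()
  aa <- gc3[[codon]]
  for (j in 3:1) {
    for (alt in setdiff(BASES, substring(codon, j, j))) {
      cand <- codon
      substring(cand, j, j) <- alt
      if (gc3[[cand]] == aa) return(list(within = j, alt = alt))
    }
  }
  NULL
}

#' Expand a variant table into the two-guide SGE library
#'
#' Each exon is covered by two guide libraries (`g1`, `g2`). Every guide
#' library carries a guide-specific synonymous PAM-codon edit that blocks
#' re-cutting; designed variants overlapping that codon are flagged
#' (`pam_codon_flag`), because on that guide's background they form
#' multi-nucleotide changes whose consequence may differ from the intended
#' one. Designed sequences are the exon window (upstream flank + exon +
#' downstream flank) carrying the PAM edit plus the variant.
#'
#' @param gene an `sge_gene`.
#' @param variants output of [enumerate_variants()].
#' @return data.frame with one row per (variant, guide): `variant_id`,
#'   `guide`, `exon`, `pam_codon_flag`, `pam_codon_index`,
#'   `designed_sequence`.
#' @export
variant_library <- function(gene, variants) {
  stopifnot(inherits(gene, "sge_gene"))
  ex <- gene$exons
  gc3 <- genetic_code()

  ## per exon and guide, pick the PAM codon: first (g1) / last (g2) codon
  ## fully contained in the exon that admits a synonymous edit
  pam <- list()
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    first_codon <- ceiling((e$cds_start - 1) / 3) + 1
    last_codon <- floor(e$cds_end / 3)
    full <- first_codon:last_codon
    full <- full[(full - 1) * 3 + 1 >= e$cds_start & full * 3 <= e$cds_end]
    pick <- function(order_idx) {
      for (ci in order_idx) {
        codon <- substring(gene$cds, (ci - 1) * 3 + 1, ci * 3)
        ed <- synonymous_edit(codon)
        if (!is.null(ed)) return(list(codon_index = ci, edit = ed))
      }
      stop("no codon with a synonymous edit in exon ", e$exon)
    }
    pam[[paste0(e$exon, "_g1")]] <- pick(full)
    pam[[paste0(e$exon, "_g2")]] <- pick(rev(full))
  }

  window_of <- function(exon) {
    e <- ex[exon, ]
    list(start = e$contig_start - gene$intron5_length,
         end = e$contig_end + gene$intron3_length,
         seq = paste0(gene$flank5[exon], gene$exon_seq[exon], gene$flank3[exon]))
  }

  rows <- list()
  for (g in c("g1", "g2")) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      p <- pam[[paste0(v$exon, "_", g)]]
      e <- ex[v$exon, ]
      win <- window_of(v$exon)
      seq <- win$seq
      ## apply PAM synonymous edit
      pam_cds <- (p$codon_index - 1) * 3 + p$edit$within
      pam_contig <- e$contig_start + (pam_cds - e$cds_start)
      pam_off <- pam_contig - win$start + 1
      substring(seq, pam_off, pam_off) <- p$edit$alt
      ## does this variant touch the PAM codon?
      pam_start_contig <- e$contig_start + ((p$codon_index - 1) * 3 + 1 - e$cds_start)
      pam_end_contig <- pam_start_contig + 2
      v_end <- v$pos + nchar(v$ref) - 1
      flag <- v$pos <= pam_end_contig && v_end >= pam_start_contig
      ## apply the variant
      off <- v$pos - win$start + 1
      seq <- paste0(substring(seq, 1, off - 1), v$alt,
                    substring(seq, off + nchar(v$ref), nchar(seq)))
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v$variant_id, guide = g, exon = v$exon,
        pam_codon_flag = flag, pam_codon_index = p$codon_index,
        designed_sequence = seq
      )
    }
  }
  lib <- do.call(rbind, rows)
  rownames(lib) <- NULL
  ## a PAM edit can make two designs sequence-identical (e.g. deleting
  ## either of two codons that the edit rendered identical); PAM-flagged
  ## designs are excluded from analysis, so drop them from collisions
  key <- paste(lib$guide, lib$designed_sequence)
  in_collision <- key %in% key[duplicated(key)]
  lib <- lib[!(in_collision & lib$pam_codon_flag), ]
  key <- paste(lib$guide, lib$designed_sequence)
  if (anyDuplicated(key))
    stop("designed sequences are not unique within a guide library (",
         sum(duplicated(key)), " collisions)")
  rownames(lib) <- NULL
  lib
}
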