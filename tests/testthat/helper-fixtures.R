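# Shared fixtures, built in code at test time.

tiny_gene <- function(seed = 3) make_gene(2, c(12, 9), seed = seed)

small_screen <- function(seed = 11, mean_count = 300, ...) {
  gene <- make_gene(2, c(30, 24), seed = seed)
  variants <- enumerate_variants(gene)
  library <- variant_library(gene, variants)
  assignment <- assign_true_classes(variants, seed = seed + 1)
  scenario <- sge_scenario(seed = seed + 2, mean_count = mean_count, ...)
  counts <- simulate_counts(library, assignment, scenario)
  list(gene = gene, variants = variants, library = library,
       assignment = assignment, scenario = scenario, counts = counts)
}

# brute-force step-up BH, independent of the implementation under test
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0)))
    adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# hand 2x2 chi-squared without continuity correction
chisq_hand <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# a minimal but well-formed PDB: one ALA (3 side-chain-less backbone + CB),
# one GLY (backbone only), fixed-width ATOM records
write_tiny_pdb <- function(path, coords) {
  fmt <- "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s"
  lines <- character(0)
  i <- 0
  for (r in seq_along(coords)) {
    res <- coords[[r]]
    for (a in seq_len(nrow(res$atoms))) {
      i <- i + 1
      at <- res$atoms[a, ]
      lines <- c(lines, sprintf(fmt, i, paste0(" ", at$name), res$resid, r,
                                at$x, at$y, at$z,
                                substr(trimws(at$name), 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
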