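#' Trinucleotide context of each SNV on the toy contig
#'
#' @param variants variant table (SNVs only are annotated; others get NA).
#' @param gene an `sge_gene`.
#' @return the variant table with `context` (trinucleotide centred on the
#'   reference base) and `boundary_distance` (bp to the nearest exon-intron
#'   boundary, 0 on the boundary base) columns.
#' @export
annotate_contexts <- function(variants, gene) {
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  ctx <- rep(NA_character_, nrow(variants))
  pos <- variants$pos
  ok <- is_snv & pos > 1 & pos < nchar(gene$contig)
  ctx[ok] <- substring(gene$contig, pos[ok] - 1, pos[ok] + 1)
  ex <- gene$exons
  bd <- vapply(seq_len(nrow(variants)), function(i) {
    e <- ex[variants$exon[i], ]
    min(abs(pos[i] - (e$contig_start - 1)), abs(pos[i] - e$contig_start),
        abs(pos[i] - e$contig_end), abs(pos[i] - (e$contig_end + 1)))
  }, 0)
  variants$context <- ctx
  variants$boundary_distance <- bd
  variants
}

#' Synthetic trinucleotide mutation-rate table
#'
#' A pluggable stand-in for a published germline triplet mutational model:
#' per-generation probabilities for every (trinucleotide context, alt)
#' combination, log-normally spread around a realistic scale and
#' strand-complement symmetric after folding. Synthetic - for tests and
#' simulations only.
#'
#' @param seed integer seed.
#' @param mean_rate geometric-mean per-generation rate.
#' @return data.frame `context`, `alt`, `rate`.
#' @export
synthetic_rate_table <- function(seed = 1L, mean_rate = 1e-8) {
  set.seed(seed)
  ctx <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  grid <- expand.grid(context = ctx, alt = BASES, stringsAsFactors = FALSE)
  grid <- grid[substring(grid$context, 2, 2) != grid$alt, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  key <- paste(grid$context, grid$alt)
  fold <- vapply(seq_len(nrow(grid)), function(i)
    paste(revcomp(grid$context[i]), comp[[grid$alt[i]]]), "")
  canon <- pmin(key, fold)
  ucanon <- unique(canon)
  rate_c <- setNames(rlnorm(length(ucanon), log(mean_rate), 1), ucanon)
  grid$rate <- as.numeric(rate_c[canon])
  rownames(grid) <- NULL
  grid
}

#' Summed mutational probability per SGE functional class
#'
#' Restricts to SNVs within `boundary_window` bp of an exon-intron
#' boundary (for exome-coverage comparability), sums the per-generation
#' mutation rate of each variant's (context, alt) within each functional
#' class, and normalises across classes.
#'
#' @param variants context-annotated variant table (needs `context`,
#'   `boundary_distance`, `ref`, `alt`, `variant_id`).
#' @param calls functional calls (`variant_id`, `sge_class`).
#' @param rates rate table (`context`, `alt`, `rate`).
#' @param boundary_window eligibility window in bp.
#' @return named numeric vector of class probabilities summing to 1.
#' @export
class_probabilities <- function(variants, calls, rates, boundary_window = 10) {
  v <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
                  variants$boundary_distance <= boundary_window, ]
  v$sge_class <- calls$sge_class[match(v$variant_id, calls$variant_id)]
  v <- v[!is.na(v$sge_class), ]
  miss <- is.na(v$context)
  if (any(miss))
    stop("missing trinucleotide context for: ",
         paste(head(v$variant_id[miss], 5), collapse = ", "))
  r <- rates$rate[match(paste(v$context, v$alt), paste(rates$context, rates$alt))]
  if (anyNA(r))
    stop("rate table lacks entries for: ",
         paste(head(unique(paste(v$context, v$alt)[is.na(r)]), 5),
               collapse = ", "))
  s <- tapply(r, v$sge_class, sum)
  p <- s / sum(s)
  p[order(names(p))]
}

#' Observed vs expected counts per functional class
#'
#' Expected counts allocate the total number of population observations
#' according to the neutral mutational probability of each class; the
#' observed/expected ratio carries an exact Poisson 95 percent CI on the
#' observed count.
#'
#' @param probabilities class probabilities from [class_probabilities()].
#' @param observed named observed counts (same classes).
#' @param total total observations (defaults to `sum(observed)`); a
#'   variant seen in two databases counts twice, which callers honour via
#'   a multiplicity column upstream.
#' @return data.frame `sge_class`, `probability`, `observed`, `expected`,
#'   `oe_ratio`, `oe_lo`, `oe_hi`.
#' @export
observed_expected <- function(probabilities, observed, total = sum(observed)) {
  cls <- names(probabilities)
  obs <- observed[cls]
  if (anyNA(obs)) stop("observed counts missing for some classes")
  if (sum(obs) != total)
    warning("sum of observed counts (", sum(obs),
            ") differs from total observations (", total, ")")
  expected <- total * probabilities
  ci <- t(vapply(obs, function(o) poisson.test(o)$conf.int, c(0, 0)))
  data.frame(sge_class = cls, probability = as.numeric(probabilities),
             observed = as.numeric(obs), expected = as.numeric(expected),
             oe_ratio = as.numeric(obs / expected),
             oe_lo = ci[, 1] / as.numeric(expected),
             oe_hi = ci[, 2] / as.numeric(expected),
             row.names = NULL)
}

#' Fraction of missense variants pathogenic for the disease
#'
#' Compares the observed missense:nonsense ratio among de novo variants in
#' a large disease cohort with the ratio expected under the neutral
#' mutational model: `fraction = (obs_missense / obs_nonsense) /
#' expected_ratio`. The 95 percent CI is a seeded parametric bootstrap on
#' independent Poisson counts.
#'
#' @param obs_missense,obs_nonsense observed de novo counts.
#' @param expected_ratio expected missense:nonsense ratio under the
#'   neutral model.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `fraction`, `ci` (length 2), `n_boot`.
#' @export
missense_pathogenic_fraction <- function(obs_missense, obs_nonsense,
                                         expected_ratio, n_boot = 1e5,
                                         seed = 1L, conf = 0.95) {
  if (obs_nonsense <= 0) stop("obs_nonsense must be positive")
  if (obs_missense <= 0) stop("obs_missense must be positive")
  frac <- (obs_missense / obs_nonsense) / expected_ratio
  set.seed(seed)
  bm <- rpois(n_boot, obs_missense)
  bn <- rpois(n_boot, obs_nonsense)
  ok <- bn > 0
  bf <- (bm[ok] / bn[ok]) / expected_ratio
  a <- (1 - conf) / 2
  list(fraction = frac,
       ci = as.numeric(quantile(bf, c(a, 1 - a))),
       n_boot = sum(ok))
}

#' Functional-class proportions stratified by cancer driver status
#'
#' Joins cancer variants to their SGE functional class, computes class
#' proportions within driver and non-driver strata, the driver:non-driver
#' proportion ratio per class, a per-class 2x2 chi-squared test (1 df,
#' no continuity correction) and the overall stratum-by-class test.
#'
#' @param cancer cancer variant table (`variant_id`, `driver_flag`, and
#'   optionally `sample`, `cancer_type`).
#' @param calls functional calls (`variant_id`, `sge_class`).
#' @return list: `proportions` (per stratum x class), `ratios` (per class:
#'   ratio, chisq, df, p), `overall` (chisq, df, p), `unjoined` variant
#'   ids.
#' @export
driver_class_proportions <- function(cancer, calls) {
  cls <- calls$sge_class[match(cancer$variant_id, calls$variant_id)]
  unjoined <- unique(cancer$variant_id[is.na(cls)])
  ok <- !is.na(cls)
  cc <- data.frame(driver = cancer$driver_flag[ok], sge_class = cls[ok])
  tab <- table(cc$driver, cc$sge_class)
  props <- prop.table(tab, margin = 1)
  ratios <- lapply(colnames(tab), function(k) {
    in_k <- tab[, k]
    out_k <- rowSums(tab) - in_k
    m <- rbind(in_k, out_k)
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    p_driver <- props[rownames(props) == "TRUE", k]
    p_non <- props[rownames(props) == "FALSE", k]
    data.frame(sge_class = k, prop_driver = as.numeric(p_driver),
               prop_nondriver = as.numeric(p_non),
               ratio = as.numeric(p_driver / p_non),
               chisq = unname(ct$statistic), df = unname(ct$parameter),
               p = unname(ct$p.value))
  })
  overall <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(proportions = props, ratios = do.call(rbind, ratios),
       overall = data.frame(chisq = unname(overall$statistic),
                            df = unname(overall$parameter),
                            p = unname(overall$p.value)),
       unjoined = unjoined)
}

#' Correlation of depleted proportion with driver fraction across cancers
#'
#' Pearson correlation of the per-cancer-type proportion of variants that
#' are SGE-depleted against the externally estimated driver fraction, with
#' a seeded bootstrap CI over cancer types.
#'
#' @param per_type data.frame `cancer_type`, `driver_fraction`,
#'   `depleted_proportion`.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `r`, `ci`, `n_types`.
#' @export
depleted_vs_driver_fraction <- function(per_type, n_boot = 2000, seed = 1L,
                                        conf = 0.95) {
  check_columns(per_type, c("cancer_type", "driver_fraction",
                            "depleted_proportion"), "per-type table")
  n <- nrow(per_type)
  if (n < 3) stop("need at least 3 cancer types, got ", n)
  r <- cor(per_type$depleted_proportion, per_type$driver_fraction)
  set.seed(seed)
  br <- replicate(n_boot, {
    idx <- sample(n, replace = TRUE)
    suppressWarnings(cor(per_type$depleted_proportion[idx],
                         per_type$driver_fraction[idx]))
  })
  a <- (1 - conf) / 2
  list(r = r, ci = as.numeric(quantile(br, c(a, 1 - a), na.rm = TRUE)),
       n_types = n)
}
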