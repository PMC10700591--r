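SGE_CLASSES <- c("unchanged", "enriched", "fast_depleting", "slow_depleting")

#' Simulation scenario for a synthetic SGE screen
#'
#' Bundles the experimental design (replicates, guides, timepoints) and the
#' generative kinetic parameters of a synthetic screen. The default design
#' mirrors the assay layout this pipeline targets: two guide libraries per
#' exon, three replicates, sampling at days 4/7/11/15/21 with day 4 the
#' baseline. Per-class kinetic rates are synthetic repository defaults
#' chosen for class separability (log2 abundance change per day).
#'
#' @param n_replicates replicates per guide library.
#' @param guides_per_exon guide libraries per exon (1 or 2).
#' @param timepoint_days strictly increasing sampling days; the first is the
#'   baseline.
#' @param class_slopes named numeric, log2 change per day per SGE class.
#' @param slope_sd standard deviation of the per-variant kinetic deviation
#'   around the class slope (log2/day).
#' @param guide_effect_correlation fraction of the per-variant slope
#'   deviation variance shared between the two guides (the correlation of
#'   true per-guide slopes within a class).
#' @param nb_dispersion negative binomial dispersion alpha, variance
#'   mu + alpha * mu^2.
#' @param mean_count expected baseline count per variant.
#' @param initial_abundance_log_sd log-normal sd of per-variant baseline
#'   abundance (natural log scale).
#' @param depth_log_sd log-normal sd of per-sample sequencing depth factors.
#' @param seed integer seed driving all per-stage streams.
#' @return an object of class `sge_scenario`.
#' @export
sge_scenario <- function(n_replicates = 3, guides_per_exon = 2,
                         timepoint_days = c(4, 7, 11, 15, 21),
                         class_slopes = c(unchanged = 0, enriched = 0.15,
                                          slow_depleting = -0.15,
                                          fast_depleting = -0.45),
                         slope_sd = 0.04,
                         guide_effect_correlation = 0.9,
                         nb_dispersion = 0.05,
                         mean_count = 500,
                         initial_abundance_log_sd = 0.5,
                         depth_log_sd = 0.1,
                         seed = 1L) {
  stopifnot(all(diff(timepoint_days) > 0), nb_dispersion > 0,
            all(is.finite(class_slopes)),
            guide_effect_correlation >= 0, guide_effect_correlation <= 1,
            all(SGE_CLASSES %in% names(class_slopes)))
  structure(list(
    n_replicates = n_replicates, guides_per_exon = guides_per_exon,
    timepoint_days = timepoint_days, class_slopes = class_slopes,
    slope_sd = slope_sd, guide_effect_correlation = guide_effect_correlation,
    nb_dispersion = nb_dispersion, mean_count = mean_count,
    initial_abundance_log_sd = initial_abundance_log_sd,
    depth_log_sd = depth_log_sd, seed = as.integer(seed)
  ), class = "sge_scenario")
}

#' Default class distributions per consequence
#'
#' Class-conditional probabilities used to draw each variant's true
#' functional class from its consequence. Defaults mirror the class
#' proportions reported for a genome-edited essential-gene screen (e.g.
#' ~95% of nonsense variants depleted, ~98% of synonymous variants
#' unchanged).
#'
#' @return a named list: consequence -> named probability vector over the
#'   four SGE classes, each summing to 1.
#' @export
default_class_probabilities <- function() {
  list(
    synonymous    = c(unchanged = 0.980, enriched = 0.010, fast_depleting = 0.005, slow_depleting = 0.005),
    intronic      = c(unchanged = 0.890, enriched = 0.055, fast_depleting = 0.020, slow_depleting = 0.035),
    splice_acceptor_donor = c(unchanged = 0.225, enriched = 0.035, fast_depleting = 0.580, slow_depleting = 0.160),
    missense      = c(unchanged = 0.725, enriched = 0.115, fast_depleting = 0.088, slow_depleting = 0.072),
    nonsense      = c(unchanged = 0.050, enriched = 0.000, fast_depleting = 0.900, slow_depleting = 0.050),
    codon_deletion = c(unchanged = 0.430, enriched = 0.080, fast_depleting = 0.372, slow_depleting = 0.118),
    other         = c(unchanged = 1, enriched = 0, fast_depleting = 0, slow_depleting = 0)
  )
}

#' Assign true functional classes to variants
#'
#' Draws each variant's generative SGE class from the class distribution of
#' its consequence.
#'
#' @param variants variant table from [enumerate_variants()].
#' @param class_probabilities consequence -> class probability map; each
#'   distribution must sum to 1.
#' @param seed integer seed.
#' @return data.frame `variant_id`, `consequence`, `true_class`.
#' @export
assign_true_classes <- function(variants,
                                class_probabilities = default_class_probabilities(),
                                seed = 1L) {
  probs <- class_probabilities
  bad <- vapply(probs, function(p) abs(sum(p) - 1) > 1e-8, TRUE)
  if (any(bad))
    stop("class probabilities must sum to 1 for: ",
         paste(names(probs)[bad], collapse = ", "))
  set.seed(seed)
  cls <- vapply(variants$consequence, function(csq) {
    p <- probs[[csq]]
    if (is.null(p)) p <- probs[["other"]]
    sample(names(p), 1, prob = p)
  }, "", USE.NAMES = FALSE)
  data.frame(variant_id = variants$variant_id,
             consequence = variants$consequence,
             true_class = cls)
}

#' Simulate the count tensor of a synthetic SGE screen
#'
#' Counts are negative binomial around an expected abundance
#' `N0 * 2^(slope * (day - baseline)) * depth`, with a log-normal
#' per-variant baseline `N0`, a per-sample depth factor, and per-guide
#' slopes sharing a configurable fraction of their variance
#' (`guide_effect_correlation`). PAM-codon-flagged (variant, guide)
#' entries are not emitted: on that guide's background the designed variant
#' is a multi-nucleotide change excluded from analysis, and the other
#' guide's library carries the measurement.
#'
#' @param library two-guide library from [variant_library()].
#' @param assignment truth from [assign_true_classes()].
#' @param scenario an [sge_scenario()].
#' @return long data.frame `variant_id`, `guide`, `replicate`, `day`,
#'   `count`, with attributes `true_slopes` (per variant x guide) and
#'   `depth_factors`.
#' @export
simulate_counts <- function(library, assignment, scenario = sge_scenario()) {
  stopifnot(inherits(scenario, "sge_scenario"))
  if (!all(library$variant_id %in% assignment$variant_id))
    stop("every variant in the library needs a true class")
  set.seed(scenario$seed + 1L)

  guides <- c("g1", "g2")[seq_len(scenario$guides_per_exon)]
  lib <- library[library$guide %in% guides & !library$pam_codon_flag, ]
  cls <- assignment$true_class[match(lib$variant_id, assignment$variant_id)]
  base_slope <- scenario$class_slopes[cls]

  ## per-variant shared deviation and per-(variant,guide) noise
  rho <- scenario$guide_effect_correlation
  sd_shared <- scenario$slope_sd * sqrt(rho)
  sd_guide <- scenario$slope_sd * sqrt(1 - rho)
  uvar <- unique(lib$variant_id)
  shared <- setNames(rnorm(length(uvar), 0, sd_shared), uvar)
  ## kinetic deviation models variant- and guide-level variability of the
  ## fitness effect; functionally neutral (slope-0) variants have none
  functional <- as.numeric(base_slope) != 0
  slope <- as.numeric(base_slope) +
    functional * (shared[lib$variant_id] + rnorm(nrow(lib), 0, sd_guide))

  n0 <- rlnorm(nrow(lib), log(scenario$mean_count),
               scenario$initial_abundance_log_sd)

  days <- scenario$timepoint_days
  reps <- seq_len(scenario$n_replicates)
  depth <- expand.grid(guide = guides, replicate = reps, day = days,
                       stringsAsFactors = FALSE)
  depth$factor <- rlnorm(nrow(depth), 0, scenario$depth_log_sd)

  grid <- expand.grid(row = seq_len(nrow(lib)), replicate = reps, day = days)
  mu <- n0[grid$row] * 2^(slope[grid$row] * (grid$day - days[1]))
  dkey <- paste(lib$guide[grid$row], grid$replicate, grid$day)
  mu <- mu * depth$factor[match(dkey, paste(depth$guide, depth$replicate, depth$day))]
  counts <- rnbinom(length(mu), mu = mu, size = 1 / scenario$nb_dispersion)

  out <- data.frame(
    variant_id = lib$variant_id[grid$row],
    guide = lib$guide[grid$row],
    replicate = grid$replicate,
    day = grid$day,
    count = counts
  )
  out <- out[order(out$guide, out$variant_id, out$replicate, out$day), ]
  rownames(out) <- NULL
  attr(out, "true_slopes") <- data.frame(
    variant_id = lib$variant_id, guide = lib$guide, slope = slope)
  attr(out, "depth_factors") <- depth
  attr(out, "days") <- days
  out
}

#' Simulate matched truth-set, allele-frequency and in-silico score tables
#'
#' Positive (disease) truth labels are drawn mostly from depleted variants,
#' negative labels from unchanged variants observed in a simulated
#' population; in-silico score columns are drawn from class-conditional
#' distributions so that fixed-threshold classifiers have intermediate
#' accuracy. Allele frequencies are zero for positives.
#'
#' @param variants variant table (needs `variant_id`, `consequence`).
#' @param assignment truth classes from [assign_true_classes()].
#' @param seed integer seed.
#' @param n_positive,n_negative target truth-set sizes (positives are capped
#'   by the number of depleted variants available, negatives by unchanged).
#' @return list with `labels` (variant_id, label), `frequencies`
#'   (variant_id, af), `scores` (variant_id + sift, polyphen2, revel, cadd,
#'   spliceai columns for every variant).
#' @export
simulate_truth_tables <- function(variants, assignment, seed = 1L,
                                  n_positive = 168, n_negative = 540) {
  set.seed(seed)
  cls <- assignment$true_class[match(variants$variant_id, assignment$variant_id)]
  depleted <- variants$variant_id[cls %in% c("fast_depleting", "slow_depleting")]
  unchanged <- variants$variant_id[cls == "unchanged"]
  if (length(depleted) == 0) {
    pos <- character(0)
  } else {
    pos <- sample(depleted, min(n_positive, length(depleted)))
  }
  neg <- sample(unchanged, min(n_negative, length(unchanged)))
  labels <- rbind(
    data.frame(variant_id = pos,
               label = rep("positive", length(pos))),
    data.frame(variant_id = neg,
               label = rep("negative", length(neg)))
  )

  af <- data.frame(variant_id = c(pos, neg),
                   af = c(rep(0, length(pos)),
                          10^runif(length(neg), -6, -3)))

  damaging <- variants$variant_id %in% depleted
  n <- nrow(variants)
  scores <- data.frame(
    variant_id = variants$variant_id,
    sift = ifelse(damaging, rbeta(n, 0.3, 8), rbeta(n, 3, 2)),
    polyphen2 = ifelse(damaging, rbeta(n, 6, 1.2), rbeta(n, 1.2, 5)),
    revel = ifelse(damaging, rbeta(n, 6, 2), rbeta(n, 2, 6)),
    cadd = ifelse(damaging, rnorm(n, 27, 3.5), rnorm(n, 16, 5)),
    spliceai = ifelse(variants$consequence %in% c("splice_acceptor_donor") & damaging,
                      rbeta(n, 8, 1.5), rbeta(n, 0.4, 12))
  )
  list(labels = labels, frequencies = af, scores = scores)
}

#' Emit FASTQ reads for one (guide, replicate, day) count slice
#'
#' Writes one read per count unit; the read is the designed exon-window
#' sequence of the variant flanked by the sequencing primers, so that
#' [count_reads()] recovers the count table exactly.
#'
#' @param counts long count table (will be subset to one slice).
#' @param library library with designed sequences.
#' @param guide,replicate,day slice selectors.
#' @param primer5,primer3 primer sequences flanking the window.
#' @return character vector of FASTQ lines (4 per read).
#' @export
emit_reads <- function(counts, library, guide, replicate, day,
                       primer5 = "ACGTACGTAC", primer3 = "GTCAGTCAGT") {
  sl <- counts[counts$guide == guide & counts$replicate == replicate &
                 counts$day == day & counts$count > 0, ]
  if (nrow(sl) == 0) return(character(0))
  lib <- library[library$guide == guide, ]
  seqs <- lib$designed_sequence[match(sl$variant_id, lib$variant_id)]
  if (anyNA(seqs))
    stop("counts refer to variants absent from the guide library")
  reads <- rep(paste0(primer5, seqs, primer3), sl$count)
  ids <- sprintf("@read_%06d %s_%s_r%d_d%d", seq_along(reads),
                 rep(sl$variant_id, sl$count), guide, replicate, day)
  as.vector(rbind(ids, reads, "+", strrep("I", nchar(reads))))
}
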