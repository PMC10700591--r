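#' Total-count size factors
#'
#' Each sample (guide, replicate, day) is scaled by its total read count
#' divided by the geometric mean of totals within the same guide library,
#' so factors have geometric mean 1 per guide. This replaces median-ratio
#' scaling deliberately: an SGE screen violates the assumption that most
#' variants are unchanged.
#'
#' @param counts long count table.
#' @return data.frame `guide`, `replicate`, `day`, `total`, `size_factor`.
#' @export
size_factors <- function(counts) {
  check_columns(counts, c("variant_id", "guide", "replicate", "day", "count"),
                "count table")
  ag <- aggregate(count ~ guide + replicate + day, counts, sum)
  names(ag)[names(ag) == "count"] <- "total"
  zero <- ag$total == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(sprintf("%s/rep%d/day%d", ag$guide[zero], ag$replicate[zero],
                       ag$day[zero]), collapse = ", "))
  gm <- tapply(ag$total, ag$guide, function(t) exp(mean(log(t))))
  ag$size_factor <- ag$total / as.numeric(gm[ag$guide])
  ag[order(ag$guide, ag$replicate, ag$day), ]
}

## internal: reshape a long count table into a list of per-(variant,guide)
## matrices [replicate x day] plus aligned size factors
count_matrices <- function(counts, factors) {
  days <- sort(unique(counts$day))
  reps <- sort(unique(counts$replicate))
  skey <- paste(factors$guide, factors$replicate, factors$day)
  sf <- setNames(factors$size_factor, skey)
  ckey <- paste(counts$guide, counts$replicate, counts$day)
  if (anyNA(sf[ckey])) stop("size factors missing for some samples")
  units <- unique(counts[, c("variant_id", "guide")])
  uidx <- match(paste(counts$variant_id, counts$guide),
                paste(units$variant_id, units$guide))
  ridx <- match(counts$replicate, reps)
  didx <- match(counts$day, days)
  cnt <- array(NA_real_, c(nrow(units), length(reps), length(days)))
  cnt[cbind(uidx, ridx, didx)] <- counts$count
  sfm <- matrix(NA_real_, length(reps), length(days))
  list(units = units, days = days, reps = reps, cnt = cnt,
       sf = function(guide) {
         m <- sfm
         m[cbind(rep(seq_along(reps), length(days)),
                 rep(seq_along(days), each = length(reps)))] <-
           sf[paste(guide, rep(reps, length(days)),
                    rep(days, each = length(reps)))]
         m
       })
}

## method-of-moments NB dispersion pooled over timepoints, on normalised
## counts: alpha = sum_d (s2_d - m_d) / sum_d m_d^2, floored
mom_dispersion <- function(norm, floor = 1e-8) {
  m <- colMeans(norm, na.rm = TRUE)
  s2 <- apply(norm, 2, var)
  ok <- !is.na(s2) & m > 0
  if (!any(ok)) return(floor)
  max(sum(s2[ok] - m[ok]) / sum(m[ok]^2), floor)
}

## Wald fit of a NB log-link model with fixed dispersion; returns
## estimate (log2 per unit of x2), se, z, p referenced to t(df)
nb_wald <- function(y, x2, off, alpha, df) {
  x <- cbind(1, x2)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = MASS::negative.binomial(theta = 1 / alpha),
                   offset = off))
  w <- fit$weights
  xtwx <- crossprod(x, w * x)
  cv <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(cv) || !fit$converged) return(NULL)
  est <- coef(fit)[2] / log(2)
  se <- sqrt(cv[2, 2]) / log(2)
  z <- est / se
  c(estimate = unname(est), se = unname(se), z = unname(z),
    p = unname(2 * pt(-abs(z), df)))
}

fit_effects <- function(counts, factors, x_of_day, kind) {
  cm <- count_matrices(counts, factors)
  xs <- x_of_day(cm$days)
  use <- !is.na(xs)
  res <- vector("list", nrow(cm$units))
  excluded <- logical(nrow(cm$units))
  pseudo <- logical(nrow(cm$units))
  for (i in seq_len(nrow(cm$units))) {
    cntm <- cm$cnt[i, , , drop = TRUE]
    sfm <- cm$sf(cm$units$guide[i])
    ## dispersion pooled over all observed timepoints
    norm <- cntm / sfm
    alpha <- mom_dispersion(norm)
    obs <- which(use & colSums(!is.na(cntm)) > 0)
    y <- as.vector(cntm[, obs])
    x2 <- rep(xs[obs], each = length(cm$reps))
    sf <- as.vector(sfm[, obs])
    ok <- !is.na(y)
    y <- y[ok]; x2 <- x2[ok]; sf <- sf[ok]
    if (length(unique(x2)) < 2) { excluded[i] <- TRUE; next }
    ## all-zero in both groups: nothing to estimate
    if (all(y == 0)) { excluded[i] <- TRUE; next }
    ## a group that is all zero keeps the MLE finite via a half pseudocount
    for (lev in unique(x2)) {
      if (all(y[x2 == lev] == 0)) { y[x2 == lev] <- 0.5; pseudo[i] <- TRUE }
    }
    ndays <- sum(colSums(!is.na(cntm)) > 0)
    dfree <- max(sum(!is.na(cntm)) - ndays, 1)
    f <- nb_wald(y, x2, log(sf), alpha, dfree)
    if (is.null(f)) { excluded[i] <- TRUE; next }
    res[[i]] <- f
  }
  keep <- !excluded
  out <- data.frame(
    variant_id = cm$units$variant_id[keep],
    guide = cm$units$guide[keep],
    kind = kind,
    do.call(rbind, res[keep]),
    pseudocount = pseudo[keep]
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- cm$units[excluded, ]
  out
}

#' Per-variant log2 fold-change at one timepoint
#'
#' Fits, per (variant, guide), a negative binomial log-link model with the
#' timepoint as a two-level factor (baseline day vs `day`) and the log size
#' factor as offset. Dispersion is estimated per variant by the method of
#' moments on normalised counts, pooled across all observed timepoints and
#' floored at 1e-8. Estimates are reported in log2 units; the Wald
#' statistic is referenced to a t distribution with the dispersion residual
#' degrees of freedom. Variants with all-zero counts in both groups are
#' excluded and reported in the `excluded` attribute; an all-zero group
#' gets a half-count pseudocount (flagged in the `pseudocount` column).
#'
#' @param counts long count table.
#' @param factors size factors from [size_factors()].
#' @param day target day; the baseline is the earliest day in the table.
#' @param baseline_day baseline day (default: earliest day present).
#' @return data.frame `variant_id`, `guide`, `kind`, `estimate`, `se`,
#'   `z`, `p`, `pseudocount`.
#' @export
fit_lfc <- function(counts, factors, day, baseline_day = NULL) {
  days_all <- sort(unique(counts$day))
  if (is.null(baseline_day)) baseline_day <- days_all[1]
  if (!day %in% days_all) stop("day ", day, " not present in count table")
  if (!baseline_day %in% days_all) stop("baseline day missing from count table")
  if (day == baseline_day) stop("target day equals the baseline day")
  fit_effects(counts, factors,
              function(days) ifelse(days == baseline_day, 0,
                                    ifelse(days == day, 1, NA_real_)),
              kind = paste0("lfc_day", day))
}

#' Per-variant log2 fold-change trend (depletion rate)
#'
#' Same per-variant negative binomial model as [fit_lfc()] but with a
#' single numeric covariate: days are coded as elapsed days since the
#' baseline (4/7/11/15/21 -> 0/3/7/11/17), so the slope is the log2
#' abundance change per day.
#'
#' @inheritParams fit_lfc
#' @return data.frame as [fit_lfc()] with `kind = "lfc_trend"` and the
#'   estimate in log2 units per day.
#' @export
fit_lfc_trend <- function(counts, factors, baseline_day = NULL) {
  days_all <- sort(unique(counts$day))
  if (length(days_all) < 3)
    stop("LFC-trend needs at least 3 timepoints, got ", length(days_all))
  if (is.null(baseline_day)) baseline_day <- days_all[1]
  fit_effects(counts, factors, function(days) days - baseline_day,
              kind = "lfc_trend")
}
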