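#' Map length in centimorgans
#'
#' One centimorgan corresponds to one recombinant gamete per hundred
#' meioses, so the map length implied by a crossover count is
#' `100 * n_cos / n_meioses`.
#'
#' @param n_cos number of crossovers observed.
#' @param n_meioses number of meioses (gametes) screened.
#' @return Map length in cM.
#' @examples
#' map_length_cM(302, 30)  # 1006.7
#' map_length_cM(396, 24)  # 1650
#' @export
map_length_cM <- function(n_cos, n_meioses) {
  if (any(n_meioses <= 0)) stop("n_meioses must be positive")
  100 * n_cos / n_meioses
}

#' Per-chromosome sex-specific map table
#'
#' Builds the full map table from a crossover table: per chromosome and
#' sex, the retained crossover count and map length in cM; the
#' female-to-male ratio computed from unrounded lengths; a totals row; and
#' as attributes the mean crossovers per chromosome per meiosis per sex
#' and the Pearson correlation between the two sexes' per-chromosome map
#' lengths.
#'
#' @param co_table crossover table (only `status == "validated"` rows are
#'   counted) or a data.frame of precomputed counts with columns `chrom`,
#'   `count_female`, `count_male`.
#' @param meioses_by_sex named numeric, e.g. `c(male = 30, female = 24)`.
#' @param chromosomes character vector fixing chromosome order (and
#'   including chromosomes with zero crossovers).
#' @return data.frame with `chrom`, `count_female`, `count_male`,
#'   `length_female`, `length_male`, `ratio_fm`, plus a `"Total"` row;
#'   attributes `cos_per_chrom` and `pearson_r`.
#' @export
per_chromosome_table <- function(co_table, meioses_by_sex, chromosomes) {
  stopifnot(all(c("male", "female") %in% names(meioses_by_sex)))
  if (all(c("count_female", "count_male") %in% names(co_table))) {
    counts <- co_table[match(chromosomes, co_table$chrom), ]
    cf <- counts$count_female; cm <- counts$count_male
  } else {
    kept <- retained_crossovers(co_table)
    cf <- vapply(chromosomes, function(ch)
      sum(kept$chrom == ch & kept$parent_sex == "female"), numeric(1))
    cm <- vapply(chromosomes, function(ch)
      sum(kept$chrom == ch & kept$parent_sex == "male"), numeric(1))
  }
  lf <- map_length_cM(cf, meioses_by_sex[["female"]])
  lm <- map_length_cM(cm, meioses_by_sex[["male"]])
  ratio <- ifelse(cm > 0, lf / lm, NA_real_)
  tab <- data.frame(chrom = chromosomes,
                    count_female = cf, count_male = cm,
                    length_female = lf, length_male = lm,
                    ratio_fm = ratio, stringsAsFactors = FALSE)
  total <- data.frame(chrom = "Total",
                      count_female = sum(cf), count_male = sum(cm),
                      length_female = sum(lf), length_male = sum(lm),
                      ratio_fm = sum(lf) / sum(lm))
  out <- rbind(tab, total)
  n_chr <- length(chromosomes)
  attr(out, "cos_per_chrom") <- c(
    male = sum(cm) / (meioses_by_sex[["male"]] * n_chr),
    female = sum(cf) / (meioses_by_sex[["female"]] * n_chr))
  # correlation between the sexes' map-length columns; r = 1 by convention
  # when both columns are constant and equal (zero variance)
  attr(out, "pearson_r") <- if (sd(lf) == 0 || sd(lm) == 0) {
    if (identical(lf, lm)) 1 else NA_real_
  } else cor(lf, lm)
  out
}

#' Tail probability under the obligate-crossover model
#'
#' Under one obligate chiasma per chromosome per meiosis, a sampled gamete
#' carries the crossover with probability 1/2 (two of four chromatids are
#' involved), so the observed count over `n_meioses` meioses is
#' Binomial(n, 1/2). Returns `P[X <= observed]`, the probability of seeing
#' this few crossovers or fewer.
#'
#' @param observed_cos observed crossover count for the chromosome.
#' @param n_meioses number of meioses screened.
#' @return Lower-tail binomial probability.
#' @examples
#' obligate_co_probability(4, 30)  # 2.97e-05
#' @export
obligate_co_probability <- function(observed_cos, n_meioses) {
  stopifnot(observed_cos >= 0, observed_cos <= n_meioses)
  pbinom(observed_cos, n_meioses, 0.5)
}

#' Test equality of coefficients of variation between sexes
#'
#' Computes the per-sex coefficient of variation (sample SD / mean) of
#' per-individual crossover totals and the Feltz-Miller asymptotic
#' chi-square test for equality of CVs between the two groups.
#'
#' @param counts_female,counts_male per-individual crossover totals.
#' @return List with `cv_female`, `cv_male`, `statistic`, `p_value`.
#' @export
cv_equality_test <- function(counts_female, counts_male) {
  stopifnot(length(counts_female) >= 2, length(counts_male) >= 2)
  if (mean(counts_female) == 0 || mean(counts_male) == 0)
    stop("zero mean crossover count")
  cvs <- c(sd(counts_female) / mean(counts_female),
           sd(counts_male) / mean(counts_male))
  m <- c(length(counts_female) - 1, length(counts_male) - 1)
  cbar <- sum(m * cvs) / sum(m)
  stat <- sum(m * (cvs - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  list(cv_female = cvs[1], cv_male = cvs[2], statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fold crossover positions and bin into equal segments
#'
#' Each crossover midpoint is mapped to its relative distance from the
#' nearest chromosome end, scaled by half the chromosome length (folded
#' coordinate in `[0, 1]`), and binned into `n_segments` equal segments.
#' The relative map length of a segment is its share of the chromosome's
#' crossovers. A folded coordinate of exactly 1 (the chromosome centre)
#' falls in the last segment.
#'
#' @param co_table crossover table (validated rows used).
#' @param meta a [chrom_meta()] table.
#' @param n_segments number of segments, 2-20.
#' @return data.frame: `sex`, `chrom`, `segment`, `count`,
#'   `relative_length` (share of the chromosome's crossovers in the
#'   segment; rows present for every chromosome with at least one
#'   crossover of that sex).
#' @export
fold_and_bin <- function(co_table, meta, n_segments) {
  stopifnot(n_segments >= 2, n_segments <= 20)
  kept <- retained_crossovers(co_table)
  len <- setNames(meta$length_bp, meta$name)
  coord <- folded_coordinate(kept$midpoint, len[kept$chrom])
  seg <- pmin(floor(coord * n_segments) + 1L, n_segments)
  out <- list()
  for (sex in unique(kept$parent_sex)) {
    for (ch in unique(kept$chrom[kept$parent_sex == sex])) {
      sel <- kept$parent_sex == sex & kept$chrom == ch
      counts <- tabulate(seg[sel], nbins = n_segments)
      out[[length(out) + 1]] <- data.frame(
        sex = sex, chrom = ch, segment = seq_len(n_segments),
        count = counts, relative_length = counts / sum(counts))
    }
  }
  do.call(rbind, out)
}

#' Folded chromosome coordinate
#'
#' @param midpoint position in bp.
#' @param length_bp chromosome length in bp.
#' @return `min(midpoint, L - midpoint) / (L / 2)` in `[0, 1]`.
#' @export
folded_coordinate <- function(midpoint, length_bp) {
  pmin(midpoint, length_bp - midpoint) / (length_bp / 2)
}

#' Correlation of relative map lengths between the sexes
#'
#' Pools the per-chromosome segment shares of the two sexes over matching
#' (chromosome, segment) cells and reports the Pearson correlation with
#' the least-squares regression p-value, for a given segmentation scale.
#'
#' @param seg_f,seg_m outputs of [fold_and_bin()] restricted to one sex
#'   each (or the same output; the `sex` column is honoured).
#' @return List with `r`, `p_value`, `n` (cells used); `r = NA` when a
#'   side has zero variance.
#' @export
sex_segment_correlation <- function(seg_f, seg_m) {
  f <- seg_f
  m <- seg_m
  key_f <- paste(f$chrom, f$segment)
  key_m <- paste(m$chrom, m$segment)
  common <- intersect(key_f, key_m)
  x <- f$relative_length[match(common, key_f)]
  y <- m$relative_length[match(common, key_m)]
  if (length(common) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(common)))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common))
}

#' Per-arm crossover rates and the short-arm deficit test
#'
#' Computes crossovers per Mb for each chromosome arm (by midpoint), and a
#' one-degree-of-freedom chi-square test for a deficit of crossovers on
#' short arms: observed short- versus long-arm counts pooled over
#' chromosomes whose short arm is less than `short_arm_max_frac` of the
#' chromosome, against expectations proportional to physical arm length.
#' Chromosomes without a located centromere are excluded.
#'
#' @param co_table crossover table (validated rows used).
#' @param meta a [chrom_meta()] table.
#' @param sex restrict to one parent sex (`NULL` = all).
#' @param short_arm_max_frac inclusion threshold for the pooled test,
#'   default 0.30.
#' @return List with `arms` (data.frame: chrom, arm, length_mb, n_cos,
#'   rate_per_mb) and `deficit_test` (list: observed short/long counts,
#'   expected, chisq, p_value) or `NULL` with a warning when no crossovers
#'   are available.
#' @export
arm_rates <- function(co_table, meta, sex = NULL,
                      short_arm_max_frac = 0.30) {
  kept <- retained_crossovers(co_table)
  if (!is.null(sex)) kept <- kept[kept$parent_sex == sex, , drop = FALSE]
  meta <- arm_lengths(meta[!is.na(meta$centromere_bp), , drop = FALSE])
  arms <- list()
  obs_short <- 0; obs_long <- 0; exp_short_frac_num <- 0; tot <- 0
  es <- 0; el <- 0
  for (i in seq_len(nrow(meta))) {
    ch <- meta$name[i]; cen <- meta$centromere_bp[i]
    L <- meta$length_bp[i]
    mids <- kept$midpoint[kept$chrom == ch]
    p_len <- cen; q_len <- L - cen
    n_p <- sum(mids < cen); n_q <- sum(mids >= cen)
    short_is_p <- p_len <= q_len
    arms[[length(arms) + 1]] <- data.frame(
      chrom = ch,
      arm = c(if (short_is_p) "short" else "long",
              if (short_is_p) "long" else "short"),
      length_mb = c(p_len, q_len) / 1e6,
      n_cos = c(n_p, n_q),
      rate_per_mb = c(n_p / (p_len / 1e6), n_q / (q_len / 1e6)))
    if (min(p_len, q_len) / L < short_arm_max_frac) {
      n_s <- if (short_is_p) n_p else n_q
      n_l <- if (short_is_p) n_q else n_p
      n_tot <- n_s + n_l
      obs_short <- obs_short + n_s
      obs_long <- obs_long + n_l
      es <- es + n_tot * min(p_len, q_len) / L
      el <- el + n_tot * max(p_len, q_len) / L
    }
  }
  arms <- do.call(rbind, arms)
  if (obs_short + obs_long == 0) {
    warning("no crossovers on included chromosomes; deficit test skipped")
    return(list(arms = arms, deficit_test = NULL))
  }
  chisq <- (obs_short - es)^2 / es + (obs_long - el)^2 / el
  list(arms = arms,
       deficit_test = list(observed_short = obs_short,
                           observed_long = obs_long,
                           expected_short = es, expected_long = el,
                           chisq = chisq,
                           p_value = pchisq(chisq, 1, lower.tail = FALSE)))
}
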