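#' Build per-segment telomere/centromere covariates
#'
#' Divides each included chromosome (or its long arm) into 10 equal
#' segments and attaches, per segment: the crossover count of the
#' requested sex (the response), `d_telo` = relative distance from the
#' segment centre to the nearest chromosome end scaled by half the
#' chromosome length, `d_centro` = distance from the segment centre to the
#' centromere in Mb divided by the maximum arm length (Mb) over included
#' chromosomes (suppression around centromeres acts on an absolute, not
#' relative, scale), `d_centro_rel` = the same distance scaled instead by
#' the chromosome's own length (for model comparison), and `d_center` =
#' distance to the chromosome centre scaled by chromosome length.
#'
#' Sex chromosomes and chromosomes without a located centromere are
#' excluded.
#'
#' @param co_table crossover table (validated rows of the chosen sex are
#'   counted); may be `NULL` when only covariates are needed.
#' @param meta a [chrom_meta()] table.
#' @param sex `"male"` or `"female"`.
#' @param scope `"whole"` (segments span the chromosome) or `"long_arm"`
#'   (segments span centromere to the far telomere of the long arm).
#' @param n_segments segments per chromosome, default 10.
#' @return data.frame: `chrom`, `segment`, `start`, `end`, `mid`,
#'   `n_cos`, `d_telo`, `d_centro`, `d_centro_rel`, `d_center`.
#' @export
build_covariates <- function(co_table, meta, sex = "male",
                             scope = c("whole", "long_arm"),
                             n_segments = 10) {
  scope <- match.arg(scope)
  inc <- meta[!meta$is_sex & !is.na(meta$centromere_bp), , drop = FALSE]
  if (nrow(inc) < nrow(meta))
    message("build_covariates: excluded ", nrow(meta) - nrow(inc),
            " sex / centromere-less chromosomes")
  inc <- arm_lengths(inc)
  max_arm_mb <- max(inc$long_arm_bp) / 1e6
  kept <- if (is.null(co_table)) NULL else {
    k <- retained_crossovers(co_table)
    k[k$parent_sex == sex, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(inc)), function(i) {
    L <- inc$length_bp[i]; cen <- inc$centromere_bp[i]
    if (scope == "whole") {
      lo <- 0; hi <- L
    } else {
      # long arm: centromere -> farther telomere
      if (cen <= L - cen) { lo <- cen; hi <- L } else { lo <- 0; hi <- cen }
    }
    brk <- seq(lo, hi, length.out = n_segments + 1)
    mid <- (head(brk, -1) + tail(brk, -1)) / 2
    n_cos <- if (is.null(kept)) NA_integer_ else {
      m <- kept$midpoint[kept$chrom == inc$name[i] & kept$midpoint >= lo &
                           kept$midpoint <= hi]
      as.integer(tabulate(pmin(findInterval(m, brk), n_segments),
                          nbins = n_segments))
    }
    data.frame(chrom = inc$name[i], segment = seq_len(n_segments),
               start = head(brk, -1), end = tail(brk, -1), mid = mid,
               n_cos = n_cos,
               d_telo = pmin(mid, L - mid) / (L / 2),
               d_centro = abs(mid - cen) / 1e6 / max_arm_mb,
               d_centro_rel = abs(mid - cen) / L,
               d_center = abs(mid - L / 2) / L)
  })
  do.call(rbind, rows)
}

#' Fit and compare mixed models of crossover placement
#'
#' Fits Gaussian linear mixed models of the per-segment response with a
#' random intercept per chromosome, by maximum likelihood (not REML, so
#' AIC values are comparable across fixed-effect structures), for the four
#' candidate fixed-effect structures: null, telomere distance only,
#' centromere distance only, and both. Ranks them by AIC.
#'
#' @param covariates output of [build_covariates()] (or any data.frame
#'   with `chrom` and the model columns).
#' @param response name of the response column (default `"n_cos"`).
#' @param telomere_term,centromere_term covariate column names.
#' @return data.frame ledger: `model`, `k` (parameters), `logLik`, `AIC`,
#'   `dAIC` (vs best), `singular`; sorted by AIC; attribute `fits` holds
#'   the `lmer` objects.
#' @export
fit_model_ledger <- function(covariates, response = "n_cos",
                             telomere_term = "d_telo",
                             centromere_term = "d_centro") {
  stopifnot(length(unique(covariates$chrom)) >= 2)
  forms <- list(
    null = sprintf("%s ~ 1 + (1 | chrom)", response),
    telomere = sprintf("%s ~ %s + (1 | chrom)", response, telomere_term),
    centromere = sprintf("%s ~ %s + (1 | chrom)", response,
                         centromere_term),
    both = sprintf("%s ~ %s + %s + (1 | chrom)", response, telomere_term,
                   centromere_term))
  fits <- lapply(forms, function(f)
    suppressMessages(lme4::lmer(stats::as.formula(f), data = covariates,
                                REML = FALSE)))
  ledger <- data.frame(
    model = names(forms),
    k = vapply(fits, function(f) attr(logLik(f), "df"), numeric(1)),
    logLik = vapply(fits, function(f) as.numeric(logLik(f)), numeric(1)),
    AIC = vapply(fits, AIC, numeric(1)),
    singular = vapply(fits, lme4::isSingular, logical(1)),
    stringsAsFactors = FALSE)
  usable <- if (all(ledger$singular)) ledger$AIC else
    ifelse(ledger$singular, Inf, ledger$AIC)
  ledger$dAIC <- ledger$AIC - min(usable)
  ledger <- ledger[order(ledger$AIC), ]
  rownames(ledger) <- NULL
  attr(ledger, "fits") <- fits
  ledger
}

#' Scale FST windows by the chromosome mean
#'
#' `fst_star = fst / mean(fst)` per chromosome, so that the scaled values
#' average to 1 on every chromosome and differentiation is comparable
#' across chromosomes. Chromosomes whose mean FST is zero or negative are
#' excluded with a warning.
#'
#' @param fst_windows data.frame with `chrom`, `start`, `end`, `fst`
#'   (100-kb non-overlapping windows).
#' @return The table with an added `fst_star` column.
#' @export
fst_star <- function(fst_windows) {
  means <- tapply(fst_windows$fst, fst_windows$chrom, mean)
  bad <- names(means)[means <= 0]
  if (length(bad) > 0) {
    warning("excluding chromosomes with non-positive mean FST: ",
            paste(bad, collapse = ", "))
    fst_windows <- fst_windows[!fst_windows$chrom %in% bad, , drop = FALSE]
  }
  fst_windows$fst_star <-
    fst_windows$fst / as.numeric(means[fst_windows$chrom])
  rownames(fst_windows) <- NULL
  fst_windows
}

#' Read a per-window FST TSV
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `fst`.
#' @return data.frame.
#' @export
read_fst_windows <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "fst") %in% names(tab)))
  tab
}

#' Correlation between recombination and differentiation along chromosomes
#'
#' Pearson correlation (with p-value) between the per-segment mean
#' relative map length and the per-segment mean scaled FST, over matched
#' (chromosome-folded) segments.
#'
#' @param segment_recomb data.frame with `segment` and `relative_length`
#'   (e.g. segment means of [fold_and_bin()] output, pooled over
#'   chromosomes).
#' @param segment_fst data.frame with `segment` and `fst_star`.
#' @return List with `r`, `p_value`, `n`.
#' @export
recomb_differentiation_correlation <- function(segment_recomb,
                                               segment_fst) {
  m <- merge(segment_recomb, segment_fst, by = "segment")
  if (nrow(m) < 3 || sd(m$relative_length) == 0 || sd(m$fst_star) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(m)))
  ct <- cor.test(m$relative_length, m$fst_star)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
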