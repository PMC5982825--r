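#' Fraction of crossovers in multi-crossover windows
#'
#' Chromosomes are tiled with non-overlapping `window_bp` windows from
#' position 0; each crossover is assigned to the window containing its
#' midpoint. A hotspot is a window holding two or more crossovers; the
#' statistic is the fraction of all crossovers that fall in hotspots.
#'
#' @param co_table crossover table (validated rows used) or any data.frame
#'   with `chrom` and `midpoint`.
#' @param window_bp window size (e.g. 1e5 or 1e4).
#' @return Fraction in `[0, 1]` (0 when fewer than 2 crossovers).
#' @export
hotspot_fraction <- function(co_table, window_bp) {
  stopifnot(window_bp > 0)
  kept <- if ("status" %in% names(co_table))
    retained_crossovers(co_table) else co_table
  if (nrow(kept) < 2) return(0)
  win <- paste(kept$chrom, floor(kept$midpoint / window_bp))
  counts <- table(win)
  sum(counts[counts >= 2]) / nrow(kept)
}

#' Permutation test for crossover clustering into hotspots
#'
#' Null model: every observed crossover interval is re-placed uniformly at
#' random on its own chromosome (start ~ Uniform over the positions where
#' the interval fits), preserving interval lengths, and the hotspot
#' fraction is recomputed; repeated `n_sims` times. The p-value uses the
#' add-one convention `p = (1 + #{null >= observed}) / (n_sims + 1)`.
#'
#' @param co_table crossover table (validated rows used).
#' @param meta a [chrom_meta()] table.
#' @param window_bp hotspot window size.
#' @param n_sims number of simulations, default 10000.
#' @return List of class `permutation_result`: `statistic`, `observed`,
#'   `n_sims`, `null_median`, `null_q025`, `null_q975`, `p_value`, `null`
#'   (the full null sample).
#' @export
hotspot_permutation <- function(co_table, meta, window_bp,
                                n_sims = 10000) {
  kept <- if ("status" %in% names(co_table))
    retained_crossovers(co_table) else co_table
  observed <- hotspot_fraction(kept, window_bp)
  len <- setNames(meta$length_bp, meta$name)
  width <- if ("resolution" %in% names(kept)) kept$resolution else
    kept$right - kept$left
  if (any(width > len[kept$chrom]))
    stop("crossover interval longer than its chromosome")
  null <- replicate(n_sims, {
    start <- runif(nrow(kept), 0, len[kept$chrom] - width)
    hotspot_fraction(data.frame(chrom = kept$chrom,
                                midpoint = start + width / 2),
                     window_bp)
  })
  perm_result("hotspot_fraction", observed, null)
}

perm_result <- function(name, observed, null) {
  structure(list(
    statistic = name, observed = observed, n_sims = length(null),
    null_median = median(null),
    null_q025 = unname(quantile(null, 0.025)),
    null_q975 = unname(quantile(null, 0.975)),
    p_value = (1 + sum(null >= observed)) / (length(null) + 1),
    p_value_depletion = (1 + sum(null <= observed)) / (length(null) + 1),
    null = null), class = "permutation_result")
}

#' @exportS3Method base::print
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "%s: observed %.4f, null median %.4f [%.4f, %.4f], p = %.4g (%d sims)\n",
    x$statistic, x$observed, x$null_median, x$null_q025, x$null_q975,
    x$p_value, x$n_sims))
  invisible(x)
}

#' Permutation test for crossover-interval overlap with gene features
#'
#' The observed statistic is the fraction of crossover intervals
#' overlapping at least one feature of the requested class by at least one
#' base. The null re-places intervals uniformly on their chromosomes
#' (lengths preserved), as in [hotspot_permutation()]. Both enrichment and
#' depletion p-values are reported (add-one convention); `p_two_sided` is
#' twice the smaller, capped at 1.
#'
#' @param co_table crossover table (validated rows used).
#' @param annotations a `GRanges` of gene annotations (see
#'   [read_gene_annotations()]).
#' @param feature one of `"gene"`, `"exon"`, `"intron"`, `"promoter"`.
#' @param meta a [chrom_meta()] table.
#' @param n_sims number of simulations.
#' @param end_buffer optionally constrain null placements to midpoints at
#'   least this far from chromosome ends (0 = unconstrained, the default).
#' @return A `permutation_result` with an extra `p_two_sided` element.
#' @export
feature_overlap_permutation <- function(co_table, annotations, feature,
                                        meta, n_sims = 10000,
                                        end_buffer = 0) {
  kept <- if ("status" %in% names(co_table))
    retained_crossovers(co_table) else co_table
  feats <- feature_ranges(annotations, feature, meta)
  co_gr <- GenomicRanges::GRanges(
    kept$chrom, IRanges::IRanges(kept$left, kept$right))
  obs <- overlap_fraction(co_gr, feats)
  len <- setNames(meta$length_bp, meta$name)
  width <- kept$right - kept$left
  lo <- pmax(0, end_buffer - width / 2)
  hi <- pmin(len[kept$chrom] - width, len[kept$chrom] - end_buffer -
               width / 2)
  null <- replicate(n_sims, {
    start <- runif(nrow(kept), lo, pmax(lo, hi))
    gr <- GenomicRanges::GRanges(
      kept$chrom, IRanges::IRanges(round(start), round(start) + width))
    overlap_fraction(gr, feats)
  })
  out <- perm_result(paste0("overlap_", feature), obs, null)
  out$p_two_sided <- min(1, 2 * min(out$p_value, out$p_value_depletion))
  out
}

overlap_fraction <- function(query, subject) {
  if (length(query) == 0) return(0)
  mean(IRanges::overlapsAny(query, subject, ignore.strand = TRUE))
}

#' GC content of crossover intervals versus flanking regions
#'
#' Computes GC content — (G + C) / (A + C + G + T), Ns ignored — inside
#' each crossover interval and in its two `flank_bp` flanking regions
#' (pooled, truncated at chromosome ends), and compares interval to flank
#' per sex with a paired t-test. Intervals consisting only of Ns are
#' excluded.
#'
#' @param co_table crossover table (validated rows used).
#' @param genome a `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`) named by chromosome.
#' @param flank_bp flank size, default 250 kb.
#' @return List with `per_interval` (data.frame: chrom, left, right,
#'   parent_sex, gc_interval, gc_flank) and `tests` (per sex: mean GC in
#'   intervals, in flanks, paired-t p-value).
#' @export
gc_analysis <- function(co_table, genome, flank_bp = 250000) {
  kept <- retained_crossovers(co_table)
  stopifnot(all(kept$chrom %in% names(genome)))
  n <- nrow(kept)
  gc_i <- numeric(n); gc_f <- numeric(n)
  for (i in seq_len(n)) {
    seq <- genome[[kept$chrom[i]]]
    L <- length(seq)
    a <- max(1, round(kept$left[i])); b <- min(L, round(kept$right[i]))
    gc_i[i] <- gc_of(Biostrings::subseq(seq, a, b))
    fl <- max(1, a - flank_bp)
    fr <- min(L, b + flank_bp)
    left_fl <- if (a > 1) Biostrings::subseq(seq, fl, a - 1) else NULL
    right_fl <- if (b < L) Biostrings::subseq(seq, b + 1, fr) else NULL
    gc_f[i] <- gc_of_pooled(left_fl, right_fl)
  }
  ok <- !is.na(gc_i) & !is.na(gc_f)
  if (any(!ok))
    message("gc_analysis: excluded ", sum(!ok), " all-N intervals")
  per <- data.frame(chrom = kept$chrom[ok], left = kept$left[ok],
                    right = kept$right[ok],
                    parent_sex = kept$parent_sex[ok],
                    gc_interval = gc_i[ok], gc_flank = gc_f[ok])
  tests <- lapply(split(per, per$parent_sex), function(d) {
    tt <- if (nrow(d) >= 2 && sd(d$gc_interval - d$gc_flank) > 0)
      t.test(d$gc_interval, d$gc_flank, paired = TRUE) else NULL
    list(n = nrow(d), mean_gc_interval = mean(d$gc_interval),
         mean_gc_flank = mean(d$gc_flank),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  list(per_interval = per, tests = tests)
}

acgt_counts <- function(seq) {
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  if (is.matrix(f)) f <- f[1, ]
  f
}

gc_of <- function(seq) {
  f <- acgt_counts(seq)
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / tot)
}

gc_of_pooled <- function(a, b) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in list(a, b)) {
    if (!is.null(s)) counts <- counts + acgt_counts(s)
  }
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts[["G"]] + counts[["C"]]) / tot)
}
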