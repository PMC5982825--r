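#' Allele-sharing track for a sibling gamete pair
#'
#' For one parent and chromosome, codes each informative site 0 when the
#' two siblings inherited the same parental allele and 1 when they
#' inherited different alleles (exclusive-or). A crossover in one of the
#' two transmitted gametes manifests as a changepoint in this binary
#' series.
#'
#' @param pair data.frame with `pos`, `allele_son`, `allele_daughter`
#'   (one element of [gamete_pairs()]).
#' @return data.frame with `pos` and binary `share` code.
#' @export
sharing_track <- function(pair) {
  stopifnot(nrow(pair) >= 1)
  data.frame(pos = pair$pos,
             share = as.integer(pair$allele_son != pair$allele_daughter))
}

#' Detect candidate changepoints in a binary sharing track
#'
#' Exact penalized-likelihood segmentation of the binary series: the cost
#' of a segment is its Bernoulli maximum log-likelihood (negated) and each
#' changepoint pays a penalty of `beta * log(n)` where `n` is the track
#' length. The optimum over all segmentations is found by pruned exact
#' linear-time optimal partitioning (PELT), which is guaranteed to match
#' exhaustive search for this cost class.
#'
#' @param track a [sharing_track()].
#' @param beta penalty multiplier (default 3).
#' @return Integer vector of candidate indices `i`: a changepoint lies
#'   between sites `i` and `i + 1` of the track.
#' @export
detect_changepoints <- function(track, beta = 3) {
  x <- as.integer(track$share)
  n <- length(x)
  if (n < 2) return(integer(0))
  .pelt_binary(x, beta * log(n))
}

#' Validate candidate changepoints by windowed allele-sharing means
#'
#' A candidate between sites `i` and `i + 1` is kept only when the mean
#' share code over the `window_bp` span to the left of site `i` and the
#' span to the right of site `i + 1` fall on opposite sides of the
#' `(lo, hi)` band — an unambiguous switch from near-0 to near-1 sharing or
#' vice versa. Candidates whose window contains no sites on either side are
#' rejected.
#'
#' @param candidates indices from [detect_changepoints()].
#' @param track the [sharing_track()].
#' @param window_bp averaging window, default 100 kb.
#' @param lo,hi thresholds, default 0.1 and 0.9.
#' @return The accepted subset of `candidates`, with attribute
#'   `rejected` (data.frame of rejected candidates and reasons).
#' @export
validate_crossovers <- function(candidates, track, window_bp = 1e5,
                                lo = 0.1, hi = 0.9) {
  stopifnot(window_bp > 0, lo >= 0, lo < hi, hi <= 1)
  keep <- logical(length(candidates))
  reason <- character(length(candidates))
  for (k in seq_along(candidates)) {
    i <- candidates[k]
    lp <- track$pos[i]; rp <- track$pos[i + 1]
    left <- track$share[track$pos <= lp & track$pos > lp - window_bp]
    right <- track$share[track$pos >= rp & track$pos < rp + window_bp]
    if (length(left) == 0 || length(right) == 0) {
      reason[k] <- "empty_window"
      next
    }
    ml <- mean(left); mr <- mean(right)
    if ((ml < lo && mr > hi) || (ml > hi && mr < lo)) {
      keep[k] <- TRUE
    } else {
      reason[k] <- "ambiguous_sharing"
    }
  }
  out <- candidates[keep]
  attr(out, "rejected") <- data.frame(index = candidates[!keep],
                                      reason = reason[!keep])
  out
}

#' Apply the gene-conversion pair rule and chromosome-end rule
#'
#' Within each (parent, pair, chromosome) group, any two crossovers whose
#' midpoints are closer than `min_separation` are **both** removed (such
#' pairs are more plausibly gene-conversion events or mapping artefacts
#' than genuine double crossovers). Crossovers whose midpoint lies within
#' `end_buffer` of either chromosome end are removed. Removed rows stay in
#' the table with a `status` recording the rule that fired.
#'
#' @param cos data.frame of crossover intervals (columns `chrom`,
#'   `parent_sex`, `parent_id`, `pair_id`, `left`, `right`, `midpoint`,
#'   `resolution`, `status`).
#' @param meta a [chrom_meta()] table.
#' @param min_separation pair-rule distance, default 400 kb.
#' @param end_buffer end-rule distance, default 400 kb.
#' @return `cos` with updated `status`.
#' @export
filter_crossovers <- function(cos, meta, min_separation = 4e5,
                              end_buffer = 4e5) {
  if (nrow(cos) == 0) return(cos)
  len <- setNames(meta$length_bp, meta$name)
  grp <- interaction(cos$parent_id, cos$pair_id, cos$chrom, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g & cos$status == "validated")
    if (length(idx) >= 2) {
      m <- cos$midpoint[idx]
      close <- close_pair_flag(sort(m), min_separation)
      cos$status[idx[order(m)][close]] <- "removed_pair_rule"
    }
  }
  at_end <- cos$midpoint < end_buffer |
    cos$midpoint > len[cos$chrom] - end_buffer
  cos$status[cos$status == "validated" & at_end] <- "removed_end_rule"
  cos
}

#' Call crossovers for one gamete pair on one chromosome
#'
#' @param pair data.frame with `pos`, `allele_son`, `allele_daughter`.
#' @param beta,window_bp,lo,hi see [detect_changepoints()] and
#'   [validate_crossovers()].
#' @return data.frame with `left`, `right`, `midpoint`, `resolution`,
#'   `status` (`"validated"` or `"removed_validation"`).
#' @export
call_pair_chromosome <- function(pair, beta = 3, window_bp = 1e5,
                                 lo = 0.1, hi = 0.9) {
  track <- sharing_track(pair)
  cand <- detect_changepoints(track, beta = beta)
  if (length(cand) == 0)
    return(data.frame(left = numeric(0), right = numeric(0),
                      midpoint = numeric(0), resolution = numeric(0),
                      status = character(0)))
  ok <- validate_crossovers(cand, track, window_bp = window_bp,
                            lo = lo, hi = hi)
  status <- ifelse(cand %in% ok, "validated", "removed_validation")
  left <- track$pos[cand]
  right <- track$pos[cand + 1]
  data.frame(left = left, right = right, midpoint = (left + right) / 2,
             resolution = right - left, status = status)
}

#' Call crossovers across a set of quartets
#'
#' Runs phasing, sharing-track construction, changepoint detection,
#' window validation and the pair/end filters over every quartet, parent
#' and chromosome, and returns the combined crossover table. Each quartet
#' contributes one sibling gamete pair per parent; crossovers are counted
#' per pair per parent and never assigned to an individual gamete (the two
#' sibling gametes cannot be distinguished). Groups with three or more
#' retained crossovers on one chromosome are flagged
#' `implies_double_co = TRUE`, since they imply at least one gamete with a
#' double crossover.
#'
#' @param quartets list of [variant_table()]s (or a single one).
#' @param meta a [chrom_meta()] table.
#' @param config a [pipeline_config()] (thresholds; defaults are the
#'   conventional values).
#' @param mother_included logical vector per quartet: whether the maternal
#'   pair enters the analysis (default all TRUE).
#' @return data.frame: `chrom`, `parent_sex`, `parent_id`, `pair_id`,
#'   `left`, `right`, `midpoint`, `resolution`, `status`,
#'   `implies_double_co`.
#' @export
call_crossovers <- function(quartets, meta, config = pipeline_config(),
                            mother_included = NULL) {
  if (is.data.frame(quartets)) quartets <- list(quartets)
  if (is.null(mother_included))
    mother_included <- rep(TRUE, length(quartets))
  rows <- list()
  for (q in seq_along(quartets)) {
    phased <- phase_quartet(quartets[[q]], min_gq = config$min_gq,
                            min_tp = config$min_tp)
    for (parent in c("father", "mother")) {
      if (parent == "mother" && !mother_included[q]) next
      sub <- phased[phased$parent == parent, , drop = FALSE]
      for (chr in unique(sub$chrom)) {
        pair <- sub[sub$chrom == chr, , drop = FALSE]
        if (nrow(pair) < 2) next
        calls <- call_pair_chromosome(pair, beta = config$beta,
                                      window_bp = config$window_bp,
                                      lo = config$lo, hi = config$hi)
        if (nrow(calls) == 0) next
        calls$chrom <- chr
        calls$parent_sex <- if (parent == "father") "male" else "female"
        calls$parent_id <- sprintf("%s%02d", parent, q)
        calls$pair_id <- sprintf("pair%02d", q)
        rows[[length(rows) + 1]] <- calls
      }
    }
  }
  if (length(rows) == 0)
    return(empty_co_table())
  cos <- do.call(rbind, rows)
  cos <- cos[c("chrom", "parent_sex", "parent_id", "pair_id", "left",
               "right", "midpoint", "resolution", "status")]
  cos <- filter_crossovers(cos, meta,
                           min_separation = config$min_separation,
                           end_buffer = config$end_buffer)
  cos$implies_double_co <- flag_double_co(cos)
  rownames(cos) <- NULL
  cos
}

empty_co_table <- function() {
  data.frame(chrom = character(0), parent_sex = character(0),
             parent_id = character(0), pair_id = character(0),
             left = numeric(0), right = numeric(0), midpoint = numeric(0),
             resolution = numeric(0), status = character(0),
             implies_double_co = logical(0))
}

flag_double_co <- function(cos) {
  if (nrow(cos) == 0) return(logical(0))
  key <- paste(cos$parent_id, cos$pair_id, cos$chrom)
  retained <- cos$status == "validated"
  counts <- table(key[retained])
  key %in% names(counts)[counts >= 3] & retained
}

#' Retained crossovers
#'
#' @param cos a crossover table from [call_crossovers()].
#' @return The rows with `status == "validated"`.
#' @export
retained_crossovers <- function(cos) {
  cos[cos$status == "validated", , drop = FALSE]
}

#' Write / read a crossover table as TSV
#'
#' @param cos crossover table.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_co_table <- function(cos, path) {
  write.table(cos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_co_table
#' @export
read_co_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
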