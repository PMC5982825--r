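#' Phase a single site by Mendelian transmission
#'
#' Given the unordered genotypes of father, mother and one offspring at a
#' biallelic SNP (coded as the count of the alternate allele: 0, 1, 2, or
#' `NA` for missing), determine which allele each parent transmitted to the
#' offspring. The assignment is unique exactly when the offspring is
#' heterozygous and at least one parent is homozygous (the informative-site
#' rule), or when the offspring is homozygous and both parents carry the
#' transmitted allele.
#'
#' @param father_gt,mother_gt,offspring_gt genotypes in `c(0, 1, 2, NA)`.
#' @return A list with `status` in
#'   `c("determined", "undetermined", "violation", "missing")` and, when
#'   determined, integer `paternal` and `maternal` transmitted alleles
#'   (each 0 or 1); otherwise `NA`.
#' @examples
#' phase_site(1, 2, 1)  # father 0/1, mother 1/1, offspring 0/1
#' phase_site(1, 1, 1)  # both parents het: undetermined
#' phase_site(0, 0, 1)  # Mendelian violation
#' @export
phase_site <- function(father_gt, mother_gt, offspring_gt) {
  if (is.na(father_gt) || is.na(mother_gt) || is.na(offspring_gt))
    return(list(status = "missing", paternal = NA_integer_,
                maternal = NA_integer_))
  sols <- phase_solutions(father_gt, mother_gt, offspring_gt)
  if (nrow(sols) == 0L)
    return(list(status = "violation", paternal = NA_integer_,
                maternal = NA_integer_))
  if (nrow(sols) > 1L)
    return(list(status = "undetermined", paternal = NA_integer_,
                maternal = NA_integer_))
  list(status = "determined", paternal = sols$paternal,
       maternal = sols$maternal)
}

# all (paternal, maternal) allele assignments consistent with the triple
phase_solutions <- function(father_gt, mother_gt, offspring_gt) {
  can_transmit <- function(gt, allele) {
    (allele == 0 && gt <= 1) || (allele == 1 && gt >= 1)
  }
  out <- expand.grid(paternal = 0:1, maternal = 0:1)
  ok <- vapply(seq_len(nrow(out)), function(i) {
    p <- out$paternal[i]; m <- out$maternal[i]
    p + m == offspring_gt && can_transmit(father_gt, p) &&
      can_transmit(mother_gt, m)
  }, logical(1))
  out[ok, , drop = FALSE]
}

# Vectorized phasing of one offspring over a whole table. Returns a list of
# integer vectors paternal/maternal (NA unless determined) and a status
# factor. Encodes the triple as f*9 + m*3 + o and looks the answer up in a
# 27-entry table built from phase_site() itself at load time.
phase_offspring_vec <- function(father_gt, mother_gt, offspring_gt) {
  key <- father_gt * 9L + mother_gt * 3L + offspring_gt + 1L
  lut <- phase_lut()
  status <- rep("missing", length(key))
  pat <- rep(NA_integer_, length(key))
  mat <- rep(NA_integer_, length(key))
  ok <- !is.na(key)
  status[ok] <- lut$status[key[ok]]
  pat[ok] <- lut$paternal[key[ok]]
  mat[ok] <- lut$maternal[key[ok]]
  list(status = status, paternal = pat, maternal = mat)
}

phase_lut_cache <- new.env(parent = emptyenv())
phase_lut <- function() {
  if (is.null(phase_lut_cache$lut)) {
    grid <- expand.grid(o = 0:2, m = 0:2, f = 0:2)
    res <- lapply(seq_len(nrow(grid)), function(i)
      phase_site(grid$f[i], grid$m[i], grid$o[i]))
    phase_lut_cache$lut <- list(
      status = vapply(res, `[[`, character(1), "status"),
      paternal = vapply(res, `[[`, integer(1), "paternal"),
      maternal = vapply(res, `[[`, integer(1), "maternal")
    )
  }
  phase_lut_cache$lut
}

#' Phase a quartet's gametes by transmission
#'
#' Applies the per-site transmission rule to both offspring of a quartet,
#' then applies the quality filters: all four genotypes must be present
#' with genotype quality `GQ >= min_gq`, and the phasing confidence of both
#' offspring must reach `min_tp`. When the input carries no `TP` field (the
#' usual case for this package's own phaser), a confidence analogue is
#' assigned: 60 for sites whose transmission assignment is unique with all
#' genotypes passing the GQ filter, 0 otherwise, so the conventional
#' `min_tp = 60` retains exactly the uniquely determined high-quality sites.
#'
#' For each parent, the returned track keeps only sites that are
#' *informative for that parent* — the parent is heterozygous (so its two
#' haplotypes are distinguishable) and the transmitted allele is determined
#' for **both** offspring. Counts of sites dropped at each stage are
#' reported as a `filter_log` attribute.
#'
#' @param vt a [variant_table()] of quartet genotypes.
#' @param min_gq minimum genotype quality, default 999.
#' @param min_tp minimum phasing confidence, default 60.
#' @return A `data.frame` with columns `parent` (`"father"`/`"mother"`),
#'   `chrom`, `pos`, `allele_son`, `allele_daughter`, with attribute
#'   `filter_log`.
#' @export
phase_quartet <- function(vt, min_gq = 999, min_tp = 60) {
  n <- nrow(vt)
  log <- list(n_input = n)

  gq_ok <- !is.na(vt$father_gq) & vt$father_gq >= min_gq &
    !is.na(vt$mother_gq) & vt$mother_gq >= min_gq &
    !is.na(vt$son_gq) & vt$son_gq >= min_gq &
    !is.na(vt$daughter_gq) & vt$daughter_gq >= min_gq
  gt_ok <- !is.na(vt$father_gt) & !is.na(vt$mother_gt) &
    !is.na(vt$son_gt) & !is.na(vt$daughter_gt)
  log$n_fail_gq <- sum(!gq_ok)
  log$n_missing_gt <- sum(gt_ok == FALSE)

  son <- phase_offspring_vec(vt$father_gt, vt$mother_gt, vt$son_gt)
  dau <- phase_offspring_vec(vt$father_gt, vt$mother_gt, vt$daughter_gt)
  log$n_violation <- sum(son$status == "violation" |
                           dau$status == "violation")

  tp_son <- tp_track(vt, "son", son$status, gq_ok, min_tp)
  tp_dau <- tp_track(vt, "daughter", dau$status, gq_ok, min_tp)

  keep <- gq_ok & gt_ok &
    son$status == "determined" & dau$status == "determined" &
    tp_son & tp_dau
  log$n_phased_both <- sum(keep)

  out <- lapply(c("father", "mother"), function(parent) {
    het <- if (parent == "father") vt$father_gt == 1L else vt$mother_gt == 1L
    idx <- which(keep & !is.na(het) & het)
    a_son <- if (parent == "father") son$paternal else son$maternal
    a_dau <- if (parent == "father") dau$paternal else dau$maternal
    data.frame(parent = rep(parent, length(idx)),
               chrom = vt$chrom[idx], pos = vt$pos[idx],
               allele_son = a_son[idx], allele_daughter = a_dau[idx],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  log$n_informative_father <- sum(res$parent == "father")
  log$n_informative_mother <- sum(res$parent == "mother")
  attr(res, "filter_log") <- log
  res
}

# honor an external TP column when present, otherwise the analogue:
# determined + GQ pass -> 60
tp_track <- function(vt, who, status, gq_ok, min_tp) {
  col <- paste0(who, "_tp")
  if (col %in% names(vt) && any(!is.na(vt[[col]]))) {
    tp <- vt[[col]]
    !is.na(tp) & tp >= min_tp
  } else {
    analogue <- ifelse(status == "determined" & gq_ok, 60, 0)
    analogue >= min_tp
  }
}

#' Split a phased quartet into per-parent, per-chromosome gamete pairs
#'
#' @param phased output of [phase_quartet()].
#' @return Named list (by `parent.chrom`) of data.frames with `pos`,
#'   `allele_son`, `allele_daughter`.
#' @export
gamete_pairs <- function(phased) {
  split(phased[c("pos", "allele_son", "allele_daughter")],
        list(phased$parent, phased$chrom), drop = TRUE)
}
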