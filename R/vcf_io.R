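#' Quartet variant table
#'
#' The ingestion boundary of the pipeline: per-site genotypes (count of the
#' alternate allele: 0, 1, 2 or `NA`), genotype qualities and optional
#' phasing-confidence scores for the four members of a quartet. Only
#' biallelic SNPs are admitted; positions are strictly increasing within a
#' chromosome.
#'
#' @param chrom,pos,ref,alt site columns (`pos` 1-based).
#' @param father_gt,mother_gt,son_gt,daughter_gt genotypes in `c(0,1,2,NA)`.
#' @param father_gq,mother_gq,son_gq,daughter_gq genotype qualities.
#' @param father_tp,mother_tp,son_tp,daughter_tp phasing confidence
#'   (optional, `NA` when absent).
#' @return A `data.frame` of class `variant_table`, sorted by
#'   `(chrom, pos)`.
#' @export
variant_table <- function(chrom, pos, ref, alt,
                          father_gt, mother_gt, son_gt, daughter_gt,
                          father_gq, mother_gq, son_gq, daughter_gq,
                          father_tp = NA_integer_, mother_tp = NA_integer_,
                          son_tp = NA_integer_, daughter_tp = NA_integer_) {
  vt <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    father_gt = as.integer(father_gt), mother_gt = as.integer(mother_gt),
    son_gt = as.integer(son_gt), daughter_gt = as.integer(daughter_gt),
    father_gq = as.integer(father_gq), mother_gq = as.integer(mother_gq),
    son_gq = as.integer(son_gq), daughter_gq = as.integer(daughter_gq),
    father_tp = as.integer(father_tp), mother_tp = as.integer(mother_tp),
    son_tp = as.integer(son_tp), daughter_tp = as.integer(daughter_tp),
    stringsAsFactors = FALSE
  )
  vt <- vt[order(vt$chrom, vt$pos), , drop = FALSE]
  if (any(unlist(lapply(split(vt$pos, vt$chrom), duplicated))))
    stop("duplicated positions within a chromosome")
  rownames(vt) <- NULL
  class(vt) <- c("variant_table", "data.frame")
  vt
}

quartet_roles <- c("father", "mother", "son", "daughter")

#' Read quartet genotypes from a VCF
#'
#' Loads a VCF via \pkg{vcfR}, keeps only biallelic SNP records (indels and
#' multiallelic sites are dropped, with counts reported in the
#' `filter_log` attribute) and extracts GT, GQ and (when present) TP for
#' the four named individuals.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param individual_ids named character vector with entries `father`,
#'   `mother`, `son`, `daughter` giving the sample names in the VCF.
#' @return A [variant_table()].
#' @export
read_vcf_quartet <- function(path, individual_ids) {
  stopifnot(all(quartet_roles %in% names(individual_ids)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  miss <- setdiff(unname(individual_ids[quartet_roles]), samples)
  if (length(miss) > 0)
    stop("individuals not found in VCF: ", paste(miss, collapse = ", "))

  fix <- vcf@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message("read_vcf_quartet: dropped ", n_drop,
            " non-biallelic-SNP records")

  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)[is_snp, ,
                                                                 drop = FALSE]
  has_tp <- grepl("TP", unique(vcf@gt[, "FORMAT"])[1], fixed = TRUE)
  tp <- if (has_tp)
    vcfR::extract.gt(vcf, element = "TP", as.numeric = TRUE)[is_snp, ,
                                                             drop = FALSE]
  else NULL

  grab <- function(role, mat, default = NA_integer_) {
    if (is.null(mat)) return(default)
    mat[, individual_ids[[role]]]
  }
  vt <- variant_table(
    chrom = fix[is_snp, "CHROM"], pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp], alt = alt[is_snp],
    father_gt = gt_to_dosage(grab("father", gt)),
    mother_gt = gt_to_dosage(grab("mother", gt)),
    son_gt = gt_to_dosage(grab("son", gt)),
    daughter_gt = gt_to_dosage(grab("daughter", gt)),
    father_gq = grab("father", gq), mother_gq = grab("mother", gq),
    son_gq = grab("son", gq), daughter_gq = grab("daughter", gq),
    father_tp = grab("father", tp), mother_tp = grab("mother", tp),
    son_tp = grab("son", tp), daughter_tp = grab("daughter", tp)
  )
  attr(vt, "filter_log") <- list(n_records = length(is_snp),
                                 n_dropped_nonsnp = n_drop,
                                 n_retained = sum(is_snp))
  vt
}

# "0/0", "0|1", "1/1", "./." -> 0, 1, 2, NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  out <- suppressWarnings(as.integer(a1) + as.integer(a2))
  out[is.na(gt) | a1 == "." | a2 == "."] <- NA_integer_
  out
}

#' Write a quartet variant table as VCF
#'
#' Emits a minimal VCF 4.2 with `GT:GQ` (plus `:TP` when any
#' phasing-confidence value is present) for the four quartet members, in
#' the column order father, mother, son, daughter.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param meta optional [chrom_meta()] used to write contig headers.
#' @param individual_ids sample names for the four roles.
#' @return `path`, invisibly.
#' @export
write_quartet_vcf <- function(vt, path, meta = NULL,
                              individual_ids = c(father = "father",
                                                 mother = "mother",
                                                 son = "son",
                                                 daughter = "daughter")) {
  has_tp <- any(!is.na(vt$father_tp)) || any(!is.na(vt$son_tp)) ||
    any(!is.na(vt$mother_tp)) || any(!is.na(vt$daughter_tp))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=meiomap",
           if (!is.null(meta))
             sprintf("##contig=<ID=%s,length=%d>", meta$name,
                     as.integer(meta$length_bp)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           if (has_tp)
             "##FORMAT=<ID=TP,Number=1,Type=Integer,Description=\"Phasing confidence\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   unname(individual_ids[quartet_roles])), collapse = "\t"))
  fmt <- if (has_tp) "GT:GQ:TP" else "GT:GQ"
  cell <- function(gt, gq, tp) {
    g <- c("0/0", "0/1", "1/1")[gt + 1L]
    g[is.na(gt)] <- "./."
    q <- ifelse(is.na(gq), ".", as.character(gq))
    if (has_tp) {
      t <- ifelse(is.na(tp), ".", as.character(tp))
      paste(g, q, t, sep = ":")
    } else paste(g, q, sep = ":")
  }
  lines <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".",
                 fmt,
                 cell(vt$father_gt, vt$father_gq, vt$father_tp),
                 cell(vt$mother_gt, vt$mother_gq, vt$mother_tp),
                 cell(vt$son_gt, vt$son_gq, vt$son_tp),
                 cell(vt$daughter_gt, vt$daughter_gq, vt$daughter_tp),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
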