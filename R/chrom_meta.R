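#' Chromosome metadata
#'
#' A chromosome metadata table holds, for every chromosome in the assembly,
#' its physical length, the centromere position where one could be located,
#' and whether the chromosome is a sex chromosome. Centromere-dependent
#' analyses (arm rates, centromere-distance covariates) silently drop
#' chromosomes whose centromere is absent; sex chromosomes are excluded from
#' the mixed-model analyses.
#'
#' @param name character vector of chromosome names.
#' @param length_bp integer vector of chromosome lengths in bp.
#' @param centromere_bp numeric vector of centromere positions in bp
#'   (`NA` where no centromere could be located).
#' @param is_sex logical vector flagging sex chromosomes.
#' @return A `data.frame` of class `chrom_meta` with columns `name`,
#'   `length_bp`, `centromere_bp`, `is_sex`.
#' @examples
#' chrom_meta("chrI", 2e7, 5e6, FALSE)
#' @export
chrom_meta <- function(name, length_bp, centromere_bp = NA_real_,
                       is_sex = FALSE) {
  meta <- data.frame(
    name = as.character(name),
    length_bp = as.numeric(length_bp),
    centromere_bp = as.numeric(centromere_bp),
    is_sex = as.logical(is_sex),
    stringsAsFactors = FALSE
  )
  validate_chrom_meta(meta)
  class(meta) <- c("chrom_meta", "data.frame")
  meta
}

validate_chrom_meta <- function(meta) {
  stopifnot(all(c("name", "length_bp", "centromere_bp", "is_sex") %in%
                  names(meta)))
  if (anyDuplicated(meta$name))
    stop("duplicated chromosome names in metadata")
  if (any(meta$length_bp <= 0))
    stop("chromosome lengths must be positive")
  bad <- !is.na(meta$centromere_bp) &
    (meta$centromere_bp <= 0 | meta$centromere_bp >= meta$length_bp)
  if (any(bad))
    stop("centromere position outside (0, length) for: ",
         paste(meta$name[bad], collapse = ", "))
  invisible(meta)
}

#' Read a chromosome metadata TSV
#'
#' Expects a tab-separated file with columns `name`, `length_bp`,
#' `centromere_bp` (may be empty for chromosomes where no centromere could
#' be located) and `is_sex` (TRUE/FALSE).
#'
#' @param path path to the TSV file.
#' @return A [chrom_meta()] table.
#' @export
read_chrom_meta <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "length_bp", "centromere_bp", "is_sex")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("chromosome metadata is missing columns: ",
         paste(miss, collapse = ", "))
  chrom_meta(tab$name, tab$length_bp,
             suppressWarnings(as.numeric(tab$centromere_bp)),
             as.logical(tab$is_sex))
}

#' Write chromosome metadata as TSV
#'
#' @param meta a [chrom_meta()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic karyotype
#'
#' Deterministic 21-chromosome karyotype emulating a stickleback-like
#' genome: chromosome lengths between 15 and 30 Mb, a mixture of
#' acrocentric and metacentric centromere placements, three chromosomes
#' with no locatable centromere (analogues of chromosomes 2, 4 and 8) and
#' two sex chromosomes (analogues of 9 and 19).
#'
#' @param n_chrom number of chromosomes (default 21).
#' @return A [chrom_meta()] table.
#' @examples
#' meta <- default_chrom_meta()
#' sum(is.na(meta$centromere_bp))  # 3 without centromere
#' @export
default_chrom_meta <- function(n_chrom = 21) {
  i <- seq_len(n_chrom)
  # lengths cycle deterministically through 15-30 Mb
  len <- 15e6 + ((i * 7) %% 16) * 1e6
  # alternate acrocentric (20% in) and metacentric (45% in)
  frac <- ifelse(i %% 2 == 0, 0.45, 0.20)
  cen <- round(len * frac)
  no_cen <- i %in% c(2, 4, 8)
  cen[no_cen] <- NA_real_
  is_sex <- i %in% c(9, 19)
  chrom_meta(sprintf("chr%02d", i), len, cen, is_sex)
}

#' Arm lengths from metadata
#'
#' @param meta a [chrom_meta()] table.
#' @return `meta` with added columns `short_arm_bp` and `long_arm_bp`
#'   (`NA` where the centromere is absent).
#' @export
arm_lengths <- function(meta) {
  p <- meta$centromere_bp
  q <- meta$length_bp - p
  meta$short_arm_bp <- pmin(p, q)
  meta$long_arm_bp <- pmax(p, q)
  meta
}
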