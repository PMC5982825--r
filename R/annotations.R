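#' Read gene annotations from GFF3 or BED
#'
#' Thin wrapper over `rtracklayer::import`. GFF3 files keep their `type`
#' column (gene/exon features as annotated); BED files are treated as gene
#' spans (`type = "gene"`).
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @return A `GRanges` with a `type` metadata column.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(gr$type)) gr$type <- "gene"
  gr
}

#' Derive feature ranges of a class from gene annotations
#'
#' `"gene"` and `"exon"` select records of that type; `"intron"` is the
#' per-gene set difference gene-minus-exons; `"promoter"` is the 2-kb
#' region upstream of each gene's transcription start, strand-aware and
#' truncated at chromosome edges.
#'
#' @param annotations a `GRanges` with a `type` column.
#' @param feature `"gene"`, `"exon"`, `"intron"` or `"promoter"`.
#' @param meta a [chrom_meta()] table (for edge truncation).
#' @param promoter_bp promoter length, default 2000.
#' @return A `GRanges`.
#' @export
feature_ranges <- function(annotations, feature, meta,
                           promoter_bp = 2000) {
  feature <- match.arg(feature, c("gene", "exon", "intron", "promoter"))
  genes <- annotations[annotations$type == "gene"]
  if (feature == "gene") return(genes)
  exons <- annotations[annotations$type == "exon"]
  if (feature == "exon") return(exons)
  if (feature == "intron")
    return(GenomicRanges::setdiff(GenomicRanges::reduce(genes),
                                  GenomicRanges::reduce(exons),
                                  ignore.strand = TRUE))
  # 2 kb upstream of the transcription start, strand-aware, clamped to
  # the chromosome
  lens <- setNames(meta$length_bp, meta$name)
  chr <- as.character(GenomicRanges::seqnames(genes))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  tss_up_start <- ifelse(minus, GenomicRanges::end(genes) + 1,
                         GenomicRanges::start(genes) - promoter_bp)
  tss_up_end <- ifelse(minus, GenomicRanges::end(genes) + promoter_bp,
                       GenomicRanges::start(genes) - 1)
  s <- pmax(1, tss_up_start)
  e <- pmin(lens[chr], tss_up_end)
  keep <- e >= s
  GenomicRanges::GRanges(chr[keep], IRanges::IRanges(s[keep], e[keep]),
                         strand = GenomicRanges::strand(genes)[keep])
}
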