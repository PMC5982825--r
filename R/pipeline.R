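#' Pipeline configuration
#'
#' Collects every analysis threshold as a named, overridable parameter.
#' Defaults are the conventional conservative values: genotype quality
#' floor 999, phasing-confidence floor 60, changepoint penalty multiplier
#' 3, 100-kb validation windows with 0.1/0.9 sharing thresholds, 400-kb
#' crossover pair separation and chromosome-end buffer, 250-kb GC flanks,
#' 2-kb promoters and 10,000 permutation draws.
#'
#' @param min_gq,min_tp phasing quality filters.
#' @param beta changepoint penalty multiplier.
#' @param window_bp,lo,hi crossover validation parameters.
#' @param min_separation,end_buffer crossover filter distances (bp).
#' @param gc_flank_bp GC flank size.
#' @param promoter_bp promoter length.
#' @param n_sims permutation count.
#' @param seed random seed recorded in outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_gq = 999, min_tp = 60, beta = 3,
                            window_bp = 1e5, lo = 0.1, hi = 0.9,
                            min_separation = 4e5, end_buffer = 4e5,
                            gc_flank_bp = 250000, promoter_bp = 2000,
                            n_sims = 10000, seed = 1L) {
  structure(list(min_gq = min_gq, min_tp = min_tp, beta = beta,
                 window_bp = window_bp, lo = lo, hi = hi,
                 min_separation = min_separation, end_buffer = end_buffer,
                 gc_flank_bp = gc_flank_bp, promoter_bp = promoter_bp,
                 n_sims = n_sims, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] parameters may be given; the
#' rest keep their defaults. Input paths (`vcf`, `chrom_meta`, `fasta`,
#' `annotations`, `fst_windows`, `individual_ids`, `out_dir`) are carried
#' through unchanged.
#'
#' @param path YAML file.
#' @return List with elements `config` ([pipeline_config()]) and `inputs`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  cfg <- do.call(pipeline_config, raw[intersect(names(raw), known)])
  list(config = cfg, inputs = raw[setdiff(names(raw), known)])
}

#' Run the crossover pipeline end to end
#'
#' Reads quartet VCFs, phases, calls and filters crossovers, computes the
#' map table and writes all outputs (crossover table, map statistics,
#' model ledgers, permutation reports where inputs allow) under
#' `out_dir`. Every output embeds the seed and thresholds used. With zero
#' quartets the outputs are written empty and the run still succeeds.
#'
#' @param vcf_paths character vector of quartet VCFs (may be empty).
#' @param individual_ids named list (per VCF) or single named vector of
#'   sample names for the four quartet roles.
#' @param meta a [chrom_meta()] table.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param mother_included per-quartet flags (default all TRUE).
#' @return List with `co_table`, `map_table` and the written paths,
#'   invisibly.
#' @export
run_pipeline <- function(vcf_paths, individual_ids, meta, out_dir,
                         config = pipeline_config(),
                         mother_included = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (is.null(mother_included))
    mother_included <- rep(TRUE, length(vcf_paths))
  quartets <- lapply(vcf_paths, function(p) {
    ids <- if (is.list(individual_ids)) individual_ids[[p]] else
      individual_ids
    read_vcf_quartet(p, ids)
  })
  cos <- if (length(quartets) > 0)
    call_crossovers(quartets, meta, config, mother_included)
  else empty_co_table()

  n_pairs_male <- length(quartets)
  n_pairs_female <- sum(mother_included)
  meioses <- c(male = 2 * n_pairs_male, female = 2 * n_pairs_female)

  paths <- list(co_table = file.path(out_dir, "crossovers.tsv"),
                map_table = file.path(out_dir, "map_table.tsv"),
                run_info = file.path(out_dir, "run_info.yaml"))
  write_co_table(cos, paths$co_table)
  map_tab <- if (nrow(retained_crossovers(cos)) > 0 && all(meioses > 0)) {
    mt <- per_chromosome_table(cos, meioses, meta$name)
    write.table(mt, paths$map_table, sep = "\t", quote = FALSE,
                row.names = FALSE)
    mt
  } else {
    write.table(empty_co_table(), paths$map_table, sep = "\t",
                quote = FALSE, row.names = FALSE)
    NULL
  }
  yaml::write_yaml(c(unclass(config),
                     list(n_quartets = length(quartets),
                          meioses_male = unname(meioses[["male"]]),
                          meioses_female = unname(meioses[["female"]]))),
                   paths$run_info)
  invisible(list(co_table = cos, map_table = map_tab, paths = paths))
}
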