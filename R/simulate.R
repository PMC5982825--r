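#' Meiosis parameters
#'
#' Parameters controlling chiasma number and placement for one sex.
#' Chiasma count per chromosome per meiosis is `obligate_co + Poisson
#' (extra_co_rate)`; positions are drawn from a piecewise placement density
#' (uniform base, multiplied by `1 + telomere_weight` within the distal
#' `telomere_fraction` of each chromosome end, multiplied by
#' `centromere_factor` within `centromere_radius_bp` of the centromere,
#' renormalized) and then thinned so that no two chiasmata of one meiosis
#' lie closer than `interference_bp` (hard-core interference). Each chiasma
#' involves two of the four chromatids, so a transmitted gamete carries it
#' with probability 1/2.
#'
#' Defaults encode the study conditions of a stickleback-like
#' interspecific cross: males with exactly one obligate chiasma, strongly
#' telomere-concentrated and centromere-suppressed; females with an
#' obligate chiasma plus extras (rate 0.57, giving 0.785 expected observed
#' crossovers per chromosome per gamete) and only weak spatial effects.
#'
#' @param sex `"male"` or `"female"`.
#' @param obligate_co guarantee at least one chiasma per chromosome.
#' @param extra_co_rate Poisson mean of additional chiasmata.
#' @param telomere_fraction distal fraction of the chromosome (each end)
#'   receiving elevated density.
#' @param telomere_weight density within the distal region is multiplied
#'   by `1 + telomere_weight`.
#' @param centromere_radius_bp radius of centromeric suppression.
#' @param centromere_factor multiplier in `[0, 1]` applied within the
#'   radius; 0 means total suppression.
#' @param interference_bp hard-core minimum distance between chiasmata of
#'   one meiosis.
#' @return A list of class `meiosis_params`.
#' @export
meiosis_params <- function(sex,
                           obligate_co = TRUE,
                           extra_co_rate = if (sex == "male") 0 else 0.57,
                           telomere_fraction = if (sex == "male") 0.15 else 0.15,
                           telomere_weight = if (sex == "male") 6 else 0.5,
                           centromere_radius_bp = if (sex == "male") 5e6 else 1.5e6,
                           centromere_factor = if (sex == "male") 0.05 else 0.5,
                           interference_bp = 4e6) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(extra_co_rate >= 0, telomere_fraction >= 0,
            telomere_fraction <= 0.5, telomere_weight >= 0,
            centromere_factor >= 0, centromere_factor <= 1)
  structure(list(sex = sex, obligate_co = obligate_co,
                 extra_co_rate = extra_co_rate,
                 telomere_fraction = telomere_fraction,
                 telomere_weight = telomere_weight,
                 centromere_radius_bp = centromere_radius_bp,
                 centromere_factor = centromere_factor,
                 interference_bp = interference_bp),
            class = "meiosis_params")
}

# Piecewise-constant chiasma placement density on [0, L]: breakpoints and
# per-piece relative weight, renormalized to integrate to 1.
placement_density <- function(L, params, centromere_bp = NA) {
  tf <- params$telomere_fraction
  brk <- c(0, L)
  if (tf > 0) brk <- c(brk, tf * L, (1 - tf) * L)
  if (!is.na(centromere_bp) && params$centromere_radius_bp > 0)
    brk <- c(brk, max(0, centromere_bp - params$centromere_radius_bp),
             min(L, centromere_bp + params$centromere_radius_bp))
  brk <- sort(unique(pmin(pmax(brk, 0), L)))
  mid <- (head(brk, -1) + tail(brk, -1)) / 2
  w <- rep(1, length(mid))
  if (tf > 0)
    w <- w * ifelse(mid < tf * L | mid > (1 - tf) * L,
                    1 + params$telomere_weight, 1)
  if (!is.na(centromere_bp))
    w <- w * ifelse(abs(mid - centromere_bp) < params$centromere_radius_bp,
                    params$centromere_factor, 1)
  piece_mass <- w * diff(brk)
  if (sum(piece_mass) <= 0) {  # degenerate: fall back to uniform
    w <- rep(1, length(mid))
    piece_mass <- w * diff(brk)
  }
  list(breaks = brk, weight = w, mass = piece_mass / sum(piece_mass))
}

# inverse-CDF sampling from a piecewise-constant density
sample_density <- function(n, dens) {
  if (n == 0) return(numeric(0))
  piece <- sample.int(length(dens$mass), n, replace = TRUE,
                      prob = dens$mass)
  runif(n, dens$breaks[piece], dens$breaks[piece + 1])
}

# greedy hard-core thinning: keep each point (in random order of priority
# by sorted position) unless within min_d of an already-kept point
hardcore_thin <- function(pos, min_d) {
  pos <- sort(pos)
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= min_d) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  pos[keep]
}

#' Simulate chiasmata and one transmitted gamete for a single chromosome
#'
#' @param L chromosome length in bp.
#' @param params a [meiosis_params()] object.
#' @param centromere_bp centromere position (`NA` for none).
#' @return List with `chiasma_pos` (all chiasmata of the meiosis, after
#'   interference thinning) and `gamete_breaks` (the subset carried by the
#'   sampled gamete, each retained independently with probability 1/2).
#' @export
simulate_meiosis <- function(L, params, centromere_bp = NA) {
  n <- (if (params$obligate_co) 1L else 0L) + rpois(1, params$extra_co_rate)
  dens <- placement_density(L, params, centromere_bp)
  pos <- sample_density(n, dens)
  pos <- hardcore_thin(pos, params$interference_bp)
  kept <- pos[runif(length(pos)) < 0.5]
  list(chiasma_pos = sort(pos), gamete_breaks = sort(kept))
}

#' Simulate parental haplotypes over shared SNP positions
#'
#' SNP positions per chromosome follow a Poisson process with mean spacing
#' `snp_spacing_mean`. Each site is assigned a type: with probability
#' `informative_fraction / 2` it is father-informative (father
#' heterozygous, mother homozygous), with the same probability
#' mother-informative, otherwise uninformative (all four haplotypes carry
#' the reference allele).
#'
#' @param meta a [chrom_meta()] table.
#' @param snp_spacing_mean mean inter-SNP distance in bp.
#' @param informative_fraction fraction of sites informative for one
#'   parent, in `(0, 1]`.
#' @return Named list per chromosome: data.frame with `pos`, haplotype
#'   columns `f1`, `f2`, `m1`, `m2` (0/1 alleles).
#' @export
simulate_parental_haplotypes <- function(meta, snp_spacing_mean = 5000,
                                         informative_fraction = 1.0) {
  stopifnot(snp_spacing_mean > 0, informative_fraction > 0,
            informative_fraction <= 1)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    L <- meta$length_bp[i]
    n <- rpois(1, L / snp_spacing_mean)
    if (n == 0) stop("no SNPs simulated on ", meta$name[i])
    pos <- sort(sample.int(L, n))
    type <- sample(c("f", "m", "u"), n, replace = TRUE,
                   prob = c(informative_fraction / 2,
                            informative_fraction / 2,
                            1 - informative_fraction))
    flip <- runif(n) < 0.5          # which haplotype carries the alt allele
    hom_alt <- runif(n) < 0.5       # hom parent's allele at informative sites
    f1 <- integer(n); f2 <- integer(n); m1 <- integer(n); m2 <- integer(n)
    fi <- type == "f"
    f1[fi] <- as.integer(flip[fi]); f2[fi] <- as.integer(!flip[fi])
    m1[fi] <- m2[fi] <- as.integer(hom_alt[fi])
    mi <- type == "m"
    m1[mi] <- as.integer(flip[mi]); m2[mi] <- as.integer(!flip[mi])
    f1[mi] <- f2[mi] <- as.integer(hom_alt[mi])
    data.frame(pos = pos, f1 = f1, f2 = f2, m1 = m1, m2 = m2)
  })
  names(out) <- meta$name
  out
}

# gamete alleles along one chromosome: start on a random haplotype and
# switch at each breakpoint
gamete_from_breaks <- function(pos, hap1, hap2, breaks) {
  phase <- (findInterval(pos, breaks) + sample.int(2, 1)) %% 2 == 0
  ifelse(phase, hap1, hap2)
}

#' Simulate a set of quartets with crossover ground truth
#'
#' Generates parental haplotypes, simulates two independent meioses per
#' parent per quartet (one per offspring), assembles offspring genotypes,
#' perturbs them with genotyping error and missingness, and records the
#' ground truth needed to score downstream crossover calls.
#'
#' Maternal gametes are only generated for the first `n_mother_quartets`
#' quartets, emulating a design in which some mothers are excluded from
#' analysis; with the defaults (15 quartets, 12 mothers) the data contain
#' 30 male and 24 female meioses.
#'
#' Observable truth transitions for a sibling pair and parent are the
#' symmetric difference of the two gametes' breakpoint sets. Each is
#' flagged `detectable` unless it violates the end rule (within
#' `end_buffer` of a chromosome end) or the pair rule (within
#' `min_separation` of another transition of the same pair, parent and
#' chromosome).
#'
#' @param meta a [chrom_meta()] table.
#' @param n_quartets number of quartets (fathers contribute pairs from
#'   all of them).
#' @param n_mother_quartets quartets whose mother contributes a pair.
#' @param male_params,female_params [meiosis_params()] for each parent sex.
#' @param snp_spacing_mean,informative_fraction see
#'   [simulate_parental_haplotypes()].
#' @param error_rate per-genotype probability of a symmetric genotyping
#'   error (the genotype is replaced by one of the other two states).
#' @param missing_rate per-genotype probability of a missing call.
#' @param min_separation,end_buffer thresholds used for the truth
#'   detectability flags (must match the caller's configuration).
#' @param gq_clean,gq_error_max GQ assigned to clean genotypes and the
#'   upper bound of the uniform low GQ assigned to perturbed ones.
#' @return List with elements `quartets` (list of [variant_table()]s),
#'   `truth` (data.frame: quartet, parent, chrom, pos, detectable,
#'   fails_end_rule, fails_pair_rule), `chiasmata` (data.frame: quartet,
#'   parent, offspring, chrom, pos, in_gamete) and `meta`.
#' @export
simulate_quartets <- function(meta,
                              n_quartets = 15,
                              n_mother_quartets = 12,
                              male_params = meiosis_params("male"),
                              female_params = meiosis_params("female"),
                              snp_spacing_mean = 5000,
                              informative_fraction = 1.0,
                              error_rate = 1e-3,
                              missing_rate = 1e-3,
                              min_separation = 4e5,
                              end_buffer = 4e5,
                              gq_clean = 999L,
                              gq_error_max = 500L) {
  stopifnot(n_mother_quartets <= n_quartets)
  quartets <- vector("list", n_quartets)
  truth <- list(); chi <- list()

  for (q in seq_len(n_quartets)) {
    haps <- simulate_parental_haplotypes(meta, snp_spacing_mean,
                                         informative_fraction)
    has_mother <- q <= n_mother_quartets
    per_chr <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      h <- haps[[i]]
      L <- meta$length_bp[i]
      cen <- meta$centromere_bp[i]

      sim_pair <- function(params, hap1, hap2, parent) {
        g <- lapply(c("son", "daughter"), function(off) {
          m <- simulate_meiosis(L, params, cen)
          if (length(m$chiasma_pos) > 0)
            chi[[length(chi) + 1]] <<- data.frame(
              quartet = q, parent = parent, offspring = off,
              chrom = meta$name[i],
              pos = m$chiasma_pos,
              in_gamete = m$chiasma_pos %in% m$gamete_breaks)
          list(alleles = gamete_from_breaks(h$pos, hap1, hap2,
                                            m$gamete_breaks),
               breaks = m$gamete_breaks)
        })
        trans <- sym_diff(g[[1]]$breaks, g[[2]]$breaks)
        if (length(trans) > 0) {
          fe <- trans < end_buffer | trans > L - end_buffer
          fp <- close_pair_flag(trans, min_separation)
          truth[[length(truth) + 1]] <<- data.frame(
            quartet = q, parent = parent, chrom = meta$name[i],
            pos = trans, fails_end_rule = fe, fails_pair_rule = fp,
            detectable = !fe & !fp)
        }
        list(son = g[[1]]$alleles, daughter = g[[2]]$alleles)
      }

      pat <- sim_pair(male_params, h$f1, h$f2, "father")
      mat <- if (has_mother)
        sim_pair(female_params, h$m1, h$m2, "mother")
      else {
        # untracked filler meioses so offspring genotypes remain complete
        list(son = gamete_from_breaks(h$pos, h$m1, h$m2,
               simulate_meiosis(L, female_params, cen)$gamete_breaks),
             daughter = gamete_from_breaks(h$pos, h$m1, h$m2,
               simulate_meiosis(L, female_params, cen)$gamete_breaks))
      }

      per_chr[[i]] <- data.frame(
        chrom = meta$name[i], pos = h$pos,
        father_gt = h$f1 + h$f2, mother_gt = h$m1 + h$m2,
        son_gt = pat$son + mat$son,
        daughter_gt = pat$daughter + mat$daughter)
    }
    tab <- do.call(rbind, per_chr)
    quartets[[q]] <- perturb_genotypes(tab, error_rate, missing_rate,
                                       gq_clean, gq_error_max)
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(quartet = integer(0), parent = character(0),
               chrom = character(0), pos = numeric(0),
               fails_end_rule = logical(0), fails_pair_rule = logical(0),
               detectable = logical(0))
  chi <- if (length(chi)) do.call(rbind, chi) else NULL
  list(quartets = quartets, truth = truth, chiasmata = chi, meta = meta)
}

sym_diff <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))

# TRUE for transitions with a neighbour closer than min_d
close_pair_flag <- function(pos, min_d) {
  if (length(pos) < 2) return(rep(FALSE, length(pos)))
  d_prev <- c(Inf, diff(pos))
  d_next <- c(diff(pos), Inf)
  d_prev < min_d | d_next < min_d
}

# apply symmetric genotype errors + missingness, assign GQ, build the
# variant_table (ref/alt fixed A/T: allele identities are immaterial here)
perturb_genotypes <- function(tab, error_rate, missing_rate,
                              gq_clean, gq_error_max) {
  n <- nrow(tab)
  cols <- paste0(quartet_roles, "_gt")
  gq <- matrix(gq_clean, n, 4)
  for (j in seq_along(cols)) {
    g <- tab[[cols[j]]]
    err <- runif(n) < error_rate
    if (any(err)) {
      shift <- sample.int(2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift[seq_len(sum(err))]) %% 3L
      gq[err, j] <- sample.int(gq_error_max, sum(err), replace = TRUE)
    }
    g[runif(n) < missing_rate] <- NA_integer_
    tab[[cols[j]]] <- g
  }
  variant_table(tab$chrom, tab$pos, "A", "T",
                tab$father_gt, tab$mother_gt, tab$son_gt, tab$daughter_gt,
                gq[, 1], gq[, 2], gq[, 3], gq[, 4])
}

#' Write a simulated quartet set to disk
#'
#' Emits one VCF per quartet plus the truth table and chromosome metadata
#' as TSV.
#'
#' @param sim result of [simulate_quartets()].
#' @param dir output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcfs <- vapply(seq_along(sim$quartets), function(q) {
    p <- file.path(dir, sprintf("quartet%02d.vcf", q))
    write_quartet_vcf(sim$quartets[[q]], p, meta = sim$meta)
    p
  }, character(1))
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta_path <- file.path(dir, "chrom_meta.tsv")
  write_chrom_meta(sim$meta, meta_path)
  invisible(list(vcf = vcfs, truth = truth_path, meta = meta_path))
}
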