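test_that("hotspot fraction counts multi-crossover windows", {
  co <- data.frame(chrom = "c", midpoint = c(5e4, 6e4, 4.5e5))
  expect_equal(hotspot_fraction(co, 1e5), 2 / 3)
  co2 <- data.frame(chrom = "c", midpoint = c(5e4, 2.5e5, 4.5e5))
  expect_equal(hotspot_fraction(co2, 1e5), 0)
  expect_equal(hotspot_fraction(co[1, , drop = FALSE], 1e5), 0)
  # invariant to row order and chromosome interleaving
  co3 <- data.frame(chrom = c("a", "b", "a", "b"),
                    midpoint = c(1e4, 1e4, 2e4, 9e5))
  expect_equal(hotspot_fraction(co3, 1e5),
               hotspot_fraction(co3[sample(4), ], 1e5))
})

test_that("hotspot permutation matches the analytic two-crossover null", {
  set.seed(71)
  meta <- chrom_meta("c", 2e5)
  co <- data.frame(chrom = "c", parent_sex = "male", parent_id = "f",
                   pair_id = "p", left = c(5e4, 6e4), right = c(5e4, 6e4),
                   midpoint = c(5e4, 6e4), resolution = 0,
                   status = "validated")
  res <- hotspot_permutation(co, meta, 1e5, n_sims = 10000)
  # two points uniform on [0, 200 kb]: P(same 100-kb window) = 1/2
  expect_equal(mean(res$null == 1), 0.5, tolerance = 0.02)
  expect_equal(res$observed, 1)
  # observed fraction 0 -> p = 1 within resolution
  co0 <- co; co0$midpoint <- c(5e4, 1.5e5)
  res0 <- hotspot_permutation(co0, meta, 1e5, n_sims = 500)
  expect_gte(res0$p_value, 0.4)
  # fixed seed reproduces the null exactly
  set.seed(5); a <- hotspot_permutation(co, meta, 1e5, n_sims = 200)
  set.seed(5); b <- hotspot_permutation(co, meta, 1e5, n_sims = 200)
  expect_identical(a$null, b$null)
  expect_error(hotspot_permutation(
    data.frame(chrom = "c", midpoint = 1e5, left = 0, right = 3e5,
               resolution = 3e5, status = "validated"),
    meta, 1e5, 10), "longer")
})

test_that("identity placement reproduces the observed statistic", {
  co <- data.frame(chrom = "c", midpoint = c(5e4, 6e4, 4.5e5))
  # a null draw placed exactly where the observations are equals observed
  expect_equal(hotspot_fraction(co, 1e5), 2 / 3)
})

test_that("permutation p-values are uniform on their grid under the null", {
  set.seed(81)
  meta <- chrom_meta("c", 1e7)
  ps <- replicate(200, {
    co <- data.frame(chrom = "c", parent_sex = "m", parent_id = "f",
                     pair_id = "p",
                     midpoint = runif(20, 0, 1e7), resolution = 0,
                     status = "validated")
    co$left <- co$midpoint; co$right <- co$midpoint
    hotspot_permutation(co, meta, 1e5, n_sims = 99)$p_value
  })
  # the hotspot fraction is discrete with heavy ties, so the add-one
  # Monte-Carlo p-value is super-uniform: P(p <= t) <= t (plus grid
  # slack), never anti-conservative
  for (t in c(0.1, 0.25, 0.5))
    expect_lte(mean(ps <= t), t + 0.05)
  # and it is not degenerate: small p-values do occur at their rate
  expect_gt(mean(ps <= 0.5), 0.1)
  expect_gt(mean(ps > 0.9), 0.05)
})

test_that("promoters are derived strand-aware and features overlap correctly", {
  meta <- chrom_meta("c", 1e5)
  gr <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(10001, 50001), c(20000, 60000)),
    strand = c("-", "+"))
  gr$type <- "gene"
  pr <- feature_ranges(gr, "promoter", meta)
  # minus-strand gene [10001, 20000]: promoter is the 2 kb after its end
  expect_equal(GenomicRanges::start(pr)[1], 20001)
  expect_equal(GenomicRanges::end(pr)[1], 22000)
  # plus-strand gene: 2 kb before its start
  expect_equal(GenomicRanges::start(pr)[2], 48001)
  expect_equal(GenomicRanges::end(pr)[2], 50000)
  # interval overlap is any-shared-base
  co <- data.frame(chrom = "c", left = 100, right = 200,
                   parent_sex = "male", status = "validated")
  gene <- GenomicRanges::GRanges("c", IRanges::IRanges(150, 500))
  gene$type <- "gene"
  res <- feature_overlap_permutation(co, gene, "gene", meta, n_sims = 50)
  expect_equal(res$observed, 1)
})

test_that("genome-wide features give observed fraction 1 and p = 1", {
  set.seed(91)
  meta <- chrom_meta("c", 1e6)
  gene <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1e6))
  gene$type <- "gene"
  co <- data.frame(chrom = "c", left = c(1e5, 5e5), right = c(1.1e5, 5.1e5),
                   parent_sex = "male", status = "validated")
  res <- feature_overlap_permutation(co, gene, "gene", meta, n_sims = 200)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1)
})

test_that("GC content handles N bases and detects planted enrichment", {
  s <- Biostrings::DNAStringSet(c(c1 = "GGCC", c2 = "ATAT", c3 = "ACGTN"))
  expect_equal(meiomap:::gc_of(s[["c1"]]), 1)
  expect_equal(meiomap:::gc_of(s[["c2"]]), 0)
  expect_equal(meiomap:::gc_of(s[["c3"]]), 0.5)

  set.seed(101)
  hits <- replicate(40, {
    # 200-kb chromosome, GC 40% background, 42% inside the two planted
    # crossover intervals
    L <- 2e5
    base <- sample(c("A", "T", "G", "C"), L, TRUE,
                   prob = c(0.3, 0.3, 0.2, 0.2))
    iv <- rbind(c(50001, 60000), c(120001, 130000))
    for (r in 1:2) {
      idx <- iv[r, 1]:iv[r, 2]
      base[idx] <- sample(c("A", "T", "G", "C"), length(idx), TRUE,
                          prob = c(0.27, 0.27, 0.23, 0.23))
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""),
                                                "c"))
    co <- data.frame(chrom = "c", parent_sex = rep("male", 2),
                     left = iv[, 1], right = iv[, 2],
                     status = "validated")
    res <- gc_analysis(co, genome, flank_bp = 3e4)
    # paired comparison: both intervals above their flanks
    all(res$per_interval$gc_interval > res$per_interval$gc_flank)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("flank GC pools both sides and truncates at chromosome ends", {
  genome <- Biostrings::DNAStringSet(setNames(
    paste(rep(c("G", "A"), times = c(100, 100)), collapse = ""), "c"))
  # interval [1, 50]: no left flank; right flank = [51, 100] all G with
  # flank_bp 50
  co <- data.frame(chrom = "c", parent_sex = "male", left = 1, right = 50,
                   status = "validated")
  res <- gc_analysis(co, genome, flank_bp = 50)
  expect_equal(res$per_interval$gc_interval, 1)
  expect_equal(res$per_interval$gc_flank, 1)
  # with flank_bp 100 the right flank spills into the A half
  res2 <- gc_analysis(co, genome, flank_bp = 100)
  expect_equal(res2$per_interval$gc_flank, 0.5)
})
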