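test_that("map length follows the centimorgan definition", {
  expect_equal(map_length_cM(302, 30), 1006.6667, tolerance = 1e-6)
  expect_equal(map_length_cM(396, 24), 1650)
  expect_equal(map_length_cM(0, 30), 0)
  expect_error(map_length_cM(1, 0), "positive")
})

test_that("per-chromosome table reproduces the published map statistics", {
  counts <- stickleback_co_counts()
  tab <- per_chromosome_table(counts, c(male = 30, female = 24),
                              counts$chrom)
  tot <- tab[tab$chrom == "Total", ]
  expect_equal(tot$length_female, 1650)
  expect_equal(tot$length_male, 1006.7, tolerance = 1e-4)
  expect_equal(round(tot$ratio_fm, 2), 1.64)
  expect_equal(round(tab$ratio_fm[tab$chrom == "18"], 2), 5.31)
  expect_equal(round(tab$ratio_fm[tab$chrom == "7"], 2), 1.05)
  expect_equal(round(attr(tab, "pearson_r"), 2), 0.67)
  expect_equal(round(attr(tab, "cos_per_chrom")[["male"]], 2), 0.48)
  expect_equal(round(attr(tab, "cos_per_chrom")[["female"]], 2), 0.79)
})

test_that("equal counts give unit ratios and the documented r convention", {
  counts <- data.frame(chrom = c("a", "b"), count_female = c(10, 20),
                       count_male = c(10, 20))
  tab <- per_chromosome_table(counts, c(male = 10, female = 10),
                              c("a", "b"))
  expect_true(all(tab$ratio_fm == 1))
  expect_equal(attr(tab, "pearson_r"), 1)
  # constant equal columns: r = 1 by convention
  counts2 <- data.frame(chrom = c("a", "b"), count_female = c(5, 5),
                        count_male = c(5, 5))
  tab2 <- per_chromosome_table(counts2, c(male = 10, female = 10),
                               c("a", "b"))
  expect_equal(attr(tab2, "pearson_r"), 1)
})

test_that("obligate-crossover tail probability is the exact binomial sum", {
  # closed form: sum_{k<=4} C(30,k) / 2^30
  want <- sum(choose(30, 0:4)) / 2^30
  expect_equal(obligate_co_probability(4, 30), want, tolerance = 1e-12)
  expect_equal(obligate_co_probability(30, 30), 1)
  expect_equal(obligate_co_probability(0, 1), 0.5)
})

test_that("CV equality test computes CVs and calibrates near alpha", {
  expect_equal(cv_equality_test(c(10, 10, 10), c(9, 9, 11))$cv_female, 0)
  r <- cv_equality_test(c(10, 10, 12, 12), c(10, 10, 12, 12))
  expect_equal(r$cv_female, sqrt(4 / 3) / 11, tolerance = 1e-9)
  expect_equal(r$p_value, 1)
  expect_error(cv_equality_test(c(0, 0), c(1, 2)), "zero mean")

  set.seed(77)
  rej <- mean(replicate(1000, {
    a <- rpois(15, 12); b <- rpois(15, 12)
    if (mean(a) == 0 || mean(b) == 0) return(FALSE)
    cv_equality_test(a, b)$p_value < 0.05
  }))
  # asymptotic test at small n: near-nominal size (3 sigma band around
  # 0.05 at 1000 replicates is about +/- 0.021)
  expect_true(abs(rej - 0.05) < 0.035)
})

test_that("folded coordinates and binning obey the tie rule", {
  expect_equal(folded_coordinate(18e6, 20e6), 0.2)
  expect_equal(folded_coordinate(10e6, 20e6), 1)
  meta <- chrom_meta("c", 2e7, 5e6, FALSE)
  co <- data.frame(chrom = "c", parent_sex = "male", parent_id = "f",
                   pair_id = "p", midpoint = c(18e6, 10e6, 1e6),
                   left = 0, right = 0, resolution = 0,
                   status = "validated")
  seg <- fold_and_bin(co, meta, 5)
  expect_equal(sum(seg$relative_length), 1)
  # midpoint at the exact centre lands in the last segment
  expect_equal(seg$count[seg$segment == 5], 1)
  # folded 0.1 -> segment 1, folded 0.2 -> segment 2 (floor boundary)
  expect_equal(seg$count[seg$segment == 1], 1)
  expect_equal(seg$count[seg$segment == 2], 1)
})

test_that("uniform crossovers give near-uniform segment shares", {
  set.seed(88)
  meta <- chrom_meta("c", 2e7, NA, FALSE)
  n <- 2000
  co <- data.frame(chrom = "c", parent_sex = "male", parent_id = "f",
                   pair_id = "p", midpoint = runif(n, 0, 2e7),
                   left = 0, right = 0, resolution = 0,
                   status = "validated")
  for (ns in c(2, 10, 20)) {
    seg <- fold_and_bin(co, meta, ns)
    # multinomial 3-sigma band on each share
    sd_share <- sqrt((1 / ns) * (1 - 1 / ns) / n)
    expect_true(all(abs(seg$relative_length - 1 / ns) < 4 * sd_share),
                info = ns)
  }
})

test_that("segment correlation hits the +/-1 anchors", {
  a <- data.frame(sex = "female", chrom = "c", segment = 1:2,
                  count = c(9, 1), relative_length = c(0.9, 0.1))
  b <- a; b$sex <- "male"
  expect_equal(sex_segment_correlation(a, b)$r, NA_real_)  # n < 3 cells
  a2 <- data.frame(sex = "female", chrom = rep(c("c", "d"), each = 2),
                   segment = rep(1:2, 2),
                   relative_length = c(0.9, 0.1, 0.8, 0.2))
  b2 <- a2; b2$sex <- "male"
  expect_equal(sex_segment_correlation(a2, b2)$r, 1)
  b3 <- a2; b3$relative_length <- 1 - a2$relative_length
  expect_equal(sex_segment_correlation(a2, b3)$r, -1)
})

test_that("shared telomere effects give positive sex correlations", {
  set.seed(99)
  meta <- tiny_meta(6, len = 2e7, cen = 5e6)
  hits <- replicate(40, {
    sim_co <- function(sex, n) {
      # distal-biased placement for both sexes
      m <- ifelse(runif(n) < 0.6, runif(n, 0, 3e6), runif(n, 0, 2e7))
      m <- ifelse(runif(n) < 0.5, m, 2e7 - m)
      data.frame(chrom = sample(meta$name, n, TRUE), parent_sex = sex,
                 parent_id = "x", pair_id = "p", midpoint = m,
                 left = 0, right = 0, resolution = 0,
                 status = "validated")
    }
    seg <- fold_and_bin(rbind(sim_co("male", 300), sim_co("female", 300)),
                        meta, 2)
    r <- sex_segment_correlation(seg[seg$sex == "female", ],
                                 seg[seg$sex == "male", ])$r
    r > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("arm rates and the short-arm deficit chi-square behave", {
  meta <- chrom_meta("c", 2e7, 5e6, FALSE)  # short arm 25% of chromosome
  # all crossovers on the long arm: chi-square = n/3 in closed form
  n <- 30
  co <- data.frame(chrom = "c", parent_sex = "male", parent_id = "f",
                   pair_id = "p", midpoint = runif(n, 6e6, 19e6),
                   left = 0, right = 0, resolution = 0,
                   status = "validated")
  res <- arm_rates(co, meta)
  expect_equal(res$deficit_test$chisq, n / 3, tolerance = 1e-9)
  expect_equal(res$arms$n_cos[res$arms$arm == "short"], 0)
  # proportional counts: chi-square exactly 0
  co2 <- data.frame(chrom = "c", parent_sex = "male", parent_id = "f",
                    pair_id = "p",
                    midpoint = c(runif(10, 0, 5e6), runif(30, 5e6, 2e7)),
                    left = 0, right = 0, resolution = 0,
                    status = "validated")
  res2 <- arm_rates(co2, meta)
  expect_equal(res2$deficit_test$chisq, 0, tolerance = 1e-9)
  # no crossovers: skipped with a warning
  co0 <- co[0, ]
  expect_warning(r0 <- arm_rates(co0, meta), "skipped")
  expect_null(r0$deficit_test)
})
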