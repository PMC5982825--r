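test_that("sharing track is the sibling XOR", {
  pair <- data.frame(pos = c(10, 20, 30, 40),
                     allele_son = c(0, 0, 1, 1),
                     allele_daughter = c(0, 1, 1, 0))
  expect_equal(sharing_track(pair)$share, c(0, 1, 0, 1))
  pair$allele_daughter <- pair$allele_son
  expect_equal(sharing_track(pair)$share, rep(0, 4))
})

test_that("changepoint detection finds clean transitions and no spurious ones", {
  # constant track
  t0 <- data.frame(pos = seq_len(100) * 1e4, share = rep(0, 100))
  expect_length(detect_changepoints(t0), 0)
  # clean block transition at the midpoint
  t1 <- data.frame(pos = seq_len(200) * 1e4, share = rep(0:1, each = 100))
  expect_equal(detect_changepoints(t1), 100L)
  # one isolated flip inside the first block: still a single boundary at
  # the block edge under the log(n) penalty
  x <- c(rep(0, 100), rep(1, 100)); x[50] <- 1
  t2 <- data.frame(pos = seq_len(200) * 1e4, share = x)
  cand <- detect_changepoints(t2)
  expect_true(100 %in% cand)
  kept <- validate_crossovers(cand, t2)
  expect_equal(kept, 100L, ignore_attr = TRUE)
})

test_that("exact segmentation matches the unpruned dynamic program", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    x <- rbinom(n, 1, runif(1))
    track <- data.frame(pos = cumsum(sample(1e3:1e4, n, TRUE)), share = x)
    got <- detect_changepoints(track)
    want <- dp_changepoints(x, 3 * log(n))
    pen <- 3 * log(n)
    expect_equal(total_cost(x, got, pen), total_cost(x, want, pen),
                 tolerance = 1e-10)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("window validation enforces the 0.1/0.9 sharing switch", {
  # clean 0 -> 1 transition, dense sites
  t1 <- data.frame(pos = seq_len(40) * 1e4, share = rep(0:1, each = 20))
  expect_equal(validate_crossovers(20L, t1), 20L, ignore_attr = TRUE)
  # oscillating region: means near 0.5 on both sides
  t2 <- data.frame(pos = seq_len(40) * 1e4, share = rep(c(0, 1), 20))
  out <- validate_crossovers(20L, t2)
  expect_length(out, 0)
  expect_equal(attr(out, "rejected")$reason, "ambiguous_sharing")
  # 5% flips around a true transition still pass
  set.seed(3)
  x <- rep(0:1, each = 50)
  flip <- runif(100) < 0.05
  x[flip] <- 1 - x[flip]
  t3 <- data.frame(pos = seq_len(100) * 2e3, share = x)
  expect_true(50L %in% validate_crossovers(50L, t3))
})

test_that("pair and end rules remove crossovers as specified", {
  meta <- chrom_meta("chr01", 2e7, 5e6, FALSE)
  co <- data.frame(chrom = "chr01", parent_sex = "male",
                   parent_id = "father01", pair_id = "pair01",
                   left = c(0.95e6, 1.25e6, 9.9e6, 1.5e5),
                   right = c(1.05e6, 1.35e6, 10.1e6, 2.5e5),
                   midpoint = c(1.0e6, 1.3e6, 10e6, 2e5),
                   resolution = 1e5, status = "validated")
  out <- filter_crossovers(co, meta)
  expect_equal(out$status,
               c("removed_pair_rule", "removed_pair_rule", "validated",
                 "removed_end_rule"))
})

test_that("detection is symmetric in the two siblings", {
  set.seed(404)
  meta <- tiny_meta(2, len = 1e7, cen = 3e6)
  sim <- simulate_quartets(meta, n_quartets = 1, n_mother_quartets = 1,
                           snp_spacing_mean = 1e4)
  ph <- phase_quartet(sim$quartets[[1]])
  swapped <- ph
  swapped$allele_son <- ph$allele_daughter
  swapped$allele_daughter <- ph$allele_son
  for (pp in split(ph, list(ph$parent, ph$chrom), drop = TRUE)) {
    sw <- pp
    sw$allele_son <- pp$allele_daughter
    sw$allele_daughter <- pp$allele_son
    expect_identical(call_pair_chromosome(pp), call_pair_chromosome(sw))
  }
})

test_that("caller recovers simulated crossovers with accurate intervals", {
  set.seed(505)
  meta <- tiny_meta(4, len = 2e7, cen = 5e6)
  sim <- simulate_quartets(meta, n_quartets = 4, n_mother_quartets = 3)
  cos <- call_crossovers(sim$quartets, meta,
                         mother_included = c(TRUE, TRUE, TRUE, FALSE))
  truth <- sim$truth[!(sim$truth$parent == "mother" &
                         sim$truth$quartet == 4), ]
  expect_gte(truth_recovery(truth, cos), 0.9)
  expect_gte(call_containment(truth, cos), 0.9)
  # interval flanks are genuine informative-site positions
  kept <- retained_crossovers(cos)
  ph <- phase_quartet(sim$quartets[[1]])
  q1 <- kept[kept$pair_id == "pair01", ]
  sites <- paste(ph$parent, ph$chrom, ph$pos)
  par_of <- ifelse(q1$parent_sex == "male", "father", "mother")
  expect_true(all(paste(par_of, q1$chrom, q1$left) %in% sites))
  expect_true(all(paste(par_of, q1$chrom, q1$right) %in% sites))
})

test_that("degenerate zero-crossover input yields an empty table", {
  set.seed(606)
  meta <- tiny_meta(1, len = 5e6)
  none <- meiosis_params("male", obligate_co = FALSE, extra_co_rate = 0)
  sim <- simulate_quartets(meta, n_quartets = 1, n_mother_quartets = 1,
                           male_params = none, female_params = none,
                           snp_spacing_mean = 5e4)
  cos <- call_crossovers(sim$quartets, meta)
  expect_equal(nrow(cos), 0)
})

test_that("three crossovers in one pair imply a double-crossover gamete", {
  meta <- chrom_meta("chr01", 3e7, 5e6, FALSE)
  co <- data.frame(chrom = "chr01", parent_sex = "female",
                   parent_id = "mother01", pair_id = "pair01",
                   left = c(5e6, 12e6, 20e6), right = c(5.1e6, 12.1e6, 20.1e6),
                   midpoint = c(5.05e6, 12.05e6, 20.05e6),
                   resolution = 1e5, status = "validated")
  out <- filter_crossovers(co, meta)
  out$implies_double_co <- meiomap:::flag_double_co(out)
  expect_true(all(out$implies_double_co))
})
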