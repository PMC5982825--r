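# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# --- transmission phasing: brute-force enumeration over allele assignments
alleles_of <- function(gt) switch(gt + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

oracle_phase <- function(f, m, o) {
  sols <- list()
  for (p in 0:1) for (q in 0:1) {
    if (p %in% alleles_of(f) && q %in% alleles_of(m) && p + q == o)
      sols[[length(sols) + 1]] <- c(p, q)
  }
  if (length(sols) == 0) return(list(status = "violation"))
  if (length(sols) > 1) return(list(status = "undetermined"))
  list(status = "determined", paternal = sols[[1]][1],
       maternal = sols[[1]][2])
}

# --- changepoints: Bernoulli segment cost (negated max log-likelihood)
bern_cost <- function(x) {
  n <- length(x); s1 <- sum(x); s0 <- n - s1
  c <- 0
  if (s1 > 0) c <- c - s1 * log(s1 / n)
  if (s0 > 0) c <- c - s0 * log(s0 / n)
  c
}

total_cost <- function(x, cps, penalty) {
  bounds <- c(0, cps, length(x))
  segs <- Map(function(a, b) x[(a + 1):b], head(bounds, -1),
              tail(bounds, -1))
  sum(vapply(segs, bern_cost, numeric(1))) + penalty * length(cps)
}

# unpruned O(n^2) optimal-partitioning dynamic program (ties -> smallest
# last changepoint, matching the engine's first-minimum rule)
dp_changepoints <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  F <- c(-penalty, rep(Inf, n))
  last <- integer(n + 1)
  for (t in seq_len(n)) {
    vals <- vapply(0:(t - 1), function(tau)
      F[tau + 1] + bern_cost(x[(tau + 1):t]) + penalty, numeric(1))
    F[t + 1] <- min(vals)
    last[t + 1] <- which.min(vals) - 1L
  }
  cps <- integer(0); t <- n
  while (t > 0) {
    tau <- last[t + 1]
    if (tau > 0) cps <- c(tau, cps)
    t <- tau
  }
  cps
}

# full enumeration over all 2^(n-1) changepoint subsets (n small)
enum_changepoints <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  best <- NULL; best_cost <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    cost <- total_cost(x, cps, penalty)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost; best <- cps
    }
  }
  list(cps = best, cost = best_cost)
}

# --- truth scoring for simulations
# fraction of detectable truth transitions matched by a retained call of
# the same quartet/parent/chromosome whose interval (+slack) contains them
truth_recovery <- function(truth, cos, slack = 5e4) {
  kept <- cos[cos$status == "validated", , drop = FALSE]
  det <- truth[truth$detectable, , drop = FALSE]
  if (nrow(det) == 0) return(NA_real_)
  hit <- mapply(function(p, ch, par, q) {
    sel <- kept$chrom == ch &
      kept$parent_id == sprintf("%s%02d", par, q)
    any(kept$left[sel] - slack <= p & kept$right[sel] + slack >= p)
  }, det$pos, det$chrom, det$parent, det$quartet)
  mean(hit)
}

# fraction of retained calls whose interval contains a truth transition of
# the same quartet/parent/chromosome (detectable or not)
call_containment <- function(truth, cos) {
  kept <- cos[cos$status == "validated", , drop = FALSE]
  if (nrow(kept) == 0) return(NA_real_)
  pid <- sprintf("%s%02d", truth$parent, truth$quartet)
  hit <- mapply(function(l, r, ch, id) {
    sel <- truth$chrom == ch & pid == id
    any(truth$pos[sel] >= l & truth$pos[sel] <= r)
  }, kept$left, kept$right, kept$chrom, kept$parent_id)
  mean(hit)
}

# small deterministic karyotype for fast tests
tiny_meta <- function(n = 3, len = 2e7, cen = min(5e6, len / 4)) {
  chrom_meta(sprintf("chr%02d", seq_len(n)), rep(len, n), rep(cen, n),
             rep(FALSE, n))
}
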