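# shared fixture: intact elite chromosome paired with the RP haplotype
lmc_fixture <- function(L = 20L, D = c(5L, 10L, 15L)) {
  rp_hap <- rep(1L, L); rp_hap[D] <- 0L
  list(G = genotype(rep(1L, L), rp_hap),
       rp = genotype(rp_hap, rp_hap),
       r = rep(0, L - 1), D = D)
}

test_that("non-positive candidates score zero and cannot start a path", {
  fx <- lmc_fixture()
  cfg <- lookahead_config(T = 3)
  bad <- fx$G; bad[fx$D[1], ] <- 0L
  expect_identical(lmc_score(bad, fx$rp, fx$r, 1, cfg, fx$D, seed = 1), 0)
  expect_error(simulate_lookahead_path(bad, fx$rp, fx$r, 1, cfg, fx$D, 1),
               "not positive")
})

test_that("paths fail when no positive gamete is possible", {
  # targets in repulsion on a non-recombining chromosome: positive at the
  # backcross stage, yet no single gamete can carry both targets
  D <- c(2L, 3L)
  G <- genotype(c(1, 1, 0, 1, 1, 1), c(1, 0, 1, 1, 1, 1))
  rp <- genotype(c(1, 0, 0, 1, 1, 1), c(1, 0, 0, 1, 1, 1))
  r <- rep(0, 5)
  cfg <- lookahead_config(T = 3, attempt_cap = 50)
  expect_true(is_positive(G, D, "backcross"))
  po <- simulate_lookahead_path(G, rp, r, 1, cfg, D, seed = 4)
  expect_true(po$failed)
  expect_identical(po$n, 0L)
  expect_identical(lmc_score(G, rp, r, 1, cfg, D, seed = 4), 0)
})

test_that("a fully elite homozygote scores Q = 100 at the terminal generation", {
  L <- 12L; D <- c(3L, 7L)
  rp_hap <- rep(1L, L); rp_hap[D] <- 0L
  G <- matrix(1L, L, 2)
  rp <- genotype(rp_hap, rp_hap)
  cfg <- lookahead_config(P = 1, K = 50, threshold = 95, T = 3)
  # t = T: no backcross steps remain, the candidate is selfed directly and
  # every progeny is the elite homozygote (n = K, v = 100)
  expect_identical(lmc_score(G, rp, rep(0, L - 1), 3, cfg, D, seed = 2), 100)
})

test_that("the no-recombination construction converges to Q = 25", {
  fx <- lmc_fixture()
  cfg <- lookahead_config(P = 200, K = 200, threshold = 95, T = 3)
  q <- lmc_score(fx$G, fx$rp, fx$r, 1, cfg, fx$D, seed = 31)
  # per path (n/K) v has mean 25 and sd ~3.06; over P = 200, 3 sigma = 0.65
  expect_lt(abs(q - 25), 0.65)
  po <- simulate_lookahead_path(fx$G, fx$rp, fx$r, 3, cfg, fx$D, seed = 31)
  expect_false(po$failed)
  expect_identical(po$v, 100)
  expect_lt(abs(po$n / cfg$K - 0.25), 3 * sqrt(0.25 * 0.75 / cfg$K))
})

test_that("Q is unbiased in P: only the variance shrinks", {
  fx <- lmc_fixture(L = 12L, D = c(4L, 8L))
  mean_q <- function(P, seeds) {
    cfg <- lookahead_config(P = P, K = 50, threshold = 95, T = 3)
    mean(vapply(seeds, function(s) {
      lmc_score(fx$G, fx$rp, fx$r, 1, cfg, fx$D, seed = s)
    }, numeric(1)))
  }
  m10 <- mean_q(10, 1:40)
  m100 <- mean_q(100, 101:140)
  # both estimate E[(n/K) v] = 25; sd of each mean is well under 1
  expect_lt(abs(m10 - m100), 3)
})

test_that("allele-wise dominance implies no worse expected Q", {
  set.seed(14)
  L <- 30L; D <- c(8L, 15L, 22L)
  rp_hap <- rep(1L, L); rp_hap[D] <- 0L
  rp <- genotype(rp_hap, rp_hap)
  lo_hap <- rep(0L, L); lo_hap[D] <- 1L
  lo_hap[seq(1, L, by = 2)] <- 1L
  hi_hap <- lo_hap; hi_hap[lo_hap == 0L] <- 1L   # weakly dominates lo
  r <- rep(0.05, L - 1)
  cfg <- lookahead_config(P = 60, K = 100, threshold = 90, T = 3)
  q_lo <- mean(vapply(1:8, function(s) {
    lmc_score(genotype(lo_hap, rp_hap), rp, r, 2, cfg, D, seed = s)
  }, numeric(1)))
  q_hi <- mean(vapply(1:8, function(s) {
    lmc_score(genotype(hi_hap, rp_hap), rp, r, 2, cfg, D, seed = 100 + s)
  }, numeric(1)))
  expect_gte(q_hi, q_lo)
})

test_that("Q is bounded and reproducible", {
  fx <- lmc_fixture()
  cfg <- lookahead_config(P = 20, T = 3)
  q1 <- lmc_score(fx$G, fx$rp, fx$r, 2, cfg, fx$D, seed = 77)
  q2 <- lmc_score(fx$G, fx$rp, fx$r, 2, cfg, fx$D, seed = 77)
  expect_identical(q1, q2)
  expect_gte(q1, 0)
  expect_lte(q1, 100)
  expect_error(lmc_score(fx$G, fx$rp, fx$r, 4, cfg, fx$D, seed = 1),
               "terminal")
})

test_that("look-ahead configuration is validated", {
  expect_error(lookahead_config(P = 0), ">= 1")
  expect_error(lookahead_config(threshold = 0), "threshold")
  expect_error(lookahead_config(threshold = 101), "threshold")
})
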