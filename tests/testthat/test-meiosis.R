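test_that("inheritance paths follow the two-state Markov chain", {
  set.seed(1)
  # no recombination: the path is constant, each copy with probability 1/2
  paths <- replicate(2000, sample_inheritance(rep(0, 4)))
  expect_true(all(apply(paths, 2, function(p) length(unique(p)) == 1L)))
  frac1 <- mean(paths[1, ] == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / 2000))

  # free recombination: adjacent sources are independent
  paths <- replicate(5000, sample_inheritance(rep(0.5, 2)))
  sw <- mean(paths[1, ] != paths[2, ])
  expect_lt(abs(sw - 0.5), 3 * sqrt(0.25 / 5000))

  # chain rule: P(path = (1, 2)) = 0.5 * 0.1 with r = 0.1
  n <- 1e5
  paths <- replicate(n, sample_inheritance(0.1))
  p12 <- mean(paths[1, ] == 1L & paths[2, ] == 2L)
  expect_lt(abs(p12 - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("gametes read alleles along the inheritance path", {
  set.seed(2)
  hom <- genotype(c(1, 0, 1, 1), c(1, 0, 1, 1))
  r <- c(0.2, 0.3, 0.1)
  for (i in 1:10) expect_identical(sample_gamete(hom, r), hom[, 1L])

  # with r = 0 the gamete is one intact column, each at frequency 1/2
  G <- genotype(c(1, 1, 1), c(0, 0, 0))
  n <- 1e4
  draws <- replicate(n, sample_gamete(G, c(0, 0))[1])
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / n))

  # a heterozygous locus transmits its desirable allele at frequency 1/2
  G2 <- genotype(c(1, 1, 0), c(0, 1, 1))
  draws <- replicate(n, sample_gamete(G2, c(0.37, 0.11))[1])
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("gamete_probability matches hand-derived and enumerated values", {
  G <- genotype(c(1, 1, 0), c(0, 1, 1))
  r <- c(0.1, 0.2)
  # consistent paths 112 (0.5*0.9*0.2) and 122 (0.5*0.1*0.8)
  expect_equal(gamete_probability(G, r, c(1, 1, 1)), 0.13)
  expect_equal(gamete_probability(G, r, c(1, 1, 1), "enumerate"), 0.13)

  hom <- genotype(c(1, 0, 1), c(1, 0, 1))
  expect_equal(gamete_probability(hom, r, c(1, 0, 1)), 1)
  expect_equal(gamete_probability(hom, r, c(1, 1, 1)), 0)  # impossible allele
})

test_that("forward recursion agrees with the independent path enumeration", {
  set.seed(3)
  for (i in 1:25) {
    L <- sample(2:7, 1)
    G <- rand_genotype(L)
    r <- rand_recomb(L)
    g <- as.integer(stats::rbinom(L, 1, 0.5))
    expect_equal(gamete_probability(G, r, g), oracle_gamete_prob(G, r, g),
                 tolerance = 1e-14)
  }
})

test_that("gamete probabilities sum to one over all haplotypes", {
  set.seed(4)
  for (L in c(3L, 6L, 10L, 12L)) {
    G <- rand_genotype(L)
    r <- rand_recomb(L)
    H <- all_haplotypes(L)
    tot <- sum(vapply(seq_len(nrow(H)), function(i) {
      gamete_probability(G, r, H[i, ])
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("empirical gamete frequencies match the exact distribution", {
  set.seed(5)
  L <- 5
  G <- genotype(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))  # every gamete reachable
  r <- c(0.15, 0.4, 0.25, 0.2)  # keeps every expected cell count large
  H <- all_haplotypes(L)
  probs <- vapply(seq_len(nrow(H)), function(i) {
    gamete_probability(G, r, H[i, ])
  }, numeric(1))
  n <- 2e4
  codes <- replicate(n, sum(sample_gamete(G, r) * 2^(0:(L - 1)))) + 1
  counts <- tabulate(codes, nbins = nrow(H))
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.01)
})

test_that("loci across a chromosome boundary assort independently", {
  set.seed(6)
  G <- genotype(c(1, 1), c(0, 0))
  n <- 1e4
  g <- replicate(n, sample_gamete(G, 0.5))
  # both loci heterozygous and coupled in the parent: only the boundary
  # decouples them
  expect_lt(abs(stats::cor(g[1, ], g[2, ])), 5 / sqrt(n))
})

test_that("crossing and selfing behave Mendelianly", {
  set.seed(8)
  p <- tiny_parents(s = 0)
  r <- rep(0.1, p$L - 1)
  # homozygous x homozygous is deterministic: the unique F1
  f1s <- cross(p$donor, p$rp, r, 3)
  for (f1 in f1s) {
    expect_identical(f1[, 1L], p$donor[, 1L])
    expect_identical(f1[, 2L], p$rp[, 1L])
  }
  # selfing (or crossing with itself) a homozygote reproduces it
  for (G in cross(p$rp, p$rp, r, 3)) expect_identical(unname(G), unname(p$rp))
  for (G in self_cross(p$rp, r, 2)) {
    expect_identical(dim(G), dim(p$rp))
    expect_identical(unname(G), unname(p$rp))
  }

  # Mendelian segregation at a single free-recombining target
  het <- genotype(c(1, 1), c(1, 0))
  rp1 <- genotype(c(1, 0), c(1, 0))
  n <- 1e4
  bc <- cross(het, rp1, 0.5, n)
  pos <- mean(vapply(bc, is_positive, logical(1), D = 2, stage = "backcross"))
  expect_lt(abs(pos - 0.5), 3 * sqrt(0.25 / n))

  # selfing a heterozygote: 1/4 homozygous desirable
  f2 <- self_cross(het, 0.5, n)
  hom <- mean(vapply(f2, is_positive, logical(1), D = 2, stage = "selfed"))
  expect_lt(abs(hom - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  expect_error(cross(het, genotype(c(1, 1, 1), c(0, 0, 0)), c(0.1, 0.1)),
               "same locus count")
})

test_that("meiosis is reproducible under a fixed seed", {
  G <- rand_genotype(30)
  r <- rand_recomb(30)
  set.seed(99); a <- replicate(5, sample_gamete(G, r))
  set.seed(99); b <- replicate(5, sample_gamete(G, r))
  expect_identical(a, b)
})
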