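test_that("background GEBV is the desirable background allele count", {
  L <- 10; D <- c(2, 5, 9)
  rp <- genotype(ifelse(seq_len(L) %in% D, 0L, 1L),
                 ifelse(seq_len(L) %in% D, 0L, 1L))
  expect_identical(gebv_background(rp, D), 14L)          # 2 (L - Z)

  zero <- genotype(ifelse(seq_len(L) %in% D, 1L, 0L),
                   ifelse(seq_len(L) %in% D, 1L, 0L))
  expect_identical(gebv_background(zero, D), 0L)

  f1 <- make_f1(zero, rp)                                # one elite column
  expect_identical(gebv_background(f1, D), 7L)

  # column swap and r never matter
  set.seed(11)
  G <- rand_genotype(L)
  expect_identical(gebv_background(G, D), gebv_background(G[, 2:1], D))

  # weight hook reduces to the count at unit weights
  w <- rep(1, L)
  expect_equal(gebv_background(G, D, weights = w),
               as.double(gebv_background(G, D)))
})

test_that("pcv hits its closed-form corner cases", {
  r <- c(0.3, 0.2)
  expect_equal(pcv(matrix(1L, 3, 2), r), 1)
  G0 <- genotype(c(1, 0, 1), c(1, 0, 1))
  expect_equal(pcv(G0, r), 0)                            # 0/0 locus
  expect_equal(pcv(G0, r, log = TRUE), -Inf)
  G <- genotype(c(1, 1, 0), c(0, 1, 1))
  expect_equal(pcv(G, c(0.1, 0.2)), 0.13)
  expect_equal(pcv(G, c(0.1, 0.2), log = TRUE), log(0.13))
})

test_that("pcv equals the exact all-ones gamete probability", {
  set.seed(12)
  for (i in 1:200) {
    L <- sample(2:12, 1)
    G <- rand_genotype(L)
    r <- rand_recomb(L)
    expect_equal(pcv(G, r), gamete_probability(G, r, rep(1L, L)),
                 tolerance = 1e-12)
  }
})

test_that("pcv never decreases when an allele improves", {
  set.seed(13)
  for (i in 1:50) {
    L <- sample(3:10, 1)
    G <- rand_genotype(L)
    r <- rand_recomb(L)
    zeros <- which(G == 0L)
    if (length(zeros) == 0L) next
    G2 <- G
    G2[sample(zeros, 1)] <- 1L
    expect_gte(pcv(G2, r), pcv(G, r) - 1e-15)
  }
})

test_that("pcv stays finite in log space for long heterozygous genomes", {
  L <- 400
  G <- genotype(rep(1L, L), rep(0L, L))
  r <- rep(0.01, L - 1)
  lp <- pcv(G, r, log = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, log(0.5))
})

test_that("rank_select keeps the top-k positive individuals", {
  D <- 2L
  pos <- genotype(c(1, 1, 1), c(0, 1, 0))
  neg <- genotype(c(1, 0, 1), c(0, 0, 0))
  pop <- list(neg, pos, pos, pos, neg)
  scores <- c(99, 3, 1, 2, 98)      # high scores on negatives must not win
  sel <- rank_select(pop, scores, 2, D, "backcross")
  expect_identical(attr(sel, "index"), c(2L, 4L))

  # all-tied scores: a reproducible uniform subset of the positives
  set.seed(21); a <- attr(rank_select(pop, rep(1, 5), 2, D), "index")
  set.seed(21); b <- attr(rank_select(pop, rep(1, 5), 2, D), "index")
  expect_identical(a, b)
  expect_true(all(a %in% c(2L, 3L, 4L)))

  # fewer positives than k: return all, with a warning
  expect_warning(sel <- rank_select(list(neg, pos), c(1, 2), 2, D),
                 "returning all")
  expect_length(sel, 1L)

  # no positives at all: the program fails
  expect_error(rank_select(list(neg, neg), c(1, 2), 1, D), "no positive")

  # a population of one positive individual is always selected
  expect_identical(attr(rank_select(list(pos), 5, 1, D), "index"), 1L)
})
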