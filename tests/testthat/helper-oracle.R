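# Independent brute-force oracle for gamete probabilities: enumerate every
# inheritance path (2^L source vectors) by binary code and accumulate the
# chain-rule probability of the paths consistent with the requested gamete.
# Written as a straight enumeration so it shares no code with the package's
# forward recursion.
oracle_gamete_prob <- function(G, r, g) {
  L <- nrow(G)
  total <- 0
  for (code in 0:(2^L - 1)) {
    src <- as.integer(intToBits(code))[seq_len(L)] + 1L
    if (!all(G[cbind(seq_len(L), src)] == g)) next
    p <- 0.5
    if (L > 1) {
      for (l in 2:L) {
        p <- p * if (src[l] != src[l - 1]) r[l - 1] else 1 - r[l - 1]
      }
    }
    total <- total + p
  }
  total
}

rand_genotype <- function(L) {
  genotype(stats::rbinom(L, 1, 0.5), stats::rbinom(L, 1, 0.5))
}

rand_recomb <- function(L) stats::runif(L - 1, 0, 0.5)

# all 2^L binary haplotypes, one per row
all_haplotypes <- function(L) {
  m <- as.matrix(expand.grid(rep(list(0:1), L)))
  dimnames(m) <- NULL
  m
}

# a small recurrent parent / donor pair for pipeline tests
tiny_parents <- function(L = 20L, D = c(5L, 10L, 15L), s = 0.5) {
  pair <- generate_parent_pair(L, D, s)
  list(donor = pair$donor, rp = pair$rp, D = D, L = L)
}

# one-sided paired check that method a is not significantly worse than b
paired_not_worse <- function(a, b, alpha_z = 1.645) {
  d <- a - b
  se <- stats::sd(d) / sqrt(length(d))
  if (!is.finite(se) || se == 0) return(mean(d) >= 0)
  mean(d) >= -alpha_z * se
}
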