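#' Sample a meiotic inheritance path
#'
#' The inheritance path names, locus by locus, which chromosome copy the
#' gamete draws from. Under the no-interference model this is a two-state
#' first-order Markov chain: the first locus comes from either copy with
#' probability 1/2, and between adjacent loci the chain switches copy with
#' the interval's recombination frequency `r[l]` and stays put with
#' `1 - r[l]`. An interval with r = 0.5 (a chromosome boundary) makes the
#' two sides assort independently.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param r recombination map (length `L - 1`).
#' @return integer vector of length `L` over `{1, 2}`.
#' @export
sample_inheritance <- function(r) {
  r <- validate_recomb_map(r)
  L <- length(r) + 1L
  start <- sample.int(2L, 1L)
  if (L == 1L) return(start)
  switches <- as.integer(runif(L - 1L) < r)
  1L + (start - 1L + cumsum(c(0L, switches))) %% 2L
}

#' Sample one gamete from a genotype
#'
#' Draws an inheritance path and reads the transmitted allele at each
#' locus: `g[l] = G[l, source[l]]`.
#'
#' @param G genotype matrix (`L x 2`).
#' @param r recombination map (length `L - 1`).
#' @return binary integer vector of length `L` (a haplotype).
#' @export
sample_gamete <- function(G, r) {
  G <- validate_genotype(G)
  r <- validate_recomb_map(r, nrow(G))
  src <- sample_inheritance(r)
  G[cbind(seq_len(nrow(G)), src)]
}

#' Exact probability of a given gamete
#'
#' Computes `Pr(sample_gamete(G, r) == g)` exactly. The default
#' `"forward"` method runs the two-state forward recursion over the
#' inheritance chain in O(L); `"enumerate"` sums the path probabilities of
#' all `2^L` inheritance paths consistent with `g` (only for small L) and
#' serves as a brute-force cross-check of the recursion.
#'
#' @param G genotype matrix.
#' @param r recombination map.
#' @param g haplotype (length-`L` binary vector).
#' @param method `"forward"` or `"enumerate"`.
#' @return probability in `[0, 1]`.
#' @examples
#' G <- genotype(c(1, 1, 0), c(0, 1, 1))
#' gamete_probability(G, c(0.1, 0.2), c(1, 1, 1))  # 0.13
#' @export
gamete_probability <- function(G, r, g, method = c("forward", "enumerate")) {
  method <- match.arg(method)
  G <- validate_genotype(G)
  L <- nrow(G)
  r <- validate_recomb_map(r, L)
  g <- as.integer(g)
  if (length(g) != L || !all(g == 0L | g == 1L)) {
    stop("g must be a length-L binary vector")
  }
  if (method == "forward") {
    w <- 0.5 * (G[1L, ] == g[1L])
    if (L > 1L) {
      for (l in 2L:L) {
        rl <- r[l - 1L]
        w <- c(w[1L] * (1 - rl) + w[2L] * rl,
               w[1L] * rl + w[2L] * (1 - rl)) * (G[l, ] == g[l])
      }
    }
    return(sum(w))
  }
  # brute force: enumerate all 2^L inheritance paths
  if (L > 16L) stop("enumeration is limited to L <= 16")
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  consistent <- vapply(seq_len(nrow(paths)), function(i) {
    all(G[cbind(seq_len(L), paths[i, ])] == g)
  }, logical(1))
  if (!any(consistent)) return(0)
  probs <- vapply(which(consistent), function(i) {
    p <- 0.5
    if (L > 1L) {
      sw <- paths[i, -1L] != paths[i, -L]
      p <- p * prod(ifelse(sw, r, 1 - r))
    }
    p
  }, numeric(1))
  sum(probs)
}

#' Cross two parents
#'
#' Produces `n` progeny, each pairing one fresh gamete from `G1` (column 1)
#' with one from `G2` (column 2). A fully homozygous parent transmits its
#' haplotype deterministically (no random draws are consumed for it), which
#' is exact under the meiosis model and is how backcrosses to the inbred
#' recurrent parent are performed.
#'
#' @param G1,G2 parent genotypes with the same locus count.
#' @param r recombination map.
#' @param n number of progeny.
#' @return list of `n` genotype matrices.
#' @export
cross <- function(G1, G2, r, n = 1L) {
  G1 <- validate_genotype(G1)
  G2 <- validate_genotype(G2)
  if (nrow(G1) != nrow(G2)) stop("parents must have the same locus count")
  r <- validate_recomb_map(r, nrow(G1))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  hom1 <- is_homozygous(G1)
  hom2 <- is_homozygous(G2)
  lapply(seq_len(n), function(i) {
    g1 <- if (hom1) G1[, 1L] else sample_gamete(G1, r)
    g2 <- if (hom2) G2[, 1L] else sample_gamete(G2, r)
    cbind(chrom1 = g1, chrom2 = g2)
  })
}

#' Self-fertilise an individual
#'
#' Produces `n` progeny, each pairing two independent gametes drawn from
#' the same parent. Used to form the terminal BCTF2 generation, where
#' target homozygosity is required for positivity.
#'
#' @param G parent genotype.
#' @param r recombination map.
#' @param n number of progeny.
#' @return list of `n` genotype matrices.
#' @export
self_cross <- function(G, r, n = 1L) {
  cross(G, G, r, n)
}
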