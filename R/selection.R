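#' Background genomic estimated breeding value
#'
#' Under uniform marker effects the background GEBV reduces to the count of
#' desirable alleles outside the target set:
#' `sum_{l not in D} sum_m w[l] * G[l, m]`. The default weights are all 1,
#' giving an integer in `[0, 2 (L - Z)]`; a weight vector hook is provided
#' for non-uniform marker effects but is not used by the standard pipeline.
#'
#' @param G genotype matrix.
#' @param D target locus indices.
#' @param weights optional length-`L` non-negative marker weights
#'   (default all ones).
#' @return the weighted background allele count.
#' @export
gebv_background <- function(G, D, weights = NULL) {
  G <- validate_genotype(G)
  D <- validate_targets(D, nrow(G))
  if (is.null(weights)) {
    return(sum(G[-D, , drop = FALSE]))
  }
  weights <- as.double(weights)
  if (length(weights) != nrow(G) || any(weights < 0)) {
    stop("weights must be a length-L non-negative vector")
  }
  sum(weights[-D] * rowSums(G[-D, , drop = FALSE]))
}

#' Predicted cross value
#'
#' The probability that one random gamete from `G` is desirable at every
#' locus. In a backcross scheme the other parent is always the recurrent
#' parent, so this single-individual form scores each candidate by its
#' chance of producing an elite gamete. Computed exactly by a forward pass
#' over the two-state inheritance chain: state weights start at
#' `(1/2 [G[1,1] = 1], 1/2 [G[1,2] = 1])`, are propagated with the
#' stay/switch probabilities `1 - r[l]` / `r[l]`, and states whose allele
#' at the next locus is undesirable are zeroed; the final state sum is the
#' value. Identical to `gamete_probability(G, r, rep(1, L))`.
#'
#' With hundreds of heterozygous loci the probability underflows double
#' precision, so the recursion rescales its state vector and accumulates
#' the log; `log = TRUE` returns the log-probability, which is what the
#' pipeline ranks on (only relative order matters for selection).
#'
#' @param G genotype matrix.
#' @param r recombination map.
#' @param log return the log-probability instead of the probability.
#' @return probability in `[0, 1]`, or its log (possibly `-Inf`).
#' @examples
#' G <- genotype(c(1, 1, 0), c(0, 1, 1))
#' pcv(G, c(0.1, 0.2))  # 0.13
#' @export
pcv <- function(G, r, log = FALSE) {
  G <- validate_genotype(G)
  L <- nrow(G)
  r <- validate_recomb_map(r, L)
  w <- 0.5 * (G[1L, ] == 1L)
  logscale <- 0
  if (L > 1L) {
    for (l in 2L:L) {
      rl <- r[l - 1L]
      w <- c(w[1L] * (1 - rl) + w[2L] * rl,
             w[1L] * rl + w[2L] * (1 - rl)) * (G[l, ] == 1L)
      s <- w[1L] + w[2L]
      if (s == 0) return(if (log) -Inf else 0)
      if (s < 1e-280) {   # rescale before double underflow bites
        w <- w / s
        logscale <- logscale + base::log(s)
      }
    }
  }
  lp <- base::log(sum(w)) + logscale
  if (log) lp else exp(lp)
}

#' Truncation selection of positive individuals
#'
#' Selection is always two-stage: individuals lacking a desirable allele at
#' any target locus are discarded first (foreground selection for the
#' trait), then the `k` highest-scoring positives are kept. Ties are broken
#' by a uniform random draw from R's RNG, so runs are reproducible under
#' [set.seed()]. If fewer than `k` positives exist, all of them are
#' returned with a warning; if none exist the replicate cannot continue and
#' an error is raised.
#'
#' @param population list of genotype matrices.
#' @param scores numeric vector aligned with `population` (larger is
#'   better; `NA` allowed for non-positive individuals).
#' @param k number of parents to select.
#' @param D target locus indices.
#' @param stage positivity stage passed to [is_positive()].
#' @return list of selected genotypes; attribute `"index"` gives their
#'   positions in `population`.
#' @export
rank_select <- function(population, scores, k,
                        D, stage = c("backcross", "selfed")) {
  stage <- match.arg(stage)
  if (length(scores) != length(population)) {
    stop("scores must align with the population")
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  pos <- vapply(population, is_positive, logical(1), D = D, stage = stage)
  idx <- which(pos)
  if (length(idx) == 0L) {
    stop("no positive individuals: the breeding program fails here")
  }
  if (length(idx) < k) {
    warning(sprintf("only %d positive individuals for k = %d; returning all",
                    length(idx), k))
    k <- length(idx)
  }
  s <- scores[idx]
  if (anyNA(s)) stop("positive individuals must all have scores")
  keep <- idx[order(-s, runif(length(s)))][seq_len(k)]
  out <- population[keep]
  attr(out, "index") <- keep
  out
}
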