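#' Look-ahead configuration
#'
#' Tuning parameters for the look-ahead Monte Carlo score. `P` paths are
#' simulated per candidate; at the terminal backcross generation the path's
#' individual is selfed into `K` progeny; `threshold` is the background
#' recovery percent a selfed positive must reach to count as a success;
#' `attempt_cap` bounds the rejection sampling of a target-positive gamete
#' at each backcross step (exhaustion marks the path failed, contributing
#' zero). `T` is the final backcross generation index.
#'
#' @param P rounds of repetition (paths per candidate).
#' @param K selfed evaluation population size per path.
#' @param threshold required recovery percent, in `(0, 100]`.
#' @param attempt_cap maximum gametes tried per backcross step.
#' @param T final backcross generation.
#' @return a `lookahead_config` list.
#' @export
lookahead_config <- function(P = 50L, K = 200L, threshold = 95,
                             attempt_cap = 200L, T = 3L) {
  P <- as.integer(P); K <- as.integer(K)
  attempt_cap <- as.integer(attempt_cap); T_ <- as.integer(T)
  if (P < 1L || K < 1L || attempt_cap < 1L || T_ < 1L) {
    stop("P, K, attempt_cap and T must all be >= 1")
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold > 100) {
    stop("threshold must lie in (0, 100]")
  }
  structure(list(P = P, K = K, threshold = threshold,
                 attempt_cap = attempt_cap, T = T_),
            class = "lookahead_config")
}

# Deterministic integer stream splitting: hashes a base seed with any
# number of integer keys into [0, 2^31 - 2]. Used to give replicates,
# generations and LMC candidates independent reproducible streams.
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + (as.double(k) %% 2147483647) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

#' Simulate one look-ahead descendant path
#'
#' From a backcross-positive candidate at generation `t`, simulates a
#' single path to the terminal generation: at each remaining backcross
#' step a gamete carrying every target allele is rejection-sampled (up to
#' `cfg$attempt_cap` tries) and paired with the recurrent-parent haplotype;
#' at generation `cfg$T` the individual is selfed into `cfg$K` progeny.
#' The outcome reports `n`, the number of target-homozygous progeny whose
#' background recovery meets `cfg$threshold`; `v`, the maximum recovery
#' among target-homozygous progeny (0 if none); and `failed`, whether any
#' step exhausted the attempt cap.
#'
#' @param G candidate genotype, positive at the backcross stage.
#' @param rp recurrent parent genotype (homozygous).
#' @param r recombination map.
#' @param t candidate's current backcross generation (`t <= cfg$T`;
#'   `t = cfg$T` means self immediately).
#' @param cfg a [lookahead_config()].
#' @param D target locus indices.
#' @param seed integer seed for the path's private RNG stream.
#' @return list with elements `n`, `v`, `failed`.
#' @export
simulate_lookahead_path <- function(G, rp, r, t, cfg, D, seed) {
  G <- validate_genotype(G)
  rp <- validate_genotype(rp)
  L <- nrow(G)
  r <- validate_recomb_map(r, L)
  D <- validate_targets(D, L)
  stopifnot(inherits(cfg, "lookahead_config"))
  t <- as.integer(t)
  if (t > cfg$T) stop("t must not exceed the terminal generation cfg$T")
  if (!is_homozygous(rp)) stop("the recurrent parent must be homozygous")
  if (!is_positive(G, D, "backcross")) {
    stop("candidate is not positive at the backcross stage")
  }
  cpp_lookahead_path(G, rp[, 1L], r, cfg$T - t, cfg$K, cfg$threshold,
                     cfg$attempt_cap, D, as.double(seed))
}

#' Look-ahead Monte Carlo Q score
#'
#' Averages `P` independent descendant paths:
#' `Q = sum_j (n_j / K) * v_j / P`, where `n_j / K` estimates the
#' probability that a selfed terminal progeny is target-homozygous with
#' recovery at or above the threshold and `v_j` is the best recovery seen
#' on path `j`. Failed paths contribute zero. `Q` lies in `[0, 100]`;
#' non-positive candidates score 0 by contract (no paths are simulated).
#'
#' @inheritParams simulate_lookahead_path
#' @return the Q score, a real in `[0, 100]`.
#' @export
lmc_score <- function(G, rp, r, t, cfg, D, seed) {
  G <- validate_genotype(G)
  rp <- validate_genotype(rp)
  L <- nrow(G)
  r <- validate_recomb_map(r, L)
  D <- validate_targets(D, L)
  stopifnot(inherits(cfg, "lookahead_config"))
  t <- as.integer(t)
  if (t > cfg$T) stop("t must not exceed the terminal generation cfg$T")
  if (!is_homozygous(rp)) stop("the recurrent parent must be homozygous")
  if (!is_positive(G, D, "backcross")) return(0)
  cpp_lmc_score(G, rp[, 1L], r, cfg$T - t, cfg$K, cfg$threshold,
                cfg$attempt_cap, D, cfg$P, as.double(seed))
}
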