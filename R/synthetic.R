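#' Nei genetic similarity of two inbred lines
#'
#' For fully homozygous biallelic lines Nei's genetic identity collapses
#' to the proportion of loci at which the two lines carry the same
#' genotype; that specialisation is what this returns. Heterozygous input
#' is rejected because the generator contract covers inbreds only.
#'
#' @param a,b homozygous genotypes with equal locus count.
#' @return proportion of matching loci, in `[0, 1]`.
#' @export
nei_similarity <- function(a, b) {
  a <- validate_genotype(a)
  b <- validate_genotype(b)
  if (nrow(a) != nrow(b)) stop("lines must have the same locus count")
  if (!is_homozygous(a) || !is_homozygous(b)) {
    stop("Nei similarity is defined here for homozygous inbred lines only")
  }
  mean(a[, 1L] == b[, 1L])
}

#' Generate a donor / recurrent-parent pair at a target Nei similarity
#'
#' The recurrent parent is homozygous desirable at every background locus
#' and undesirable at the targets; the donor is homozygous desirable at
#' the targets and at a uniformly random background subset sized so the
#' realised similarity is as close as possible to `s`. The targets always
#' mismatch, so the feasible similarity range is `[0, (L - Z) / L]`; a
#' request above it is an error naming the range. Counting convention:
#' similarity is over all `L` loci including the always-mismatching
#' targets.
#'
#' Uses R's global RNG; seed with [set.seed()].
#'
#' @param L locus count.
#' @param D target locus indices.
#' @param s requested Nei similarity in `[0, 1]`.
#' @return list with homozygous `donor` and `rp` genotypes.
#' @export
generate_parent_pair <- function(L, D, s) {
  L <- as.integer(L)
  D <- validate_targets(D, L)
  Z <- length(D)
  if (!is.finite(s) || s < 0 || s > 1) stop("s must lie in [0, 1]")
  smax <- (L - Z) / L
  if (s > smax + 1e-12) {
    stop(sprintf(
      "similarity %.4f infeasible: the %d target loci always mismatch, so s must lie in [0, %.4f]",
      s, Z, smax))
  }
  k <- min(round(s * L), L - Z)  # background loci where the donor matches the RP
  rp_hap <- rep(1L, L); rp_hap[D] <- 0L
  donor_hap <- rep(0L, L); donor_hap[D] <- 1L
  background <- setdiff(seq_len(L), D)
  if (k > 0L) donor_hap[sample(background, k)] <- 1L
  list(donor = genotype(donor_hap, donor_hap),
       rp = genotype(rp_hap, rp_hap))
}

#' Generate a synthetic recombination map
#'
#' Produces `L - 1` recombination frequencies with exactly `n_chrom - 1`
#' chromosome boundaries (entries equal to 0.5) at near-equal spacing;
#' within-chromosome entries are drawn i.i.d. from `law`, truncated to
#' `[0, 0.5)`. The default law, uniform on (0, 0.1), gives the tight
#' linkage typical of a dense marker map.
#'
#' @param L locus count.
#' @param n_chrom number of chromosomes (`>= 1`, `<= L`).
#' @param law function of `n` returning `n` draws; default
#'   `function(n) runif(n, 0, 0.1)`.
#' @return recombination map of length `L - 1`.
#' @export
generate_recomb_map <- function(L, n_chrom = 10L, law = NULL) {
  L <- as.integer(L); n_chrom <- as.integer(n_chrom)
  if (n_chrom < 1L || L < n_chrom) stop("need 1 <= n_chrom <= L")
  if (is.null(law)) law <- function(n) runif(n, 0, 0.1)
  r <- numeric(L - 1L)
  n <- length(r)
  if (n == 0L) return(r)
  draw <- law(n)
  bad <- !(draw >= 0 & draw < 0.5)
  while (any(bad)) {  # truncate the law to [0, 0.5) by rejection
    draw[bad] <- law(sum(bad))
    bad <- !(draw >= 0 & draw < 0.5)
  }
  r <- draw
  if (n_chrom > 1L) {
    # near-equal chromosome sizes; boundary after the cumulative sizes
    sizes <- rep(L %/% n_chrom, n_chrom)
    extra <- L %% n_chrom
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bounds <- cumsum(sizes)[-n_chrom]
    r[bounds] <- 0.5
  }
  validate_recomb_map(r, L)
}

#' Synthetic study-case presets
#'
#' Three donor/recurrent-parent cases at increasing initial genetic
#' similarity, emulating low / moderate / high relatedness between an
#' exotic donor and an elite line: case 1 = 195 markers at similarity
#' 0.58, case 2 = 173 at 0.72, case 3 = 172 at 0.89, each with Z = 3
#' target loci (placed at the 25/50/75% quantile positions of the map) on
#' a 10-chromosome genome.
#'
#' Uses R's global RNG; seed with [set.seed()].
#'
#' @param case `"case1"`, `"case2"` or `"case3"`.
#' @param n_chrom number of chromosomes for the synthetic map.
#' @param law within-chromosome recombination law for
#'   [generate_recomb_map()].
#' @return list with `donor`, `rp`, `r`, `targets`, `L`, `similarity`
#'   (the realised Nei similarity).
#' @export
synthetic_case <- function(case = c("case1", "case2", "case3"),
                           n_chrom = 10L, law = NULL) {
  case <- match.arg(case)
  spec <- switch(case,
                 case1 = list(L = 195L, s = 0.58),
                 case2 = list(L = 173L, s = 0.72),
                 case3 = list(L = 172L, s = 0.89))
  targets <- sort(unique(as.integer(round(spec$L * c(0.25, 0.5, 0.75)))))
  pair <- generate_parent_pair(spec$L, targets, spec$s)
  r <- generate_recomb_map(spec$L, n_chrom = n_chrom, law = law)
  list(donor = pair$donor, rp = pair$rp, r = r, targets = targets,
       L = spec$L, similarity = nei_similarity(pair$donor, pair$rp))
}
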