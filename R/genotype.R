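#' Construct a diploid genotype from two haplotypes
#'
#' A genotype is an `L x 2` integer matrix with entries in `{0, 1}`,
#' 1 marking the desirable allele. Column `m` is the m-th chromosome copy;
#' rows are loci in map order. Chromosome structure is carried by the
#' recombination map (boundary intervals have r = 0.5), not by the matrix.
#'
#' @param chrom1,chrom2 length-`L` binary vectors, one per chromosome copy.
#' @return an `L x 2` integer matrix with columns `chrom1`, `chrom2`.
#' @examples
#' g <- genotype(c(1, 0, 1), c(1, 1, 0))
#' @export
genotype <- function(chrom1, chrom2) {
  if (length(chrom1) != length(chrom2)) {
    stop("haplotypes must have equal length")
  }
  validate_genotype(cbind(chrom1 = as.integer(chrom1),
                          chrom2 = as.integer(chrom2)))
}

#' Validate a genotype matrix
#'
#' Checks the diploid binary-matrix invariants: two columns, at least one
#' locus, every entry 0 or 1. Returns the matrix in integer storage mode so
#' downstream arithmetic and the compiled code see a consistent type.
#'
#' @param G candidate genotype matrix.
#' @return `G`, validated, with integer storage.
#' @export
validate_genotype <- function(G) {
  if (!is.matrix(G) || ncol(G) != 2L) {
    stop("a genotype must be an L x 2 matrix (diploid, two chromosome copies)")
  }
  if (nrow(G) < 1L) stop("a genotype needs at least one locus")
  if (anyNA(G) || !all(G == 0L | G == 1L)) {
    stop("genotype entries must all be 0 or 1")
  }
  storage.mode(G) <- "integer"
  G
}

#' Validate a recombination map
#'
#' A recombination map is a numeric vector of `L - 1` recombination
#' frequencies, entry `l` giving the crossover probability between loci
#' `l` and `l + 1`. All entries lie in `[0, 0.5]`; chromosome boundaries
#' are encoded as exactly 0.5 (free recombination).
#'
#' @param r numeric vector of recombination frequencies.
#' @param L optional locus count; if given, `length(r)` must be `L - 1`.
#' @return `r`, validated, as a double vector.
#' @export
validate_recomb_map <- function(r, L = NULL) {
  r <- as.double(r)
  if (anyNA(r) || any(r < 0) || any(r > 0.5)) {
    stop("recombination frequencies must lie in [0, 0.5]")
  }
  if (!is.null(L) && length(r) != L - 1L) {
    stop(sprintf("recombination map has %d entries; expected L - 1 = %d",
                 length(r), L - 1L))
  }
  r
}

#' Validate a target-locus set
#'
#' Targets are the Z introgression loci: donor-desirable, recurrent-parent
#' undesirable. Indices are 1-based, distinct, within `[1, L]`, and must
#' leave a non-empty background (`Z < L`).
#'
#' @param D integer vector of target locus indices.
#' @param L locus count.
#' @return sorted integer vector of targets.
#' @export
validate_targets <- function(D, L) {
  D <- sort(unique(as.integer(D)))
  if (length(D) < 1L) stop("the target set must contain at least one locus")
  if (any(D < 1L) || any(D > L)) {
    stop(sprintf("target locus indices must lie in [1, %d]", L))
  }
  if (length(D) >= L) {
    stop("targets cover every locus: the background is empty")
  }
  D
}

#' Background recovery percentage
#'
#' The proportion (as a percent) of desirable alleles among all non-target
#' (background) alleles: `100 * sum_{l not in D, m} G[l, m] / (2 (L - Z))`.
#' This is the recurrent-parent genome recovery statistic used to evaluate
#' backcross progeny.
#'
#' @param G genotype matrix (`L x 2`, binary).
#' @param D target locus indices (1-based).
#' @return recovery percent in `[0, 100]`.
#' @examples
#' G <- matrix(1L, 10, 2)
#' recovery_percentage(G, D = 3)  # 100
#' @export
recovery_percentage <- function(G, D) {
  G <- validate_genotype(G)
  D <- validate_targets(D, nrow(G))
  bg <- G[-D, , drop = FALSE]
  100 * sum(bg) / (2 * nrow(bg))
}

#' Is an individual positive for the target alleles?
#'
#' A backcross-stage individual is positive when it carries at least one
#' desirable allele at every target locus (targets are heterozygous in
#' practice, since the recurrent parent is undesirable there). After
#' selfing, positivity requires homozygosity: both copies desirable at
#' every target.
#'
#' @param G genotype matrix.
#' @param D target locus indices.
#' @param stage `"backcross"` (at least one copy) or `"selfed"` (both).
#' @return logical scalar.
#' @export
is_positive <- function(G, D, stage = c("backcross", "selfed")) {
  stage <- match.arg(stage)
  G <- validate_genotype(G)
  D <- validate_targets(D, nrow(G))
  copies <- rowSums(G[D, , drop = FALSE])
  if (stage == "backcross") all(copies >= 1L) else all(copies == 2L)
}

#' Count desirable alleles at the target loci
#'
#' `sum_{l in D, m} G[l, m]`, between 0 and `2 Z`. A pipeline-produced
#' positive backcross individual carries exactly `Z` (one donor copy per
#' target); a positive selfed individual carries `2 Z`.
#'
#' @inheritParams is_positive
#' @return integer count of desirable target alleles.
#' @export
count_target_alleles <- function(G, D) {
  G <- validate_genotype(G)
  D <- validate_targets(D, nrow(G))
  sum(G[D, , drop = FALSE])
}

#' Is a genotype fully homozygous?
#'
#' @param G genotype matrix.
#' @return `TRUE` when both chromosome copies are identical at every locus.
#' @export
is_homozygous <- function(G) {
  G <- validate_genotype(G)
  all(G[, 1L] == G[, 2L])
}
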