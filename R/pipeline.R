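#' Breeding program configuration
#'
#' Describes one trait-introgression program: `T` backcross generations
#' followed by one selfing, with `crosses_per_gen` crosses of
#' `progeny_per_cross` progeny each in every generation. The two standard
#' resource scenarios are presets: scenario 1 (limited, 2 crosses per
#' generation, populations of 400) and scenario 2 (moderate, 6 crosses,
#' populations of 1200).
#'
#' @param method selection metric: `"gebv"`, `"pcv"` or `"lmc"`.
#' @param scenario optional preset, `1` or `2`, setting `crosses_per_gen`.
#' @param crosses_per_gen crosses (= selected parents) per generation;
#'   required unless `scenario` is given.
#' @param T number of backcross generations.
#' @param progeny_per_cross progeny per cross.
#' @param replicates number of independent simulation replicates.
#' @param threshold success recovery percent for the terminal generation.
#' @param seed master RNG seed for the replicate runner.
#' @param lmc a [lookahead_config()]; defaults to one matching `T` and
#'   `threshold`.
#' @return a `program_config` list.
#' @export
program_config <- function(method = c("gebv", "pcv", "lmc"),
                           scenario = NULL, crosses_per_gen = NULL,
                           T = 3L, progeny_per_cross = 200L,
                           replicates = 100L, threshold = 95,
                           seed = 1L, lmc = NULL) {
  method <- match.arg(method)
  T_ <- as.integer(T)
  if (!is.null(scenario)) {
    presets <- c(`1` = 2L, `2` = 6L)
    key <- as.character(as.integer(scenario))
    if (!key %in% names(presets)) stop("scenario must be 1 or 2")
    if (!is.null(crosses_per_gen) &&
        as.integer(crosses_per_gen) != presets[[key]]) {
      stop(sprintf("scenario %s implies crosses_per_gen = %d; got %s",
                   key, presets[[key]], crosses_per_gen))
    }
    crosses_per_gen <- presets[[key]]
  }
  crosses_per_gen <- if (is.null(crosses_per_gen)) NA_integer_ else
    as.integer(crosses_per_gen)
  progeny_per_cross <- as.integer(progeny_per_cross)
  replicates <- as.integer(replicates)
  if (T_ < 1L) stop("T must be >= 1")
  if (!is.na(crosses_per_gen) && crosses_per_gen < 1L) {
    stop("crosses_per_gen must be >= 1")
  }
  if (progeny_per_cross < 1L || replicates < 1L) {
    stop("progeny_per_cross and replicates must be >= 1")
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold > 100) {
    stop("threshold must lie in (0, 100]")
  }
  if (is.null(lmc)) lmc <- lookahead_config(T = T_, threshold = threshold)
  stopifnot(inherits(lmc, "lookahead_config"))
  if (lmc$T != T_) stop("lmc$T must equal the program's T")
  structure(list(method = method, crosses_per_gen = crosses_per_gen,
                 T = T_, progeny_per_cross = progeny_per_cross,
                 replicates = replicates, threshold = threshold,
                 seed = as.integer(seed), lmc = lmc),
            class = "program_config")
}

#' Make the F1 of two homozygous parents
#'
#' With both parents fully inbred, meiosis is deterministic and the F1 is
#' unique: chromosome copy 1 is the donor haplotype, copy 2 the recurrent
#' parent haplotype, so the F1 carries 50% of its material from each.
#'
#' @param donor donor genotype (homozygous).
#' @param rp recurrent parent genotype (homozygous).
#' @return the F1 genotype.
#' @export
make_f1 <- function(donor, rp) {
  donor <- validate_genotype(donor)
  rp <- validate_genotype(rp)
  if (nrow(donor) != nrow(rp)) stop("parents must have the same locus count")
  if (!is_homozygous(donor) || !is_homozygous(rp)) {
    stop("both parents must be homozygous for a deterministic F1")
  }
  genotype(donor[, 1L], rp[, 1L])
}

# recovery + positivity table for a population
population_table <- function(pop, D, stage) {
  data.frame(
    individual = seq_along(pop),
    recovery = vapply(pop, recovery_percentage, numeric(1), D = D),
    positive = vapply(pop, is_positive, logical(1), D = D, stage = stage)
  )
}

# Score the positive members of a population under the configured method;
# non-positives get NA (rank_select discards them anyway).
score_population <- function(pop, gen, cfg, rp, r, D, seed) {
  idx <- which(vapply(pop, is_positive, logical(1), D = D, stage = "backcross"))
  scores <- rep(NA_real_, length(pop))
  if (length(idx) == 0L) return(scores)
  scores[idx] <- switch(
    cfg$method,
    gebv = vapply(pop[idx], gebv_background, numeric(1), D = D),
    pcv = vapply(pop[idx], pcv, numeric(1), r = r, log = TRUE),
    lmc = vapply(seq_along(idx), function(j) {
      lmc_score(pop[[idx[j]]], rp, r, gen, cfg$lmc, D,
                seed = derive_seed(seed, 4L, gen, idx[j]))
    }, numeric(1))
  )
  scores
}

select_parents <- function(pop, gen, cfg, rp, r, D, seed, verbose = FALSE) {
  scores <- score_population(pop, gen, cfg, rp, r, D, seed)
  if (all(is.na(scores))) return(NULL)
  set.seed(derive_seed(seed, 5L, gen))
  sel <- suppressWarnings(
    rank_select(pop, scores, cfg$crosses_per_gen, D, "backcross")
  )
  if (verbose) {
    message(sprintf("gen %d: selected individuals %s (scores %s)", gen,
                    paste(attr(sel, "index"), collapse = ", "),
                    paste(signif(scores[attr(sel, "index")], 4),
                          collapse = ", ")))
  }
  sel
}

#' Run one replicate of the backcross program
#'
#' Builds the deterministic F1, produces BC1 as `crosses_per_gen` crosses
#' of F1 x RP, then for each later backcross generation scores the
#' positive individuals with the configured metric, selects the top
#' `crosses_per_gen` as parents and backcrosses each to the recurrent
#' parent. After the terminal backcross generation the selected parents
#' are selfed to form the BCTF2 population. If positives go extinct at any
#' selection the replicate is recorded as a failure.
#'
#' The first RNG phase (BC1 creation) depends only on `seed`, never on the
#' selection method, so different methods run with the same seed start
#' from identical BC1 populations and can be compared pairwise.
#'
#' @param cfg a [program_config()].
#' @param donor,rp homozygous parent genotypes (donor carries the targets,
#'   the recurrent parent is desirable at every background locus).
#' @param r recombination map.
#' @param D target locus indices.
#' @param seed replicate seed (defaults to `cfg$seed`).
#' @param verbose emit per-generation selection messages.
#' @return a `replicate_result` list: per-generation recovery/positivity
#'   tables (`generations`), the maximum recovery among target-homozygous
#'   BCTF2 individuals (`bctf2_max`, `NA` on failure), the success flag
#'   against `cfg$threshold`, and `failed`/`failed_at`.
#' @export
run_program <- function(cfg, donor, rp, r, D, seed = cfg$seed,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "program_config"))
  if (is.na(cfg$crosses_per_gen)) {
    stop("crosses_per_gen is unset: give crosses_per_gen or a scenario")
  }
  donor <- validate_genotype(donor)
  rp <- validate_genotype(rp)
  L <- nrow(donor)
  r <- validate_recomb_map(r, L)
  D <- validate_targets(D, L)
  if (!is_positive(donor, D, "selfed")) {
    stop("the donor must be homozygous desirable at every target locus")
  }
  if (!all(rp[-D, ] == 1L)) {
    stop("the recurrent parent must be desirable at every background locus")
  }
  if (!all(rp[D, ] == 0L)) {
    stop("the recurrent parent must be undesirable at every target locus")
  }

  fail_result <- function(gens, at) {
    structure(list(generations = gens, bctf2_max = NA_real_,
                   success = FALSE, failed = TRUE, failed_at = at),
              class = "replicate_result")
  }

  f1 <- make_f1(donor, rp)
  n_per_gen <- cfg$crosses_per_gen * cfg$progeny_per_cross
  set.seed(derive_seed(seed, 1L))
  pop <- cross(f1, rp, r, n_per_gen)  # the single F1 crossed crosses_per_gen times
  gens <- list(BC1 = population_table(pop, D, "backcross"))

  if (cfg$T >= 2L) {
    for (t in 2L:cfg$T) {
      parents <- select_parents(pop, t - 1L, cfg, rp, r, D, seed, verbose)
      if (is.null(parents)) return(fail_result(gens, paste0("BC", t - 1L)))
      set.seed(derive_seed(seed, 2L, t))
      pop <- unlist(lapply(parents, cross, G2 = rp, r = r,
                           n = cfg$progeny_per_cross), recursive = FALSE)
      gens[[paste0("BC", t)]] <- population_table(pop, D, "backcross")
    }
  }

  parents <- select_parents(pop, cfg$T, cfg, rp, r, D, seed, verbose)
  if (is.null(parents)) return(fail_result(gens, paste0("BC", cfg$T)))
  set.seed(derive_seed(seed, 3L))
  f2 <- unlist(lapply(parents, self_cross, r = r,
                      n = cfg$progeny_per_cross), recursive = FALSE)
  gens[[paste0("BC", cfg$T, "F2")]] <- population_table(f2, D, "selfed")

  f2_tab <- gens[[length(gens)]]
  bctf2_max <- if (any(f2_tab$positive)) {
    max(f2_tab$recovery[f2_tab$positive])
  } else NA_real_
  structure(list(generations = gens, bctf2_max = bctf2_max,
                 success = isTRUE(bctf2_max >= cfg$threshold),
                 failed = FALSE, failed_at = NA_character_),
            class = "replicate_result")
}

#' Run independent replicates of a breeding program
#'
#' Each replicate gets its own seed derived from `cfg$seed` and its index,
#' so results are reproducible, independent of execution order, and
#' identical whatever the thread count.
#'
#' @inheritParams run_program
#' @param threads replicate-level parallelism (forked; requires the
#'   parallel package for `threads > 1`).
#' @return list of [run_program()] results, one per replicate.
#' @export
run_replicates <- function(cfg, donor, rp, r, D, threads = 1L) {
  stopifnot(inherits(cfg, "program_config"))
  seeds <- vapply(seq_len(cfg$replicates), function(i) {
    derive_seed(cfg$seed, 100L, i)
  }, integer(1))
  runner <- function(s) run_program(cfg, donor, rp, r, D, seed = s)
  if (threads > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seeds, runner, mc.cores = threads)
  } else {
    lapply(seeds, runner)
  }
}

#' Probability of program success
#'
#' The proportion of replicates whose best target-homozygous terminal
#' individual reached the recovery threshold. Failed replicates (positive
#' extinction, or no homozygous positive in BCTF2) count as non-successes.
#'
#' @param results list of `replicate_result`s.
#' @param threshold recovery percent defining success.
#' @return proportion in `[0, 1]`.
#' @export
success_probability <- function(results, threshold) {
  if (length(results) == 0L) stop("need at least one replicate result")
  maxima <- vapply(results, function(x) x$bctf2_max, numeric(1))
  mean(!is.na(maxima) & maxima >= threshold)
}

#' Summarise one generation across replicates
#'
#' For each replicate, computes the minimum, mean and maximum recovery of
#' the generation's positive individuals plus the mean of its top-10
#' (fewer when fewer positives exist, flagged by `top_n`). Across
#' replicates, returns the vector of population maxima and its empirical
#' CDF — the evaluation statistics used to compare selection methods.
#' Replicates with no positives in the generation are excluded with a
#' warning.
#'
#' @param results list of `replicate_result`s.
#' @param generation generation name, e.g. `"BC1"`, `"BC3"`, `"BC3F2"`.
#' @return list with `per_replicate` (data frame), `maxima` (numeric
#'   vector) and `cdf` (a [stats::ecdf()] of the maxima).
#' @export
summarize_generation <- function(results, generation) {
  rows <- list()
  maxima <- numeric(0)
  dropped <- 0L
  for (i in seq_along(results)) {
    gens <- results[[i]]$generations
    if (!generation %in% names(gens)) next
    tab <- gens[[generation]]
    rec <- tab$recovery[tab$positive]
    if (length(rec) == 0L) {
      dropped <- dropped + 1L
      next
    }
    top <- sort(rec, decreasing = TRUE)[seq_len(min(10L, length(rec)))]
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = i, n_positive = length(rec),
      min = min(rec), mean = mean(rec), max = max(rec),
      top10_mean = mean(top), top_n = length(top)
    )
    maxima <- c(maxima, max(rec))
  }
  if (dropped > 0L) {
    warning(sprintf("%d replicate(s) had no positive individuals in %s",
                    dropped, generation))
  }
  if (length(rows) == 0L) {
    stop(sprintf("no replicate has positive individuals in %s", generation))
  }
  list(per_replicate = do.call(rbind, rows), maxima = maxima,
       cdf = stats::ecdf(maxima))
}
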