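#' Read and write genotype files
#'
#' Genotype files are tab-separated with a `# format: 1` comment line, a
#' `locus  chrom1  chrom2` header and one row per locus with 0/1 values.
#' Loci must be the contiguous sequence 1..L. Parse errors name the
#' offending line. (The data model is a binary desirability matrix, not
#' sequence, hence TSV rather than a sequence or variant format; mapping
#' observed alleles to desirability is done upstream by the user.)
#'
#' @param path file path.
#' @return `read_genotype`: a validated genotype matrix.
#' @export
read_genotype <- function(path) {
  tab <- read_tsv_checked(path, c("locus", "chrom1", "chrom2"))
  n <- nrow(tab$data)
  loc <- suppressWarnings(as.integer(tab$data$locus))
  for (col in c("chrom1", "chrom2")) {
    v <- tab$data[[col]]
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad)) {
      stop(sprintf("%s line %d: %s value '%s' is not 0/1",
                   path, tab$lines[bad[1]], col, v[bad[1]]))
    }
  }
  if (anyNA(loc)) {
    stop(sprintf("%s line %d: locus is not an integer",
                 path, tab$lines[which(is.na(loc))[1]]))
  }
  if (!identical(loc, seq_len(n))) {
    stop(sprintf("%s: loci must be contiguous 1..%d (gap, duplicate or disorder found)",
                 path, n))
  }
  genotype(as.integer(tab$data$chrom1), as.integer(tab$data$chrom2))
}

#' @rdname read_genotype
#' @param G genotype matrix to write.
#' @return `write_genotype`: `path`, invisibly.
#' @export
write_genotype <- function(G, path) {
  G <- validate_genotype(G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# format: 1", "locus\tchrom1\tchrom2"), con)
  writeLines(sprintf("%d\t%d\t%d", seq_len(nrow(G)), G[, 1L], G[, 2L]), con)
  invisible(path)
}

#' Read and write target-locus files
#'
#' One 1-based locus index per line; `#` comment lines are skipped.
#'
#' @param path file path.
#' @param L optional locus count for range validation.
#' @return `read_targets`: sorted integer vector of target indices.
#' @export
read_targets <- function(path, L = NULL) {
  ln <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", ln))
  if (length(keep) == 0L) stop(sprintf("%s: no target loci found", path))
  vals <- suppressWarnings(as.integer(trimws(ln[keep])))
  if (anyNA(vals)) {
    stop(sprintf("%s line %d: '%s' is not an integer locus index",
                 path, keep[which(is.na(vals))[1]], ln[keep[which(is.na(vals))[1]]]))
  }
  if (is.null(L)) L <- max(vals) + 1L  # only bounds-check when L is known
  validate_targets(vals, L)
}

#' @rdname read_targets
#' @param D target indices to write.
#' @return `write_targets`: `path`, invisibly.
#' @export
write_targets <- function(D, path) {
  writeLines(c("# format: 1", as.character(sort(unique(as.integer(D))))), path)
  invisible(path)
}

#' Read and write recombination-map files
#'
#' Tab-separated with header `interval  r`; row i holds the recombination
#' frequency between loci i and i+1, so a map for L loci has L - 1 rows.
#'
#' @param path file path.
#' @return `read_recomb_map`: numeric recombination map.
#' @export
read_recomb_map <- function(path) {
  tab <- read_tsv_checked(path, c("interval", "r"))
  iv <- suppressWarnings(as.integer(tab$data$interval))
  rv <- suppressWarnings(as.numeric(tab$data$r))
  if (anyNA(iv) || !identical(iv, seq_len(nrow(tab$data)))) {
    stop(sprintf("%s: intervals must be contiguous 1..%d", path, nrow(tab$data)))
  }
  bad <- which(is.na(rv) | rv < 0 | rv > 0.5)
  if (length(bad)) {
    stop(sprintf("%s line %d: r value '%s' is not in [0, 0.5]",
                 path, tab$lines[bad[1]], tab$data$r[bad[1]]))
  }
  validate_recomb_map(rv)
}

#' @rdname read_recomb_map
#' @param r recombination map to write.
#' @return `write_recomb_map`: `path`, invisibly.
#' @export
write_recomb_map <- function(r, path) {
  r <- validate_recomb_map(r)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# format: 1", "interval\tr"), con)
  writeLines(sprintf("%d\t%.17g", seq_along(r), r), con)
  invisible(path)
}

# Shared TSV reader: skips comment lines, checks the header and the column
# count per row, and reports 1-based file line numbers in errors.
read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ln <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", ln))
  if (length(keep) == 0L) stop(sprintf("%s: empty file", path))
  header <- strsplit(ln[keep[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop(sprintf("%s line %d: expected header '%s', found '%s'",
                 path, keep[1], paste(columns, collapse = "\t"), ln[keep[1]]))
  }
  body <- keep[-1]
  if (length(body) == 0L) stop(sprintf("%s: no data rows", path))
  parts <- strsplit(ln[body], "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(columns))) {
    b <- which(nc != length(columns))[1]
    stop(sprintf("%s line %d: expected %d columns, found %d",
                 path, body[b], length(columns), nc[b]))
  }
  data <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(data) <- columns
  list(data = data, lines = body)
}

#' Load a program configuration from YAML
#'
#' Recognised top-level keys: `scenario`, `T`, `crosses_per_gen`,
#' `progeny_per_cross`, `method`, `replicates`, `threshold`, `seed`, and a
#' nested `lmc` block with `P`, `K`, `threshold`, `attempt_cap`. Unknown
#' keys are rejected; missing keys take the standard defaults (T = 3,
#' 200 progeny per cross, 100 replicates, threshold 95). An empty file
#' yields all defaults, but running a program then still requires an
#' explicit scenario or `crosses_per_gen`.
#'
#' @param path YAML file path.
#' @return a [program_config()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop(sprintf("%s: config must be a YAML mapping", path))
  known <- c("scenario", "T", "crosses_per_gen", "progeny_per_cross",
             "method", "replicates", "threshold", "seed", "lmc")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  }
  lmc_cfg <- NULL
  T_ <- if (is.null(cfg$T)) 3L else cfg$T
  thr <- if (is.null(cfg$threshold)) 95 else cfg$threshold
  if (!is.null(cfg$lmc)) {
    lknown <- c("P", "K", "threshold", "attempt_cap")
    lunknown <- setdiff(names(cfg$lmc), lknown)
    if (length(lunknown)) {
      stop(sprintf("%s: unknown lmc key(s): %s", path,
                   paste(lunknown, collapse = ", ")))
    }
    args <- cfg$lmc
    args$T <- T_
    if (is.null(args$threshold)) args$threshold <- thr
    lmc_cfg <- do.call(lookahead_config, args)
  }
  program_config(
    method = if (is.null(cfg$method)) "gebv" else cfg$method,
    scenario = cfg$scenario,
    crosses_per_gen = cfg$crosses_per_gen,
    T = T_,
    progeny_per_cross = if (is.null(cfg$progeny_per_cross)) 200L else
      cfg$progeny_per_cross,
    replicates = if (is.null(cfg$replicates)) 100L else cfg$replicates,
    threshold = thr,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    lmc = lmc_cfg
  )
}

#' Write replicate results as tidy TSV tables
#'
#' `replicates.tsv` holds one row per individual per generation per
#' replicate (`replicate`, `generation`, `individual`, `positive`,
#' `recovery`); `summary.tsv` holds per-replicate terminal maxima and
#' success flags.
#'
#' @param results list of `replicate_result`s.
#' @param dir output directory (created if needed).
#' @param threshold success threshold used for the summary.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, dir, threshold = 95) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(results)) {
    for (gen in names(results[[i]]$generations)) {
      tab <- results[[i]]$generations[[gen]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, generation = gen, individual = tab$individual,
        positive = as.integer(tab$positive), recovery = tab$recovery
      )
    }
  }
  long <- do.call(rbind, rows)
  rep_path <- file.path(dir, "replicates.tsv")
  sum_path <- file.path(dir, "summary.tsv")
  con <- file(rep_path, "w")
  writeLines("# format: 1", con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  summ <- data.frame(
    replicate = seq_along(results),
    failed = vapply(results, function(x) x$failed, logical(1)),
    bctf2_max = vapply(results, function(x) x$bctf2_max, numeric(1)),
    success = vapply(results, function(x) x$success, logical(1))
  )
  con <- file(sum_path, "w")
  writeLines(c("# format: 1",
               sprintf("# success_probability\t%.6f",
                       success_probability(results, threshold))), con)
  utils::write.table(summ, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(rep_path, sum_path))
}
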