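#' Construct an aligned sequence dataset with population labels
#'
#' Container for an alignment of equal-length nucleotide sequences, each
#' tagged with the population it was sampled from.  Sequences may contain
#' the characters A, C, G, T, N and the gap symbol \code{-}; any site
#' holding N or a gap in \emph{any} sequence is excluded from all
#' site-based statistics (complete deletion).
#'
#' @param sequences character vector of equal-length nucleotide strings.
#' @param labels character vector of population identifiers, one per
#'   sequence.
#' @param ids optional sequence identifiers (defaults to \code{seq_1} ...).
#' @return An object of class \code{SequenceDataset}: a list with elements
#'   \code{sequences}, \code{labels}, \code{ids} and \code{locus_length}.
#' @export
sequence_dataset <- function(sequences, labels, ids = NULL) {
  sequences <- toupper(as.character(sequences))
  labels <- as.character(labels)
  if (length(sequences) != length(labels))
    stop("one population label per sequence required")
  if (length(sequences) == 0L) stop("empty dataset")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  if (any(!nzchar(labels)) || anyNA(labels))
    stop("every population label must be nonempty")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequences may only contain A, C, G, T, N or '-' (ambiguity codes other than N are rejected)")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  structure(list(sequences = sequences, labels = labels,
                 ids = as.character(ids), locus_length = lens[1L]),
            class = "SequenceDataset")
}

#' @export
print.SequenceDataset <- function(x, ...) {
  cat("SequenceDataset:", length(x$sequences), "sequences x",
      x$locus_length, "bp,", length(unique(x$labels)), "populations\n")
  invisible(x)
}

#' Construct a diploid microsatellite dataset
#'
#' Genotypes are repeat counts, stored as an integer matrix with two
#' columns per locus (\code{<locus>.1}, \code{<locus>.2}); a missing call
#' has \code{NA} in both columns of the locus.
#'
#' @param genotypes integer matrix, one row per individual, 2L columns for
#'   L loci.
#' @param labels population identifier per individual.
#' @param locus_names character vector of L locus names.
#' @param ids optional individual identifiers.
#' @return An object of class \code{MicrosatDataset}.
#' @export
microsat_dataset <- function(genotypes, labels, locus_names, ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  L <- length(locus_names)
  if (ncol(genotypes) != 2L * L)
    stop("genotype matrix must have 2 columns per locus")
  if (nrow(genotypes) != length(labels))
    stop("one population label per individual required")
  for (l in seq_len(L)) {
    a1 <- genotypes[, 2L * l - 1L]; a2 <- genotypes[, 2L * l]
    if (any(is.na(a1) != is.na(a2)))
      stop("half-missing genotype at locus ", locus_names[l],
           ": both alleles must be present or both missing")
  }
  if (any(genotypes <= 0L, na.rm = TRUE))
    stop("repeat counts must be positive integers")
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(genotypes)))
  colnames(genotypes) <- paste0(rep(locus_names, each = 2L), ".", 1:2)
  structure(list(genotypes = genotypes, labels = as.character(labels),
                 locus_names = as.character(locus_names),
                 ids = as.character(ids)),
            class = "MicrosatDataset")
}

#' @export
print.MicrosatDataset <- function(x, ...) {
  cat("MicrosatDataset:", nrow(x$genotypes), "individuals x",
      length(x$locus_names), "loci,", length(unique(x$labels)),
      "populations\n")
  invisible(x)
}

#' Construct a population map
#'
#' Assigns each population to a subregion and records its per-marker
#' sample sizes.
#'
#' @param population character vector of population codes.
#' @param subregion character vector assigning each population to a
#'   subregion.
#' @param n_mt,n_msat integer sample sizes (mtDNA sequences / microsatellite
#'   individuals) per population.
#' @return A data.frame of class \code{PopulationMap}.
#' @export
population_map <- function(population, subregion, n_mt, n_msat) {
  if (anyDuplicated(population)) stop("duplicate population codes")
  if (any(n_mt < 0) || any(n_msat < 0)) stop("sample sizes must be >= 0")
  out <- data.frame(population = as.character(population),
                    subregion = as.character(subregion),
                    n_mt = as.integer(n_mt), n_msat = as.integer(n_msat),
                    stringsAsFactors = FALSE)
  class(out) <- c("PopulationMap", "data.frame")
  out
}

#' Construct a run configuration
#'
#' @param seed integer RNG seed for the whole run.
#' @param scenario_file,prior_file paths to scenario/prior text files
#'   (\code{NA} to use built-in presets/priors).
#' @param n_sim number of reference-table simulations.
#' @param tolerance rejection tolerance (fraction of simulations retained),
#'   in (0, 1].
#' @param out_dir output directory.
#' @param n_retained_min minimum retained simulations (floor applied to
#'   \code{tolerance * n_sim}).
#' @return A list of class \code{RunConfig}.
#' @export
run_config <- function(seed, scenario_file = NA, prior_file = NA,
                       n_sim = 30000L, tolerance = 0.01,
                       out_dir = "results", n_retained_min = 500L) {
  if (!(tolerance > 0 && tolerance <= 1)) stop("tolerance must be in (0, 1]")
  n_ret <- max(ceiling(tolerance * n_sim), n_retained_min)
  if (n_sim < n_ret || n_ret < 1L)
    stop("simulation count must be >= retained count >= 1")
  structure(list(seed = as.integer(seed), scenario_file = scenario_file,
                 prior_file = prior_file, n_sim = as.integer(n_sim),
                 tolerance = tolerance, out_dir = out_dir,
                 n_retained_min = as.integer(n_retained_min)),
            class = "RunConfig")
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form \code{key = value}; documented keys: \code{seed},
#' \code{n_sim}, \code{tolerance}, \code{scenario_set}, \code{priors},
#' \code{out_dir}.
#'
#' @param path file path.
#' @return A \code{RunConfig}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  run_config(seed = as.integer(get("seed", "1")),
             scenario_file = get("scenario_set", NA),
             prior_file = get("priors", NA),
             n_sim = as.integer(get("n_sim", "30000")),
             tolerance = as.numeric(get("tolerance", "0.01")),
             out_dir = get("out_dir", "results"))
}
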