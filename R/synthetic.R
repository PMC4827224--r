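# Study-design fixtures and pseudo-observed datasets (PODs).

#' The eight-population study design
#'
#' Eight populations in three subregions with the study's sample sizes
#' (mtDNA / microsatellite individuals): JO 13/13, HA 20/20, HY 9/9,
#' JX 23/23, CX 20/20, QH 24/23, BS 24/24, LD 24/24 - totals 157/156.
#' Populations pool into the four analysis demes ZF = \{JO, HA\},
#' PR = \{HY, JX, CX\}, NH = \{QH, BS\}, SH = \{LD\}.
#'
#' @param seq_length mtDNA locus length in bp (the study concatenation
#'   is 1887 bp; shorter lengths are used for desk-scale simulation).
#' @param n_loci number of microsatellite loci.
#' @return list of class \code{StudyDesign}: \code{popmap} (the
#'   eight-population \code{\link{population_map}}), \code{pooling}
#'   (population -> deme), \code{demes}, per-deme \code{n_mt} and
#'   \code{n_msat}, \code{seq_length}, \code{n_loci}.
#' @export
make_design <- function(seq_length = 1887L, n_loci = 13L) {
  pm <- population_map(
    population = c("JO", "HA", "HY", "JX", "CX", "QH", "BS", "LD"),
    subregion = c("ZF", "ZF", "PR", "PR", "PR", "NH", "NH", "SH"),
    n_mt = c(13L, 20L, 9L, 23L, 20L, 24L, 24L, 24L),
    n_msat = c(13L, 20L, 9L, 23L, 20L, 23L, 24L, 24L))
  pooling <- setNames(pm$subregion, pm$population)
  demes <- c("ZF", "PR", "NH", "SH")
  structure(list(
    popmap = pm, pooling = pooling, demes = demes,
    n_mt = vapply(demes, function(d) sum(pm$n_mt[pm$subregion == d]), 0L),
    n_msat = vapply(demes, function(d) sum(pm$n_msat[pm$subregion == d]), 0L),
    seq_length = as.integer(seq_length), n_loci = as.integer(n_loci)),
    class = "StudyDesign")
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat("StudyDesign: 8 populations -> demes",
      paste(x$demes, collapse = "/"),
      sprintf("(mtDNA n = %d, msat n = %d), %d bp + %d loci\n",
              sum(x$n_mt), sum(x$n_msat), x$seq_length, x$n_loci))
  invisible(x)
}

#' Generate pseudo-observed datasets with known truth
#'
#' Each POD draws a scenario (uniformly, or fixed via
#' \code{fixed_scenario}), draws its parameters from the priors
#' (optionally overridden), simulates a dataset, and records the truth.
#'
#' @param scenario_set named list of \code{Scenario}s.
#' @param priors a \code{PriorSpec}.
#' @param design study design.
#' @param n_pods number of PODs.
#' @param seed RNG seed; the whole PodSet is reproducible from it.
#' @param fixed_scenario optional scenario name to simulate all PODs
#'   under (recovery studies).
#' @param draw_override optional function(draw) -> draw applied to each
#'   parameter draw (e.g. to force informative values).
#' @return list of class \code{PodSet}; elements have \code{scenario},
#'   \code{draw}, \code{sim} (a \code{SimulatedDataset}) and
#'   \code{stats} (its summary vector).
#' @export
generate_pod <- function(scenario_set, priors, design = make_design(),
                         n_pods = 20L, seed = 1L,
                         fixed_scenario = NULL, draw_override = NULL) {
  set.seed(seed)
  names_set <- names(scenario_set)
  pods <- vector("list", n_pods)
  for (i in seq_len(n_pods)) {
    sc <- if (is.null(fixed_scenario)) sample(names_set, 1L) else fixed_scenario
    s <- scenario_set[[sc]]
    draw <- sample_parameters(s, priors)
    if (!is.null(draw_override)) draw <- draw_override(draw)
    sim <- simulate_dataset(s, draw, design)
    pods[[i]] <- list(scenario = sc, draw = draw, sim = sim,
                      stats = summary_vector_sim(sim))
  }
  structure(pods, class = "PodSet")
}

#' Hand-constructed worked-example datasets
#'
#' Tiny fixtures whose statistics are known by hand enumeration:
#' \itemize{
#'   \item \code{seqs}: two demes of two 10-bp sequences; Hudson F_ST
#'     between P1 = \{AAA...\}, P2 = \{TTT...\}-type pools equals 0.6.
#'   \item \code{seqs4}: four 100-bp sequences with 3 segregating sites,
#'     so Watterson's theta = 3 / (a_4 * 100) = 0.016364.
#'   \item \code{msat}: two demes of two diploids at two loci.
#' }
#'
#' @return list with elements \code{seqs}, \code{seqs4}, \code{msat}.
#' @export
worked_example_dataset <- function() {
  pad <- strrep("C", 7L)
  seqs <- sequence_dataset(
    c(paste0("AAA", pad), paste0("AAT", pad),
      paste0("TTT", pad), paste0("TTA", pad)),
    labels = c("P1", "P1", "P2", "P2"),
    ids = c("s1", "s2", "s3", "s4"))
  base <- strrep("A", 100L)
  s2 <- base; substr(s2, 1L, 1L) <- "G"
  s3 <- base; substr(s3, 2L, 2L) <- "G"
  s4 <- base; substr(s4, 3L, 3L) <- "G"
  seqs4 <- sequence_dataset(c(base, s2, s3, s4),
                            labels = rep("P1", 4L))
  geno <- rbind(c(10L, 12L, 20L, 20L),
                c(10L, 10L, 20L, 22L),
                c(14L, 16L, 24L, 24L),
                c(14L, 14L, 24L, 26L))
  msat <- microsat_dataset(geno, labels = c("P1", "P1", "P2", "P2"),
                           locus_names = c("loc1", "loc2"))
  list(seqs = seqs, seqs4 = seqs4, msat = msat)
}
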