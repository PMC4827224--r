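# R-side wrappers around the compiled coalescent core.  Conventions:
# deme size parameters N are diploid sizes; effective gene-copy numbers
# are N/4 for mtDNA (maternal haploid) and 2N for nuclear loci; times in
# generations; continuous-time (Kingman) approximation throughout.

#' HKY sequence mutation model
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freq stationary base frequencies (A, C, G, T), summing
#'   to 1.  The default is a typical fish mtDNA composition.
#' @param mu per-site per-generation substitution rate.
#' @param length locus length in bp.
#' @return list of class \code{SeqMutationModel} including the scaled
#'   rate matrix \code{Q} (mean rate 1) and its eigendecomposition.
#' @export
seq_mutation_model <- function(kappa = 4, base_freq = c(0.31, 0.26, 0.15, 0.28),
                               mu = 2e-8, length = 1887L) {
  stopifnot(kappa > 0, length(base_freq) == 4, all(base_freq > 0))
  base_freq <- base_freq / sum(base_freq)
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
          (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- if (ts) kappa * base_freq[j] else base_freq[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freq * diag(Q))
  Q <- Q / scale
  # reversible: symmetrize with sqrt(pi) for a stable eigendecomposition
  sp <- sqrt(base_freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(sp)
  structure(list(model = "HKY", kappa = kappa, base_freq = base_freq,
                 mu = mu, length = as.integer(length),
                 Q = Q, U = U, Uinv = Uinv, lambda = e$values),
            class = "SeqMutationModel")
}

#' Generalized stepwise microsatellite mutation model
#'
#' Mutations are Poisson on branches at rate \code{mu} per locus per
#' generation; each mutation steps the repeat count by \code{k*s} with
#' \code{s = +/-1} equiprobable and \code{k = 1} with probability
#' \code{1 - p_geom}, otherwise \code{1 + Geometric(p_geom)}.
#' \code{p_geom = 0} gives the strict single-step model.  Steps leaving
#' \code{range} are redrawn.
#'
#' @param mu per-locus per-generation mutation rate.
#' @param p_geom geometric step parameter in [0, 1).
#' @param range allowed repeat-count range.
#' @param root_allele repeat count at the genealogy root.
#' @return list of class \code{MsatMutationModel}.
#' @export
msat_mutation_model <- function(mu = 5e-4, p_geom = 0,
                                range = c(2L, 200L), root_allele = 100L) {
  stopifnot(mu > 0 || mu == 0, p_geom >= 0, p_geom < 1, range[1] < range[2])
  structure(list(mu = mu, p_geom = p_geom,
                 range = as.integer(range),
                 root_allele = as.integer(root_allele)),
            class = "MsatMutationModel")
}

# numeric event schedule for the compiled simulator
.event_schedule <- function(s, draw, marker = c("mtDNA", "nuclear")) {
  marker <- match.arg(marker)
  copies <- function(N) if (marker == "mtDNA") N / 4 else 2 * N
  deme_idx <- setNames(seq_len(nrow(s$demes)) - 1L, s$demes$name)
  sizes <- copies(unname(draw[s$demes$size_param]))
  if (anyNA(sizes)) stop("draw missing a deme size parameter")
  rows <- lapply(s$events, function(e) {
    tm <- unname(draw[e$time])
    if (is.na(tm)) stop("draw missing time parameter ", e$time)
    switch(e$kind,
      split = c(tm, 0, deme_idx[e$source], deme_idx[e$dest], -1, 0),
      admix = c(tm, 1, deme_idx[e$source], deme_idx[e$parent1],
                deme_idx[e$parent2], unname(draw[e$r])),
      resize = c(tm, 2, deme_idx[e$deme], -1, -1,
                 copies(unname(draw[e$size]))))
  })
  ev <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0L, 6L)
  ev <- ev[order(ev[, 1]), , drop = FALSE]   # stable sort keeps list order on ties
  list(sizes = sizes, events = ev, deme_idx = deme_idx)
}

#' Simulate one gene genealogy under a scenario
#'
#' Backward-in-time Kingman coalescent: pairwise coalescence rate
#' 1/(N/4) per generation for mtDNA and 1/(2N) for nuclear loci, with N
#' the deme's diploid size; splits move all lineages of the source deme
#' into the destination; admixture sends each lineage of the source to
#' parent1 with probability r, else parent2.
#'
#' @param s a \code{Scenario}.
#' @param draw named parameter vector (see \code{\link{sample_parameters}}).
#' @param marker \code{"mtDNA"} or \code{"nuclear"}.
#' @param n_per_deme named integer vector of sample sizes (gene copies)
#'   per sampled deme; zero-size demes allowed.
#' @return list of class \code{GeneGenealogy}: \code{parent} (0-based,
#'   -1 at the root), \code{node_time} (generations), \code{n_tips},
#'   \code{tip_deme} (deme name per tip).
#' @export
simulate_genealogy <- function(s, draw, marker = c("mtDNA", "nuclear"),
                               n_per_deme) {
  marker <- match.arg(marker)
  sched <- .event_schedule(s, draw, marker)
  if (is.null(names(n_per_deme)))
    stop("n_per_deme must be named by deme")
  unknown <- setdiff(names(n_per_deme), s$demes$name)
  if (length(unknown)) stop("unknown demes: ", paste(unknown, collapse = ", "))
  tip_deme <- rep(names(n_per_deme), times = n_per_deme)
  if (length(tip_deme) < 2L) stop("need at least 2 sampled lineages")
  g <- cpp_simulate_genealogy(unname(sched$deme_idx[tip_deme]),
                              sched$sizes, sched$events)
  structure(list(parent = g$parent, node_time = g$node_time,
                 n_tips = length(tip_deme), tip_deme = tip_deme),
            class = "GeneGenealogy")
}

#' Evolve sequences down a genealogy under HKY
#'
#' The root sequence is drawn site-wise from the stationary base
#' frequencies; each site then evolves independently along branches with
#' transition probabilities \eqn{P(t) = \exp(Q \mu t)} (Q scaled to mean
#' rate 1, so \eqn{\mu t} is the expected number of substitutions).
#'
#' @param g a \code{GeneGenealogy}.
#' @param model a \code{\link{seq_mutation_model}}.
#' @return integer matrix (tips x sites) of states 0..3 = A,C,G,T, with
#'   the tip demes as attribute \code{deme}.
#' @export
evolve_sequences <- function(g, model) {
  st <- cpp_evolve_sites(g$parent, g$node_time, g$n_tips, model$length,
                         model$U, model$Uinv, model$lambda,
                         model$base_freq, model$mu)
  attr(st, "deme") <- g$tip_deme
  st
}

#' Evolve a microsatellite locus down a genealogy
#'
#' @param g a \code{GeneGenealogy} (one locus; loci are freely
#'   recombining, so each gets its own genealogy).
#' @param model a \code{\link{msat_mutation_model}}.
#' @return integer vector of tip repeat counts.
#' @export
evolve_microsats <- function(g, model) {
  cpp_evolve_msat(g$parent, g$node_time, g$n_tips, model$root_allele,
                  model$mu, model$p_geom, model$range[1], model$range[2])
}

#' Simulate a full two-marker dataset under a scenario
#'
#' One mtDNA genealogy plus \code{design$n_loci} independent nuclear
#' genealogies, mutated and packaged with deme labels.  Diploid
#' genotypes are formed by random pairing of the 2n gene copies within
#' each deme.  Mutation-model hyperparameters are taken from the draw
#' when present (\code{mu_seq}, \code{kappa}, \code{mu_msat},
#' \code{p_geom}).
#'
#' @param s a \code{Scenario}.
#' @param draw named parameter vector.
#' @param design study design from \code{\link{make_design}}.
#' @param seed optional RNG seed (fully reproducible when set).
#' @return list of class \code{SimulatedDataset}: \code{seq_states}
#'   (n_mt x L integer matrix), \code{seq_deme}, \code{msat} (n_msat x
#'   2*n_loci integer matrix), \code{msat_deme}.  Convert with
#'   \code{\link{as_sequence_dataset}} / \code{\link{as_microsat_dataset}}.
#' @export
simulate_dataset <- function(s, draw, design = make_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqmod <- seq_mutation_model(
    kappa = if ("kappa" %in% names(draw)) draw[["kappa"]] else 4,
    mu = if ("mu_seq" %in% names(draw)) draw[["mu_seq"]] else 2e-8,
    length = design$seq_length)
  msatmod <- msat_mutation_model(
    mu = if ("mu_msat" %in% names(draw)) draw[["mu_msat"]] else 5e-4,
    p_geom = if ("p_geom" %in% names(draw)) draw[["p_geom"]] else 0)

  sched_mt <- .event_schedule(s, draw, "mtDNA")
  sched_nuc <- .event_schedule(s, draw, "nuclear")
  deme_idx <- sched_mt$deme_idx

  tip_mt <- rep(unname(deme_idx[design$demes]), times = design$n_mt)
  g_mt <- cpp_simulate_genealogy(tip_mt, sched_mt$sizes, sched_mt$events)
  seq_states <- cpp_evolve_sites(g_mt$parent, g_mt$node_time,
                                 length(tip_mt), seqmod$length,
                                 seqmod$U, seqmod$Uinv, seqmod$lambda,
                                 seqmod$base_freq, seqmod$mu)

  n_copies <- 2L * design$n_msat
  tip_nuc <- rep(unname(deme_idx[design$demes]), times = n_copies)
  n_ind <- sum(design$n_msat)
  msat <- matrix(NA_integer_, n_ind, 2L * design$n_loci)
  copy0 <- cumsum(c(0L, n_copies))
  row0 <- cumsum(c(0L, design$n_msat))
  for (l in seq_len(design$n_loci)) {
    g <- cpp_simulate_genealogy(tip_nuc, sched_nuc$sizes, sched_nuc$events)
    alleles <- cpp_evolve_msat(g$parent, g$node_time, length(tip_nuc),
                               msatmod$root_allele, msatmod$mu,
                               msatmod$p_geom, msatmod$range[1],
                               msatmod$range[2])
    # random pairing of gene copies into diploids within each deme
    for (d in seq_along(design$demes)) {
      nc <- n_copies[d]
      if (nc == 0L) next
      a <- alleles[copy0[d] + sample.int(nc)]
      idx <- row0[d] + seq_len(nc %/% 2L)
      msat[idx, 2L * l - 1L] <- a[seq(1L, nc, by = 2L)]
      msat[idx, 2L * l] <- a[seq(2L, nc, by = 2L)]
    }
  }
  structure(list(seq_states = seq_states,
                 seq_deme = rep(design$demes, times = design$n_mt),
                 msat = msat,
                 msat_deme = rep(design$demes, times = design$n_msat),
                 design = design),
            class = "SimulatedDataset")
}

#' Convert simulated sequence states to a SequenceDataset
#'
#' @param sim a \code{SimulatedDataset} (or an integer state matrix with
#'   a \code{deme} attribute).
#' @return a \code{\link{sequence_dataset}}.
#' @export
as_sequence_dataset <- function(sim) {
  if (inherits(sim, "SimulatedDataset")) {
    states <- sim$seq_states; labels <- sim$seq_deme
  } else {
    states <- sim; labels <- attr(sim, "deme")
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states, 1L, function(row) paste(bases[row + 1L], collapse = ""))
  sequence_dataset(seqs, labels)
}

#' Convert simulated microsatellite alleles to a MicrosatDataset
#'
#' @param sim a \code{SimulatedDataset}.
#' @return a \code{\link{microsat_dataset}}.
#' @export
as_microsat_dataset <- function(sim) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  L <- ncol(sim$msat) / 2L
  microsat_dataset(sim$msat, sim$msat_deme,
                   locus_names = paste0("Gar", seq_len(L)))
}
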