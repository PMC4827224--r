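# Microsatellite statistics.  All statistics use per-locus complete-case
# sample sizes: an individual enters a locus's computation only if both
# alleles are called there.

# per-locus allele count table for a set of rows; returns named integer
# vector of allele copy counts (complete-case gene copies)
.locus_alleles <- function(geno, rows, locus) {
  a1 <- geno[rows, 2L * locus - 1L]; a2 <- geno[rows, 2L * locus]
  ok <- !is.na(a1)
  table(c(a1[ok], a2[ok]))
}

#' Hypergeometric rarefaction of allele counts (allelic richness)
#'
#' Expected number of distinct alleles in a subsample of \code{g} gene
#' copies: \eqn{A_R(g) = \sum_a [1 - C(N - N_a, g) / C(N, g)]}.
#'
#' @param counts integer vector of allele copy counts at one locus.
#' @param g rarefaction size in gene copies (g <= sum(counts)).
#' @return expected allele count.
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction size g exceeds the gene-copy count")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

# unbiased expected heterozygosity from allele counts
.unbiased_he <- function(counts) {
  n2 <- sum(counts)                      # gene copies = 2n
  if (n2 < 2) return(NA_real_)
  p <- counts / n2
  (n2 / (n2 - 1)) * (1 - sum(p^2))
}

# Weir & Cockerham variance components for one locus over r populations.
# geno: full genotype matrix; pops: list of row-index vectors.
# Returns 3-col matrix (a, b, c), one row per allele.
.wc_components <- function(geno, pops, locus) {
  r <- length(pops)
  al <- lapply(pops, function(rows) {
    a1 <- geno[rows, 2L * locus - 1L]; a2 <- geno[rows, 2L * locus]
    ok <- !is.na(a1)
    list(a1 = a1[ok], a2 = a2[ok])
  })
  n_i <- vapply(al, function(x) length(x$a1), 0)
  if (any(n_i < 1L)) return(NULL)
  alleles <- sort(unique(unlist(lapply(al, function(x) c(x$a1, x$a2)))))
  if (length(alleles) < 2L) return(NULL)   # monomorphic: no information
  nbar <- mean(n_i)
  rn <- r * nbar
  nc <- if (r > 1L) (rn - sum(n_i^2) / rn) / (r - 1) else NA_real_
  out <- matrix(0, length(alleles), 3L,
                dimnames = list(alleles, c("a", "b", "c")))
  for (k in seq_along(alleles)) {
    A <- alleles[k]
    p_i <- vapply(al, function(x)
      (sum(x$a1 == A) + sum(x$a2 == A)) / (2 * length(x$a1)), 0)
    h_i <- vapply(al, function(x)
      sum((x$a1 == A) != (x$a2 == A)) / length(x$a1), 0)
    pbar <- sum(n_i * p_i) / rn
    hbar <- sum(n_i * h_i) / rn
    s2 <- if (r > 1L) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
    b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a <- if (r > 1L)
      (nbar / nc) * (s2 - (1 / (nbar - 1)) * (inner - hbar / 4))
    else 0
    out[k, ] <- c(a, b, cc)
  }
  out
}

#' Weir & Cockerham's F_ST (theta) between two populations
#'
#' Multilocus theta combined as the ratio of summed variance components
#' over alleles and loci: \eqn{\theta = \sum a / \sum (a + b + c)}.
#'
#' @param data a \code{\link{microsat_dataset}}.
#' @param popA,popB population labels.
#' @return theta.
#' @export
wc_fst <- function(data, popA, popB) {
  geno <- data$genotypes
  pops <- list(which(data$labels == popA), which(data$labels == popB))
  if (any(lengths(pops) < 2L))
    stop("both populations need n >= 2")
  comp <- lapply(seq_along(data$locus_names), function(l)
    .wc_components(geno, pops, l))
  comp <- do.call(rbind, comp[!vapply(comp, is.null, TRUE)])
  if (is.null(comp) || nrow(comp) == 0L)
    stop("undefined statistic: no polymorphic locus")
  sum(comp[, "a"]) / sum(comp)
}

#' Per-population microsatellite diversity panel
#'
#' For each population: mean alleles per locus (A), rarefied allelic
#' richness A_R(g), observed and unbiased expected heterozygosity, the
#' multilocus Weir & Cockerham within-population f (F_IS), and private
#' vs shared allele tallies.
#'
#' @param data a \code{\link{microsat_dataset}}.
#' @param g rarefaction size in gene copies; default: the smallest
#'   per-locus complete-case gene-copy count over populations and loci.
#' @return A data.frame of class \code{MsatDiversityPanel} with one row
#'   per population and attribute \code{g} recording the rarefaction
#'   size used.
#' @export
msat_diversity_panel <- function(data, g = NULL) {
  geno <- data$genotypes
  pops <- unique(data$labels)
  L <- length(data$locus_names)
  rows_of <- lapply(pops, function(p) which(data$labels == p))
  names(rows_of) <- pops

  copy_counts <- unlist(lapply(rows_of, function(rows)
    vapply(seq_len(L), function(l) sum(.locus_alleles(geno, rows, l)), 0)))
  if (is.null(g)) g <- min(copy_counts[copy_counts > 0])
  if (g < 1) stop("rarefaction size must be >= 1")

  # allele presence per pop/locus for private-allele tallies
  presence <- lapply(seq_len(L), function(l)
    lapply(rows_of, function(rows) names(.locus_alleles(geno, rows, l))))

  out <- do.call(rbind, lapply(pops, function(p) {
    rows <- rows_of[[p]]
    per_locus <- lapply(seq_len(L), function(l) .locus_alleles(geno, rows, l))
    n_all <- vapply(per_locus, function(ct) length(ct[ct > 0]), 0)
    ar <- vapply(per_locus, function(ct) {
      if (sum(ct) < g) return(NA_real_)
      allelic_richness(ct, g)
    }, 0)
    he <- vapply(per_locus, .unbiased_he, 0)
    ho <- vapply(seq_len(L), function(l) {
      a1 <- geno[rows, 2L * l - 1L]; a2 <- geno[rows, 2L * l]
      ok <- !is.na(a1)
      if (!any(ok)) return(NA_real_)
      mean(a1[ok] != a2[ok])
    }, 0)
    comp <- lapply(seq_len(L), function(l) .wc_components(geno, list(rows), l))
    comp <- do.call(rbind, comp[!vapply(comp, is.null, TRUE)])
    fis <- if (is.null(comp) || nrow(comp) == 0L) NA_real_
           else 1 - sum(comp[, "c"]) / sum(comp[, "b"] + comp[, "c"])
    priv <- sum(vapply(seq_len(L), function(l) {
      mine <- presence[[l]][[p]]
      others <- unique(unlist(presence[[l]][setdiff(pops, p)]))
      sum(!(mine %in% others))
    }, 0))
    shared <- sum(vapply(seq_len(L), function(l) {
      mine <- presence[[l]][[p]]
      others <- unique(unlist(presence[[l]][setdiff(pops, p)]))
      sum(mine %in% others)
    }, 0))
    data.frame(population = p, n = length(rows),
               A = mean(n_all), A_R = mean(ar, na.rm = TRUE),
               H_O = mean(ho, na.rm = TRUE), H_E = mean(he, na.rm = TRUE),
               F_IS = fis, private_alleles = priv, shared_alleles = shared,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "g") <- g
  class(out) <- c("MsatDiversityPanel", "data.frame")
  out
}

#' Nei's D_A genetic distance between two populations
#'
#' \eqn{D_A = 1 - \frac{1}{L} \sum_{loci} \sum_{alleles} \sqrt{x_a y_a}}
#' over the loci typed in both populations.
#'
#' @param data a \code{\link{microsat_dataset}}.
#' @param popA,popB population labels.
#' @return D_A in [0, 1].
#' @export
da_distance <- function(data, popA, popB) {
  geno <- data$genotypes
  ra <- which(data$labels == popA); rb <- which(data$labels == popB)
  L <- length(data$locus_names)
  terms <- vapply(seq_len(L), function(l) {
    ca <- .locus_alleles(geno, ra, l); cb <- .locus_alleles(geno, rb, l)
    if (sum(ca) == 0 || sum(cb) == 0) return(NA_real_)
    alleles <- union(names(ca), names(cb))
    x <- as.numeric(ca[alleles]) / sum(ca); x[is.na(x)] <- 0
    y <- as.numeric(cb[alleles]) / sum(cb); y[is.na(y)] <- 0
    sum(sqrt(x * y))
  }, 0)
  if (all(is.na(terms))) stop("no locus typed in both populations")
  1 - mean(terms, na.rm = TRUE)
}
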