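# Site-based mtDNA statistics.  All of them operate on the "included"
# sites only: any alignment column containing N or '-' in any sequence is
# excluded (complete deletion), so every statistic is deterministic and
# order-independent.

.BASES <- c("A", "C", "G", "T", "N", "-")

# integer matrix coding: A=1 C=2 G=3 T=4 N=5 gap=6
.seq_matrix <- function(x) {
  stopifnot(inherits(x, "SequenceDataset"))
  chars <- strsplit(x$sequences, "", fixed = TRUE)
  m <- matrix(match(unlist(chars, use.names = FALSE), .BASES),
              nrow = length(x$sequences), byrow = TRUE)
  m
}

.included_sites <- function(m) {
  which(colSums(m > 4L) == 0L)
}

# per-site state counts (4 x L) for a set of rows
.site_counts <- function(m, rows) {
  sub <- m[rows, , drop = FALSE]
  vapply(1:4, function(s) colSums(sub == s), numeric(ncol(m)))
}

#' Collapse an alignment into haplotypes
#'
#' Sequences identical over the included sites (complete deletion of
#' columns containing N or gaps) share one haplotype.  A haplotype is
#' \emph{shared} if present in two or more populations, \emph{private}
#' otherwise.
#'
#' @param seqs a \code{\link{sequence_dataset}}.
#' @return A list of class \code{HaplotypeTable}: \code{counts}
#'   (haplotype x population copy-count matrix), \code{representative}
#'   (one full-length sequence per haplotype), \code{shared} (logical),
#'   \code{n_segregating} (count of segregating included sites).
#' @export
collapse_haplotypes <- function(seqs) {
  m <- .seq_matrix(seqs)
  incl <- .included_sites(m)
  if (length(incl) == 0L) stop("no included sites: every column contains N or a gap")
  key <- apply(m[, incl, drop = FALSE], 1L, paste, collapse = "")
  hap <- match(key, unique(key))
  pops <- unique(seqs$labels)
  counts <- table(factor(hap, levels = seq_len(max(hap))),
                  factor(seqs$labels, levels = pops))
  counts <- matrix(as.integer(counts), nrow = max(hap),
                   dimnames = list(paste0("H", seq_len(max(hap))), pops))
  seg <- sum(vapply(incl, function(s) length(unique(m[, s])) > 1L, TRUE))
  structure(list(counts = counts,
                 representative = seqs$sequences[match(seq_len(max(hap)), hap)],
                 shared = rowSums(counts > 0L) >= 2L,
                 n_segregating = seg,
                 hap_index = hap, included_sites = incl),
            class = "HaplotypeTable")
}

#' Nei's unbiased haplotype (gene) diversity
#'
#' \eqn{h = n (1 - \sum p_i^2) / (n - 1)} over haplotype copy counts.
#'
#' @param counts integer vector of per-haplotype copy numbers (n >= 2).
#' @return h in [0, 1].
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("undefined statistic: haplotype diversity needs n >= 2")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

# mean pairwise difference per included site among rows; internal core
.pi_rows <- function(m, rows, incl) {
  n <- length(rows)
  cnt <- .site_counts(m[, incl, drop = FALSE], rows)  # L x 4
  sum((n^2 - rowSums(cnt^2)) / (n * (n - 1))) / length(incl)
}

#' Nucleotide diversity (theta-pi) per site
#'
#' Mean proportion of differing included sites over all sequence pairs;
#' the "current diversity" estimator.
#'
#' @param seqs a \code{SequenceDataset}.
#' @param population restrict to one population (default: all sequences).
#' @return theta-pi per site.
#' @export
nucleotide_diversity_pi <- function(seqs, population = NULL) {
  m <- .seq_matrix(seqs)
  incl <- .included_sites(m)
  rows <- if (is.null(population)) seq_len(nrow(m)) else which(seqs$labels == population)
  if (length(rows) < 2L) stop("undefined statistic: theta-pi needs n >= 2")
  if (length(incl) == 0L) stop("no included sites")
  .pi_rows(m, rows, incl)
}

#' Watterson's theta per site
#'
#' \eqn{\theta_\omega = S / (a_n L)} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i};
#' the "historical diversity" estimator.
#'
#' @inheritParams nucleotide_diversity_pi
#' @return theta-w per site.
#' @export
watterson_theta <- function(seqs, population = NULL) {
  m <- .seq_matrix(seqs)
  incl <- .included_sites(m)
  rows <- if (is.null(population)) seq_len(nrow(m)) else which(seqs$labels == population)
  n <- length(rows)
  if (n < 2L) stop("undefined statistic: theta-w needs n >= 2")
  if (length(incl) == 0L) stop("no included sites")
  sub <- m[rows, incl, drop = FALSE]
  S <- sum(vapply(seq_len(ncol(sub)),
                  function(s) length(unique(sub[, s])) > 1L, TRUE))
  S / (sum(1 / seq_len(n - 1L)) * length(incl))
}

#' Hudson's F_ST between two populations
#'
#' The Hudson-Slatkin-Maddison estimator \eqn{F_{ST} = 1 - H_w / H_b}
#' with \eqn{H_w} the unweighted mean of the two within-population mean
#' pairwise differences and \eqn{H_b} the mean between-population
#' pairwise difference.  Negative estimates are reported as computed.
#'
#' @param seqs a \code{SequenceDataset}.
#' @param popA,popB population labels.
#' @return F_ST (<= 1).
#' @export
hudson_fst <- function(seqs, popA, popB) {
  m <- .seq_matrix(seqs)
  incl <- .included_sites(m)
  ra <- which(seqs$labels == popA); rb <- which(seqs$labels == popB)
  if (length(ra) < 2L || length(rb) < 2L)
    stop("undefined statistic: both populations need n >= 2")
  hw <- (.pi_rows(m, ra, incl) + .pi_rows(m, rb, incl)) / 2
  ca <- .site_counts(m[, incl, drop = FALSE], ra)
  cb <- .site_counts(m[, incl, drop = FALSE], rb)
  na <- length(ra); nb <- length(rb)
  hb <- sum((na * nb - rowSums(ca * cb)) / (na * nb)) / length(incl)
  if (hb == 0) stop("undefined statistic: between-population diversity is zero")
  1 - hw / hb
}

#' Kimura two-parameter distance between two sequences
#'
#' \eqn{d = -\frac12 \ln(1 - 2P - Q) - \frac14 \ln(1 - 2Q)} with P and Q
#' the proportions of transitional and transversional differences over
#' sites where both sequences carry an unambiguous base.
#'
#' @param seq1,seq2 nucleotide strings of equal length.
#' @return K2P distance (substitutions/site).
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- match(strsplit(toupper(seq1), "")[[1L]], .BASES)
  b <- match(strsplit(toupper(seq2), "")[[1L]], .BASES)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ok <- a <= 4L & b <= 4L
  if (!any(ok)) stop("no overlapping included sites")
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  diff <- a != b
  # transitions: A<->G (1,3) and C<->T (2,4)
  ts <- diff & ((pmin(a, b) == 1L & pmax(a, b) == 3L) |
                (pmin(a, b) == 2L & pmax(a, b) == 4L))
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("K2P saturation: log argument <= 0")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Mean between-group K2P distance
#'
#' Mean of \code{\link{k2p_distance}} over all pairs with one sequence in
#' each group.
#'
#' @param seqs a \code{SequenceDataset}.
#' @param groupA,groupB vectors of population labels defining the groups.
#' @return mean between-group distance.
#' @export
mean_group_k2p <- function(seqs, groupA, groupB) {
  ra <- which(seqs$labels %in% groupA); rb <- which(seqs$labels %in% groupB)
  if (length(ra) == 0L || length(rb) == 0L) stop("empty group")
  vals <- outer(ra, rb, Vectorize(function(i, j)
    k2p_distance(seqs$sequences[i], seqs$sequences[j])))
  mean(vals)
}

#' Pons & Petit G_ST and N_ST
#'
#' Sample-size-corrected differentiation estimators: G_ST uses haplotype
#' identity only; N_ST weights haplotype pairs by their distances (here
#' typically K2P), so N_ST >> G_ST signals phylogeographic structure.
#' Both are \eqn{1 - v_S / v_T} where \eqn{v_S} is the unweighted mean of
#' the per-population unbiased diversities
#' \eqn{v_k = \frac{n_k}{n_k-1}\sum_{ij} p_{ik} p_{jk} \pi_{ij}}
#' and \eqn{v_T = \sum_{ij} \bar p_i \bar p_j \pi_{ij} +
#' \frac{1}{K^2}\sum_k v_k / n_k}, an unbiased total-diversity estimator
#' (the correction term reduces to \eqn{v_S/(K\tilde n)} with
#' \eqn{\tilde n} the harmonic mean size when sizes and diversities are
#' equal).
#'
#' @param table a \code{HaplotypeTable} from \code{\link{collapse_haplotypes}}.
#' @param distances haplotype-by-haplotype distance matrix for N_ST
#'   (e.g., pairwise K2P between representatives).  If \code{NULL}, only
#'   G_ST is meaningful and N_ST equals it.
#' @return list with elements \code{G_ST} and \code{N_ST}.
#' @export
gst_nst <- function(table, distances = NULL) {
  counts <- table$counts
  keep <- colSums(counts) >= 2L
  counts <- counts[, keep, drop = FALSE]
  K <- ncol(counts)
  if (K < 2L) stop("need >= 2 populations with n >= 2")
  H <- nrow(counts)
  if (is.null(distances)) distances <- 1 - diag(H)
  distances <- as.matrix(distances)
  stopifnot(nrow(distances) == H, ncol(distances) == H)

  one_index <- function(D) {
    n_k <- colSums(counts)
    P <- sweep(counts, 2L, n_k, "/")
    v_k <- vapply(seq_len(K), function(k) {
      p <- P[, k]
      (n_k[k] / (n_k[k] - 1)) * drop(t(p) %*% D %*% p)
    }, 0)
    v_S <- mean(v_k)
    pbar <- rowMeans(P)
    v_T <- drop(t(pbar) %*% D %*% pbar) + sum(v_k / n_k) / K^2
    if (v_T <= 0) stop("undefined statistic: total diversity is zero")
    1 - v_S / v_T
  }
  list(G_ST = one_index(1 - diag(H)), N_ST = one_index(distances))
}

#' Brito's nuclear-equivalent F_ST correction
#'
#' Maps a mitochondrial differentiation value onto the nuclear scale:
#' \eqn{F_{ST}(nuc) = F_{ST}(mt) / (4 - 3 F_{ST}(mt))}, accounting for
#' the four-fold effective-size difference between the markers.
#' Monotone increasing on [0, 1] with fixed points 0 and 1.
#'
#' @param fst_mt mitochondrial F_ST in [0, 1].
#' @return the expected nuclear-scale F_ST.
#' @export
brito_correction <- function(fst_mt) {
  if (any(fst_mt < 0 | fst_mt > 1)) stop("F_ST(mt) must be in [0, 1]")
  fst_mt / (4 - 3 * fst_mt)
}

#' Divergence time from a molecular clock
#'
#' \code{time = d / rate}; the conventional calibration here is a
#' divergence rate of 2.00\% per million years (rate = 0.02).
#'
#' @param d per-site between-lineage distance (e.g. mean K2P).
#' @param rate divergence per million years (> 0).
#' @return time in millions of years.
#' @export
divergence_time <- function(d, rate = 0.02) {
  if (rate <= 0) stop("rate must be > 0")
  if (any(d < 0)) stop("distance must be >= 0")
  d / rate
}
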