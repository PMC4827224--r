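# ABC summary vector.  Fixed order and length for a given design:
#   mtDNA per deme:       number of haplotypes, S, h, theta-pi (per site)
#   mtDNA per deme pair:  Hudson F_ST, mean between-deme differences/site
#   msat per deme:        mean A, mean unbiased H_E, mean allele-size
#                         variance, mean Garza-Williamson M
#   msat per deme pair:   Weir-Cockerham theta, (delta mu)^2
# Undefined entries are imputed as 0 and flagged in the "defined"
# attribute; flagged channels are excluded from ABC distances.

summary_vector_names <- function(demes) {
  prs <- utils::combn(demes, 2L)
  pair <- paste0(prs[1L, ], "_", prs[2L, ])
  c(paste0("mt_nhap_", demes), paste0("mt_S_", demes),
    paste0("mt_h_", demes), paste0("mt_pi_", demes),
    paste0("mt_fst_", pair), paste0("mt_dxy_", pair),
    paste0("ms_A_", demes), paste0("ms_He_", demes),
    paste0("ms_var_", demes), paste0("ms_M_", demes),
    paste0("ms_fst_", pair), paste0("ms_dmu2_", pair))
}

# fast per-deme mtDNA stats from an integer state matrix (values 0..3)
.mt_deme_stats <- function(states, rows) {
  n <- length(rows)
  L <- ncol(states)
  cnt <- vapply(0:3, function(s) colSums(states[rows, , drop = FALSE] == s),
                numeric(L))
  sq <- rowSums(cnt^2)
  S <- sum(sq < n^2)                        # segregating sites
  pi <- sum((n^2 - sq) / (n * (n - 1))) / L
  var_sites <- which(sq < n^2)
  if (length(var_sites) == 0L) { nhap <- 1L; h <- 0 }
  else {
    key <- apply(states[rows, var_sites, drop = FALSE], 1L, paste,
                 collapse = "")
    tab <- table(key)
    nhap <- length(tab)
    p <- as.numeric(tab) / n
    h <- n * (1 - sum(p^2)) / (n - 1)
  }
  list(nhap = nhap, S = S, h = h, pi = pi, cnt = cnt, n = n)
}

# fast Weir-Cockerham components for one locus, two populations
# (a1x,a2x / a1y,a2y: complete-case allele vectors)
.wc_pair_locus <- function(a1x, a2x, a1y, a2y) {
  alleles <- unique(c(a1x, a2x, a1y, a2y))
  if (length(alleles) < 2L) return(c(0, 0))
  nA <- length(alleles)
  n_i <- c(length(a1x), length(a1y))
  m1x <- match(a1x, alleles); m2x <- match(a2x, alleles)
  m1y <- match(a1y, alleles); m2y <- match(a2y, alleles)
  cx <- tabulate(m1x, nA) + tabulate(m2x, nA)
  cy <- tabulate(m1y, nA) + tabulate(m2y, nA)
  hx <- tabulate(m1x[m1x != m2x], nA) + tabulate(m2x[m1x != m2x], nA)
  hy <- tabulate(m1y[m1y != m2y], nA) + tabulate(m2y[m1y != m2y], nA)
  p <- rbind(cx / (2 * n_i[1]), cy / (2 * n_i[2]))
  h <- rbind(hx / n_i[1], hy / n_i[2])
  r <- 2
  nbar <- mean(n_i); rn <- r * nbar
  nc <- (rn - sum(n_i^2) / rn) / (r - 1)
  pbar <- colSums(n_i * p) / rn
  hbar <- colSums(n_i * h) / rn
  s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
  a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(sum(a), sum(a + b + cc))
}

# compiled fast path: requires complete data (no NA) and >= 1 individual
# per deme; produces the same values as the R route below
.summary_vector_cpp <- function(seq_states, seq_deme, msat, msat_deme,
                                demes) {
  nm <- summary_vector_names(demes)
  v <- setNames(numeric(length(nm)), nm)
  def <- setNames(rep(TRUE, length(nm)), nm)
  D <- length(demes)
  di_mt <- match(seq_deme, demes) - 1L
  di_ms <- match(msat_deme, demes) - 1L
  mt <- cpp_mt_stats(seq_states, di_mt, D)
  ms <- cpp_msat_stats(msat, di_ms, D, min(msat), max(msat))
  v[paste0("mt_nhap_", demes)] <- mt$per_deme[, 1L]
  v[paste0("mt_S_", demes)] <- mt$per_deme[, 2L]
  v[paste0("mt_h_", demes)] <- mt$per_deme[, 3L]
  v[paste0("mt_pi_", demes)] <- mt$per_deme[, 4L]
  prs <- utils::combn(demes, 2L)
  pair <- paste0(prs[1L, ], "_", prs[2L, ])
  v[paste0("mt_fst_", pair)] <- mt$pairs[, 1L]
  def[paste0("mt_fst_", pair)] <- mt$fst_defined
  v[paste0("mt_dxy_", pair)] <- mt$pairs[, 2L]
  v[paste0("ms_A_", demes)] <- ms$per_deme[, 1L]
  v[paste0("ms_He_", demes)] <- ms$per_deme[, 2L]
  v[paste0("ms_var_", demes)] <- ms$per_deme[, 3L]
  v[paste0("ms_M_", demes)] <- ms$per_deme[, 4L]
  v[paste0("ms_fst_", pair)] <- ms$pairs[, 1L]
  def[paste0("ms_fst_", pair)] <- ms$fst_defined
  v[paste0("ms_dmu2_", pair)] <- ms$pairs[, 2L]
  def[paste0("ms_dmu2_", pair)] <- ms$dmu_defined
  v[!def] <- 0
  attr(v, "defined") <- def
  v
}

# internal reference path over a SimulatedDataset (or equivalent matrices)
.summary_vector_core <- function(seq_states, seq_deme, msat, msat_deme,
                                 demes, range_lo = 2L) {
  nm <- summary_vector_names(demes)
  v <- setNames(numeric(length(nm)), nm)
  def <- setNames(rep(TRUE, length(nm)), nm)
  D <- length(demes)
  rows_mt <- lapply(demes, function(d) which(seq_deme == d))
  st <- lapply(rows_mt, function(r) .mt_deme_stats(seq_states, r))
  for (i in seq_len(D)) {
    d <- demes[i]
    v[paste0("mt_nhap_", d)] <- st[[i]]$nhap
    v[paste0("mt_S_", d)] <- st[[i]]$S
    v[paste0("mt_h_", d)] <- st[[i]]$h
    v[paste0("mt_pi_", d)] <- st[[i]]$pi
  }
  L <- ncol(seq_states)
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D) {
    pair <- paste0(demes[i], "_", demes[j])
    ci <- st[[i]]$cnt; cj <- st[[j]]$cnt
    ni <- st[[i]]$n; nj <- st[[j]]$n
    dxy <- sum((ni * nj - rowSums(ci * cj)) / (ni * nj)) / L
    v[paste0("mt_dxy_", pair)] <- dxy
    hw <- (st[[i]]$pi + st[[j]]$pi) / 2
    if (dxy > 0) v[paste0("mt_fst_", pair)] <- 1 - hw / dxy
    else def[paste0("mt_fst_", pair)] <- FALSE
  }

  n_loci <- ncol(msat) / 2L
  rows_ms <- lapply(demes, function(d) which(msat_deme == d))
  # per-deme per-locus allele vectors (complete case)
  av <- lapply(rows_ms, function(rows) lapply(seq_len(n_loci), function(l) {
    a1 <- msat[rows, 2L * l - 1L]; a2 <- msat[rows, 2L * l]
    ok <- !is.na(a1)
    list(a1 = a1[ok], a2 = a2[ok])
  }))
  for (i in seq_len(D)) {
    d <- demes[i]
    per <- vapply(av[[i]], function(x) {
      all_a <- c(x$a1, x$a2)
      if (length(all_a) == 0L) return(c(NA, NA, NA, NA))
      tab <- table(all_a)
      n2 <- length(all_a)
      he <- if (n2 >= 2) (n2 / (n2 - 1)) * (1 - sum((tab / n2)^2)) else NA
      va <- if (n2 >= 2) var(all_a) else NA
      rng <- diff(range(all_a))
      c(length(tab), he, va, length(tab) / (rng + 1))
    }, numeric(4))
    v[paste0("ms_A_", d)] <- mean(per[1L, ], na.rm = TRUE)
    v[paste0("ms_He_", d)] <- mean(per[2L, ], na.rm = TRUE)
    v[paste0("ms_var_", d)] <- mean(per[3L, ], na.rm = TRUE)
    v[paste0("ms_M_", d)] <- mean(per[4L, ], na.rm = TRUE)
  }
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D) {
    pair <- paste0(demes[i], "_", demes[j])
    num <- 0; den <- 0; dmu2 <- 0; n_dmu <- 0L
    for (l in seq_len(n_loci)) {
      x <- av[[i]][[l]]; y <- av[[j]][[l]]
      if (length(x$a1) < 2L || length(y$a1) < 2L) next
      ab <- .wc_pair_locus(x$a1, x$a2, y$a1, y$a2)
      num <- num + ab[1L]; den <- den + ab[2L]
      dmu2 <- dmu2 + (mean(c(x$a1, x$a2)) - mean(c(y$a1, y$a2)))^2
      n_dmu <- n_dmu + 1L
    }
    if (den > 0) v[paste0("ms_fst_", pair)] <- num / den
    else def[paste0("ms_fst_", pair)] <- FALSE
    if (n_dmu > 0) v[paste0("ms_dmu2_", pair)] <- dmu2 / n_dmu
    else def[paste0("ms_dmu2_", pair)] <- FALSE
  }
  v[!def] <- 0
  v[!is.finite(v)] <- 0
  attr(v, "defined") <- def
  v
}

#' Assemble the ABC summary-statistic vector for one dataset
#'
#' Fixed-order, fixed-length named vector combining mtDNA and
#' microsatellite one-sample and two-sample statistics (see package
#' vignette for the exact panel).  Undefined statistics are imputed as 0
#' and flagged via the \code{defined} attribute, which downstream ABC
#' distance computations use to drop them.
#'
#' @param seqs a \code{SequenceDataset} whose labels are the design's
#'   demes, or \code{NULL} to produce the microsatellite block only.
#' @param msat a \code{MicrosatDataset} labelled by deme, or \code{NULL}
#'   for the mtDNA block only.
#' @param design study design (\code{\link{make_design}}).
#' @return named numeric vector with logical attribute \code{defined}.
#' @export
summary_vector <- function(seqs, msat, design = make_design()) {
  demes <- design$demes
  if (!is.null(seqs)) {
    bad <- setdiff(unique(seqs$labels), demes)
    if (length(bad))
      stop("design mismatch: unknown sequence demes ",
           paste(bad, collapse = ", "))
    m <- .seq_matrix(seqs)
    incl <- .included_sites(m)
    seq_states <- m[, incl, drop = FALSE] - 1L
    seq_deme <- seqs$labels
  } else {
    seq_states <- matrix(0L, length(demes) * 2L, 1L)
    seq_deme <- rep(demes, each = 2L)
  }
  if (!is.null(msat)) {
    bad <- setdiff(unique(msat$labels), demes)
    if (length(bad))
      stop("design mismatch: unknown microsatellite demes ",
           paste(bad, collapse = ", "))
    ms <- msat$genotypes; ms_deme <- msat$labels
  } else {
    ms <- matrix(NA_integer_, length(demes) * 2L, 2L)
    ms_deme <- rep(demes, each = 2L)
  }
  out <- .summary_vector_core(seq_states, seq_deme, ms, ms_deme, demes)
  if (is.null(seqs)) {
    mt <- grep("^mt_", names(out))
    out[mt] <- 0; attr(out, "defined")[mt] <- FALSE
  }
  if (is.null(msat)) {
    msc <- grep("^ms_", names(out))
    out[msc] <- 0; attr(out, "defined")[msc] <- FALSE
  }
  out
}

# fast path for simulator output (identical result; no string round trip)
summary_vector_sim <- function(sim) {
  .summary_vector_cpp(sim$seq_states, sim$seq_deme, sim$msat,
                      sim$msat_deme, sim$design$demes)
}
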