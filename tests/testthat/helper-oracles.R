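# Independent brute-force oracles, written directly from the defining
# equations with naive loops.  They share no code with the package
# implementations they check.

# mean pairwise difference per site by explicit pair enumeration
bf_pi <- function(seq_strings) {
  chars <- lapply(seq_strings, function(s) strsplit(s, "")[[1L]])
  keep <- Reduce(`&`, lapply(chars, function(x) x %in% c("A", "C", "G", "T")))
  n <- length(chars)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(chars[[i]][keep] != chars[[j]][keep]) / sum(keep)
    np <- np + 1
  }
  tot / np
}

# Hudson-Slatkin-Maddison F_ST by pair enumeration
bf_hudson_fst <- function(seqsA, seqsB) {
  hb <- 0
  for (a in seqsA) for (b in seqsB) {
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    keep <- ca %in% c("A","C","G","T") & cb %in% c("A","C","G","T")
    hb <- hb + sum(ca[keep] != cb[keep]) / sum(keep)
  }
  hb <- hb / (length(seqsA) * length(seqsB))
  hw <- (bf_pi(seqsA) + bf_pi(seqsB)) / 2
  1 - hw / hb
}

# Pons & Petit (1996) indices, direct loops over haplotypes i,j and pops k
bf_gst_nst <- function(counts, dists) {
  K <- ncol(counts); H <- nrow(counts)
  n_k <- colSums(counts)
  one <- function(D) {
    v_k <- numeric(K)
    for (k in 1:K) {
      acc <- 0
      for (i in 1:H) for (j in 1:H)
        acc <- acc + (counts[i, k] / n_k[k]) * (counts[j, k] / n_k[k]) * D[i, j]
      v_k[k] <- n_k[k] / (n_k[k] - 1) * acc
    }
    v_S <- mean(v_k)
    pbar <- numeric(H)
    for (i in 1:H) pbar[i] <- mean(counts[i, ] / n_k)
    vt <- 0
    for (i in 1:H) for (j in 1:H) vt <- vt + pbar[i] * pbar[j] * D[i, j]
    v_T <- vt + sum(v_k / n_k) / K^2
    1 - v_S / v_T
  }
  Did <- 1 - diag(H)
  list(G_ST = one(Did), N_ST = one(dists))
}

# AMOVA variance components by direct evaluation of the sums-of-squares
# equations, solving the expected-mean-square system with solve()
bf_amova <- function(d2, pops, grps) {
  N <- nrow(d2)
  upops <- unique(pops); P <- length(upops)
  ugrps <- unique(grps); G <- length(ugrps)
  ssd <- function(rows) {
    if (length(rows) < 2) return(0)
    acc <- 0
    for (i in rows) for (j in rows) acc <- acc + d2[i, j]
    acc / (2 * length(rows))
  }
  SSD_T <- ssd(1:N)
  SSD_WP <- sum(sapply(upops, function(p) ssd(which(pops == p))))
  SSD_WG <- sum(sapply(ugrps, function(g) ssd(which(grps == g))))
  n_p <- sapply(upops, function(p) sum(pops == p))
  N_g <- sapply(ugrps, function(g) sum(grps == g))
  grp_of <- sapply(upops, function(p) grps[which(pops == p)[1]])
  if (G > 1) {
    df <- c(G - 1, P - G, N - P)
    MS <- c((SSD_T - SSD_WG) / df[1], (SSD_WG - SSD_WP) / df[2],
            SSD_WP / df[3])
    sum_np2_Ng <- sum(sapply(ugrps, function(g)
      sum(n_p[grp_of == g]^2) / N_g[ugrps == g]))
    n1 <- (N - sum_np2_Ng) / df[2]
    n2 <- (sum_np2_Ng - sum(n_p^2) / N) / df[1]
    n3 <- (N - sum(N_g^2) / N) / df[1]
    # E[MS] system:  MS_AG = s_c + n2 s_b + n3 s_a ; MS_AP = s_c + n1 s_b ;
    #                MS_WP = s_c
    A <- rbind(c(n3, n2, 1), c(0, n1, 1), c(0, 0, 1))
    s <- solve(A, MS)
    list(sigma = s, FCT = s[1] / sum(s), FSC = s[2] / (s[2] + s[3]),
         FST = (s[1] + s[2]) / sum(s))
  } else {
    df <- c(P - 1, N - P)
    MS <- c((SSD_T - SSD_WP) / df[1], SSD_WP / df[2])
    n1 <- (N - sum(n_p^2) / N) / df[1]
    s <- solve(rbind(c(n1, 1), c(0, 1)), MS)
    list(sigma = c(0, s), FST = s[1] / sum(s))
  }
}

# Weir & Cockerham (1984) theta by direct per-allele evaluation
bf_wc_theta <- function(geno_list) {
  # geno_list: list of 2-column matrices of alleles, one per population
  r <- length(geno_list)
  n_i <- sapply(geno_list, nrow)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(geno_list)))
  num <- 0; den <- 0
  for (A in alleles) {
    p_i <- sapply(geno_list, function(g) mean(g == A))
    h_i <- sapply(geno_list, function(g) mean((g[, 1] == A) != (g[, 2] == A)))
    pbar <- sum(n_i * p_i) / (r * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

# rarefied allele count by exhaustive subset enumeration (tiny N only)
bf_allelic_richness <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# small helper: build a sequence dataset from explicit strings
seqs_of <- function(strings, labels) sequence_dataset(strings, labels)
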