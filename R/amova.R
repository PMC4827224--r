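#' Analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance from a matrix of pairwise squared
#' distances (for mtDNA, squared K2P distances) into among-group,
#' among-population-within-group and within-population components, with
#' the associated Phi-statistics F_CT, F_SC and F_ST and permutation
#' p-values.
#'
#' Sums of squared deviations follow the classical decomposition:
#' \eqn{SSD(total)}, \eqn{SSD(within\ pop)} and \eqn{SSD(within\ group)}
#' are computed directly from the distance matrix, mean squares from the
#' corresponding degrees of freedom, and variance components from the
#' unequal-sample-size coefficients.  Permutation schemes: F_ST permutes
#' individuals among populations, F_SC permutes individuals among
#' populations within groups, F_CT permutes whole populations among
#' groups.  P-values use the (b + 1) / (m + 1) estimator.
#'
#' @param d2 symmetric matrix of pairwise squared distances between
#'   individuals.
#' @param populations population label per individual.
#' @param groups group label per individual (constant within population).
#'   If omitted, a single group is assumed and only F_ST is estimated.
#' @param n_perm number of permutations (>= 1; 0 skips testing).
#' @param seed RNG seed for the permutations.
#' @return An object of class \code{AmovaResult}: variance components
#'   \code{sigma2} (a, b, c), \code{percent}, Phi-statistics
#'   \code{FCT, FSC, FST} and p-values \code{p}.
#' @export
amova <- function(d2, populations, groups = NULL, n_perm = 1000L, seed = NULL) {
  d2 <- as.matrix(d2)
  N <- nrow(d2)
  stopifnot(ncol(d2) == N, length(populations) == N)
  populations <- as.character(populations)
  if (is.null(groups)) groups <- rep("all", N)
  groups <- as.character(groups)
  pg <- unique(data.frame(populations, groups, stringsAsFactors = FALSE))
  if (anyDuplicated(pg$populations))
    stop("each population must belong to exactly one group")
  if (length(unique(populations)) < 2L) stop("need >= 2 populations")
  if (!is.null(seed)) set.seed(seed)

  obs <- .amova_components(d2, populations, groups)

  p <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
  if (n_perm >= 1L) {
    P <- length(unique(populations)); G <- length(unique(groups))
    cnt <- c(FCT = 0L, FSC = 0L, FST = 0L)
    for (b in seq_len(n_perm)) {
      # F_ST: individuals among populations (groups follow populations)
      perm <- sample.int(N)
      st <- .amova_components(d2, populations[perm], groups[perm])
      if (!is.na(obs$FST) && !is.na(st$FST) && st$FST >= obs$FST)
        cnt["FST"] <- cnt["FST"] + 1L
      # F_SC: individuals among populations within groups
      if (G > 1L && P > G && !is.na(obs$FSC)) {
        pops2 <- populations
        for (g in unique(groups)) {
          idx <- which(groups == g)
          pops2[idx] <- populations[idx][sample.int(length(idx))]
        }
        sc <- .amova_components(d2, pops2, groups)
        if (!is.na(sc$FSC) && sc$FSC >= obs$FSC) cnt["FSC"] <- cnt["FSC"] + 1L
      }
      # F_CT: populations among groups
      if (G > 1L && !is.na(obs$FCT)) {
        gp <- pg$groups[sample.int(nrow(pg))]
        g2 <- gp[match(populations, pg$populations)]
        ct <- .amova_components(d2, populations, g2)
        if (!is.na(ct$FCT) && ct$FCT >= obs$FCT) cnt["FCT"] <- cnt["FCT"] + 1L
      }
    }
    p["FST"] <- (cnt["FST"] + 1) / (n_perm + 1)
    if (!is.na(obs$FSC)) p["FSC"] <- (cnt["FSC"] + 1) / (n_perm + 1)
    if (!is.na(obs$FCT)) p["FCT"] <- (cnt["FCT"] + 1) / (n_perm + 1)
  }

  structure(c(obs, list(p = p, n_perm = n_perm)), class = "AmovaResult")
}

# core decomposition; returns sigma2, percent, Phi statistics
.amova_components <- function(d2, populations, groups) {
  N <- nrow(d2)
  pops <- unique(populations); P <- length(pops)
  grps <- unique(groups); G <- length(grps)
  n_p <- vapply(pops, function(p) sum(populations == p), 0)
  N_g <- vapply(grps, function(g) sum(groups == g), 0)

  ssd_of <- function(rows) {
    if (length(rows) < 2L) return(0)
    sum(d2[rows, rows]) / 2 / length(rows)
  }
  SSD_T <- ssd_of(seq_len(N))
  SSD_WP <- sum(vapply(pops, function(p) ssd_of(which(populations == p)), 0))
  SSD_WG <- sum(vapply(grps, function(g) ssd_of(which(groups == g)), 0))
  SSD_AP <- SSD_WG - SSD_WP
  SSD_AG <- SSD_T - SSD_WG

  df_WP <- N - P
  sigma_c <- if (df_WP > 0) SSD_WP / df_WP else 0

  # sum over groups of (sum of n_p^2 within group) / N_g
  grp_of_pop <- groups[match(pops, populations)]
  sum_np2_over_Ng <- sum(vapply(grps, function(g) {
    idx <- grp_of_pop == g
    sum(n_p[idx]^2) / N_g[grps == g]
  }, 0))

  if (G > 1L) {
    df_AG <- G - 1L; df_AP <- P - G
    sigma_b <- NA_real_; sigma_a <- NA_real_
    if (df_AP > 0) {
      n1 <- (N - sum_np2_over_Ng) / df_AP
      sigma_b <- (SSD_AP / df_AP - sigma_c) / n1
    } else sigma_b <- 0
    n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_AG
    n3 <- (N - sum(N_g^2) / N) / df_AG
    sigma_a <- (SSD_AG / df_AG - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    FCT <- sigma_a / tot
    FSC <- if (df_AP > 0) sigma_b / (sigma_b + sigma_c) else NA_real_
    FST <- (sigma_a + sigma_b) / tot
    sigma2 <- c(among_groups = sigma_a, among_pops_within_groups = sigma_b,
                within_pops = sigma_c)
  } else {
    df_AP <- P - 1L
    n1 <- (N - sum(n_p^2) / N) / df_AP
    sigma_b <- (SSD_AP / df_AP - sigma_c) / n1
    tot <- sigma_b + sigma_c
    FST <- sigma_b / tot
    FCT <- NA_real_; FSC <- NA_real_
    sigma2 <- c(among_groups = 0, among_pops_within_groups = sigma_b,
                within_pops = sigma_c)
  }
  list(sigma2 = sigma2, percent = 100 * sigma2 / sum(sigma2),
       FCT = FCT, FSC = FSC, FST = FST,
       ssd = c(among_groups = SSD_AG, among_pops = SSD_AP,
               within_pops = SSD_WP, total = SSD_T))
}

#' @export
print.AmovaResult <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(sigma2 = x$sigma2, percent = x$percent)
  print(round(tab, 4))
  cat(sprintf("Phi_CT = %.4f (p = %s)\n", x$FCT, format(x$p["FCT"])))
  cat(sprintf("Phi_SC = %.4f (p = %s)\n", x$FSC, format(x$p["FSC"])))
  cat(sprintf("Phi_ST = %.4f (p = %s)\n", x$FST, format(x$p["FST"])))
  invisible(x)
}
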