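#!/usr/bin/env Rscript
# Stage 2: the descriptive population-genetic panel for the observed
# data, mirroring the layout of a phylogeography paper's tables:
#   - per-deme diversity (haplotypes, h, theta-pi, theta-w; msat A, A_R,
#     H_O, H_E, F_IS)                                     [Table 1 style]
#   - pairwise F_ST matrix, mtDNA above / msat below diagonal
#                                                         [Table 3 style]
#   - AMOVA by subregion grouping                         [Table 4 style]
#   - G_ST vs N_ST and the Brito nuclear-equivalent correction
# Reads the stage-1 outputs; writes TSVs under results/.

library(garrapop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out_dir <- if (length(args) >= 2) args[[2]] else "results"

seqs <- read_fasta_with_popmap(file.path(out_dir, "observed.fasta"),
                               file.path(out_dir, "observed.popmap.tsv"))
msat <- read_genepop(file.path(out_dir, "observed.genepop.txt"),
                     pop_names = unique(seqs$labels))
demes <- unique(seqs$labels)

# ---- per-deme diversity -------------------------------------------------
ht <- collapse_haplotypes(seqs)
div <- do.call(rbind, lapply(demes, function(d) {
  n <- sum(seqs$labels == d)
  data.frame(deme = d, n_mt = n,
             n_hap = sum(ht$counts[, d] > 0),
             h = haplotype_diversity(ht$counts[, d]),
             theta_pi = nucleotide_diversity_pi(seqs, d),
             theta_w = watterson_theta(seqs, d))
}))
pan <- msat_diversity_panel(msat)
write.table(merge(div, pan, by.x = "deme", by.y = "population"),
            file.path(out_dir, "diversity_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# ---- pairwise F_ST matrix (mtDNA above, msat below diagonal) ------------
D <- length(demes)
fst <- matrix(NA_real_, D, D, dimnames = list(demes, demes))
na_if_undefined <- function(expr) tryCatch(expr, error = function(e) NA_real_)
for (i in seq_len(D - 1)) for (j in (i + 1):D) {
  # a pair fixed for one shared haplotype leaves F_ST undefined -> NA
  fst[i, j] <- na_if_undefined(hudson_fst(seqs, demes[i], demes[j]))
  fst[j, i] <- na_if_undefined(wc_fst(msat, demes[i], demes[j]))
}
write.table(round(fst, 4), file.path(out_dir, "pairwise_fst.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)

# ---- G_ST / N_ST and Brito correction -----------------------------------
reps <- ht$representative
K2P <- outer(seq_along(reps), seq_along(reps), Vectorize(function(i, j)
  if (i == j) 0 else k2p_distance(reps[i], reps[j])))
gn <- gst_nst(ht, K2P)
brito <- brito_correction(max(0, min(1, gn$N_ST)))

# ---- AMOVA: island demes (NH + SH) vs mainland (ZF + PR) ----------------
grouping <- ifelse(seqs$labels %in% c("NH", "SH"), "island", "mainland")
d2 <- K2P[ht$hap_index, ht$hap_index]^2
set.seed(seed + 2000L)
am <- amova(d2, seqs$labels, grouping, n_perm = 500L)

amova_tab <- data.frame(
  component = c("among_groups", "among_demes_within_groups", "within_demes"),
  sigma2 = unname(am$sigma2), percent = unname(am$percent))
write.table(amova_tab, file.path(out_dir, "amova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summary_tab <- data.frame(
  statistic = c("G_ST", "N_ST", "brito_corrected_fst_nuc",
                "Phi_CT", "Phi_SC", "Phi_ST",
                "p_CT", "p_SC", "p_ST"),
  value = c(gn$G_ST, gn$N_ST, brito, am$FCT, am$FSC, am$FST,
            am$p["FCT"], am$p["FSC"], am$p["FST"]))
write.table(summary_tab, file.path(out_dir, "structure_indices.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Diversity and structure panel:\n")
print(div, row.names = FALSE)
cat(sprintf("G_ST = %.3f, N_ST = %.3f -> N_ST >> G_ST indicates phylogeographic structure\n",
            gn$G_ST, gn$N_ST))
cat(sprintf("Brito nuclear-equivalent of N_ST: %.3f\n", brito))
cat(sprintf("AMOVA: Phi_CT = %.3f (p = %.3g), Phi_ST = %.3f (p = %.3g)\n",
            am$FCT, am$p[["FCT"]], am$FST, am$p[["FST"]]))
cat("Tables written under ", out_dir, "/\n", sep = "")
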