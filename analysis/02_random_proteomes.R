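#!/usr/bin/env Rscript
# pI distributions of randomized proteomes: a uniform-composition set at
# the mean human protein length (560 aa) and a human-like-composition set.
#
# Finding: both randomized proteomes deplete the near-neutral window
# relative to their flanks — almost no random sequence is uncharged at
# physiological pH. With human-like residue frequencies the two modes move
# outward and the (7,8) valley drops to ~10%, passing the strict window
# criterion; with uniform frequencies the basic mode sits at pH 8-8.5,
# just inside the valley's right flank, so the fixed-window verdict is
# negative even though the histogram is visibly bimodal.

suppressMessages(library(condensateph))
dir.create("results", showWarnings = FALSE)
seed <- 1L
n <- 5000L

specs <- list(
  uniform = random_proteome_spec(n, uniform_composition(), 560L, seed),
  human_like = random_proteome_spec(n, human_like_composition(), 560L,
                                    seed + 1L))

rows <- list(); hists <- list()
for (name in names(specs)) {
  dist <- pi_distribution(sample_proteome(specs[[name]]))
  bs <- bimodality_stats(dist)
  rows[[name]] <- data.frame(
    proteome = name, n = dist$n, skipped = dist$skipped,
    valley_7_8 = bs$valley_fraction,
    shoulder_acidic = bs$shoulder_fractions[["acidic"]],
    shoulder_basic = bs$shoulder_fractions[["basic"]],
    window_bimodal = bs$is_bimodal)
  hists[[name]] <- data.frame(proteome = name,
                              bin_left = head(dist$breaks, -1),
                              count = dist$counts)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/random_proteome_windows.csv", row.names = FALSE)
write.csv(do.call(rbind, hists), "results/random_proteome_histograms.csv",
          row.names = FALSE)

cat("Randomized proteome window fractions (n =", n, ", L = 560):\n")
print(tab, row.names = FALSE)
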