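#!/usr/bin/env Rscript
# Sequence electrochemistry of the two model peptides (insulin and its
# glargine variant): net-charge profiles, isoelectric points, the q^2
# repulsion proxy and Kyte-Doolittle hydropathy.
#
# Finding: the two sequences differ by three residues (A21G, +RR), yet the
# charge-neutral point moves by ~1.5 pH units (5.39 -> 6.88), and each q^2
# profile bottoms out at the respective pI — the electrostatic penalty on
# condensation is minimal exactly where each peptide phase separates.

suppressMessages(library(condensateph))
dir.create("results", showWarnings = FALSE)

seqs <- read_fasta_protein(system.file("extdata", "insulin.fasta",
                                       package = "condensateph"))

rows <- lapply(seqs, function(s) {
  cp <- charge_profile(s)
  hp <- hydropathy(s)
  data.frame(id = s$id, n_residues = s$n,
             pI = isoelectric_point(s),
             q2_min_ph = cp$ph[which.min(cp$q2)],
             Q_at_ph7 = protein_net_charge(s, 7),
             q2_at_ph5 = cp$q2[which.min(abs(cp$ph - 5))],
             q2_at_ph8 = cp$q2[which.min(abs(cp$ph - 8))],
             kd_sum = hp$kd_sum, kd_mean = hp$kd_mean)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/sequence_charge.csv", row.names = FALSE)

for (s in seqs)
  write_profile_csv(charge_profile(s),
                    file.path("results", paste0("profile_", s$id, ".csv")))

cat("Sequence electrochemistry:\n")
print(tab, row.names = FALSE)
cat("\nGlargine's pI sits", sprintf("%.2f", tab$pI[2] - tab$pI[1]),
    "pH units above insulin's; both q2 minima coincide with the pI.\n")
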