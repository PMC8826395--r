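#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume: protein
# families under vertical descent and under an HGT scenario, a genome with an
# inserted compositional island, a clock-like tree, and the demonstration
# PADI-like alignment. All outputs are plain text under results/.

suppressPackageStartupMessages(library(hgtrace))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

# Protein families on the reference/bridge/distal species tree.
# Ages emulate the analysis contrast: reference-bridge split 700 Ma
# (chordate-scale), distal divergence 2700 Ma (cyanobacteria-scale),
# rate 2.2e-4 subs/site/My so the distal comparison stays alignable.
st <- agd_species_tree(root_age = 2700, split_age = 700, rate = 2.2e-4)
for (i in 1:26) {
  fam <- simulate_family(st, scenario("vertical"), 300, seed = 1000L + i)
  write_fasta(fam$sequences,
              sprintf("results/simulated/vertical_%02d.fasta", i))
}
for (i in 1:10) {
  fam <- simulate_family(
    st, scenario("hgt", donor = "distal",
                 recipient = c("reference", "bridge"), time_ma = 750),
    300, seed = 2000L + i)
  write_fasta(fam$sequences, sprintf("results/simulated/hgt_%02d.fasta", i))
}
cat("wrote 26 vertical and 10 HGT families (300 aa, 3 taxa each)\n")

# A 100 kb uniform-composition host with a 5 kb island at 80% G+C.
gs <- simulate_genome_with_island(100000, rep(0.25, 4), 5000,
                                  c(0.1, 0.4, 0.4, 0.1),
                                  position = 47500, seed = seed)
write_fasta(c(island_host = gs$genome), "results/simulated/genome_island.fasta")
writeLines(sprintf("island\t%d\t%d", gs$island["start"], gs$island["end"]),
           "results/simulated/genome_island_truth.tsv")
cat(sprintf("wrote 105 kb genome; true island at [%d, %d)\n",
            gs$island["start"], gs$island["end"]))

# Clock-like tree, 8 taxa, root 900 Ma, rate 1e-3 subs/site/My, 10% noise.
# Calibrations go out as taxon sets (node numbers do not survive a Newick
# round-trip): the three deepest non-root internal nodes, truth-centered,
# sigma 5% of age.
sim <- simulate_clocklike_tree(8, root_age = 900, rate = 1e-3,
                               noise_sd = 0.1, seed = seed)
ape::write.tree(sim$tree, "results/simulated/clock_tree.nwk")
internals <- setdiff(9:(8 + sim$tree$Nnode), 9L)
nodes <- internals[order(-sim$true_ages[internals])][1:3]
cal <- do.call(rbind, lapply(nodes, function(nd) {
  tips <- ape::extract.clade(sim$tree, nd)$tip.label
  data.frame(taxa = paste(tips, collapse = ","),
             mean_ma = sim$true_ages[nd],
             sigma_ma = max(0.05 * sim$true_ages[nd], 1))
}))
write.table(cal, "results/simulated/clock_calibrations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote clock-like tree (8 taxa, true root 900 Ma) and 3 calibrations\n")

# Synthetic PADI-like alignment for the synapomorphy analysis.
aln <- make_padi_demo_alignment(seed = seed)
write_fasta(setNames(aln$seq, paste(aln$id, aln$group, sep = "|")),
            "results/simulated/padi_demo_alignment.fasta")
cat("wrote synthetic PADI-like demonstration alignment (12 rows)\n")
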