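#!/usr/bin/env Rscript
# Motif delineation of subfamilies, on a constructed (synthetic) family
# fixture laid out like the carotenoid oxygenases: one clade carrying the
# PDPCK palmitoylation motif (with one SDPCK variant), two clades without
# it, and four invariant histidines present everywhere.

library(bdmshift)

aln <- protein_alignment(c(
  bco1   = "MHAGPDPCKWHLAHTKHD",
  rpe65  = "MHSGPDPCKWHLAHSKHD",
  bco2   = "MHAGSDPCKWHLAHTKHD",   # P->S variant of the motif
  bcol_a = "MHAGKEPLNWHLAHTKHD",
  bcol_b = "MHSGKEPLNWHLAHTKHD",
  acol_a = "MHAGQEPLNWHLAHTKHD",
  acol_b = "MHAGQEPLNWHLAHSKHD",
  acol_c = "MHAGQEPMNWHLAHTKHD"
))
phy <- read_newick(paste0(
  "(((bco1:0.1,rpe65:0.1):0.1,bco2:0.15):0.2,",
  "((bcol_a:0.1,bcol_b:0.1):0.25,",
  "(acol_a:0.1,(acol_b:0.05,acol_c:0.05):0.08):0.3):0.1);"))

hits <- scan_motif(aln, "[PS]DPCK")
write.table(hits, "results/motif_hits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(nrow(hits), "motif hits ([PS]DPCK):",
    paste(hits$seq_id, collapse = ", "), "\n")

clades <- list(BCO_RPE65 = c("bco1", "rpe65", "bco2"),
               BCOL = c("bcol_a", "bcol_b"),
               ACOL = c("acol_a", "acol_b", "acol_c"))
tab <- clade_motif_table(phy, hits, clades)
print(tab)
write.table(tab, "results/motif_clades.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# the four invariant histidines, anchored on the first sequence
cons <- conserved_column_report(aln, "bco1", c(2, 11, 14, 17))
print(cons$conservation)
write.table(cons$conservation, "results/histidine_conservation.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
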