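#!/usr/bin/env Rscript
# Stage 6 — physicochemical profile of the construct polypeptide.
#
# ProtParam-style panel: molecular weight (average masses), elemental
# formula, charged-residue counts, theoretical pI (Bjellqvist pKa set,
# bisection), instability index (Guruprasad dipeptide weights), aliphatic
# index, GRAVY and the N-end-rule half-life class. Note that the profile
# depends on which segments are included (with or without the signal
# peptide and MITD), so both variants are reported.

library(mevax)

fa <- readLines("results/construct_protein.fasta")
protein <- fa[2]
bp <- construct_blueprint()

core <- substr(protein, nchar(bp$signal_peptide) + 1,
               nchar(protein) - nchar(bp$mitd))

for (variant in list(list(name = "full_construct", seq = protein),
                     list(name = "epitope_core", seq = core))) {
  prof <- protein_profile(variant$seq)
  message("== ", variant$name)
  print(prof)
  out <- data.frame(
    property = c("length", "molecular_weight", "formula", "atom_total",
                 "negative_count", "positive_count", "pI",
                 "instability_index", "instability_class",
                 "aliphatic_index", "gravy", "half_life"),
    value = c(prof$length, sprintf("%.1f", prof$molecular_weight),
              sprintf("C%dH%dN%dO%dS%d", prof$formula["C"],
                      prof$formula["H"], prof$formula["N"],
                      prof$formula["O"], prof$formula["S"]),
              prof$atom_total, prof$negative_count, prof$positive_count,
              sprintf("%.2f", prof$pI),
              sprintf("%.2f", prof$instability_index),
              prof$instability_class,
              sprintf("%.2f", prof$aliphatic_index),
              sprintf("%.3f", prof$gravy), prof$half_life_class))
  write.table(out, sprintf("results/protein_profile_%s.tsv", variant$name),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
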