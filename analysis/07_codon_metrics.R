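#!/usr/bin/env Rscript
# Stage 7 — codon-level metrics of candidate ORFs.
#
# The construct protein is reverse-translated under the two built-in
# strategies (max-CAI and GC-balancing) and both ORFs are scored for CAI
# against the packaged human usage table, GC content (the conventional
# mRNA design window is 45-55%, flagged but not enforced), and the
# base-pair-maximization structure proxy on a 5' window (higher pair count
# = more structured; not a thermodynamic folding energy).

library(mevax)

fa <- readLines("results/construct_protein.fasta")
protein <- fa[2]
u <- default_human_usage()

rows <- lapply(c("max_cai", "gc_balance"), function(mode) {
  orf <- optimize_codons(protein, u, mode)
  window <- substr(orf, 1, 300)  # 5'-proximal window, initiation-relevant
  data.frame(mode = mode,
             cai = cai(orf, u),
             gc = gc_content(orf),
             gc_in_45_55 = gc_content(orf) >= 45 & gc_content(orf) <= 55,
             pairing_5prime_300nt = pairing_score(window),
             length_nt = nchar(orf))
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.table(tab, "results/codon_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("max-CAI ORF: CAI %.3f, GC %.2f%%; GC-balanced ORF: CAI %.3f, GC %.2f%%",
                tab$cai[1], tab$gc[1], tab$cai[2], tab$gc[2]))
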