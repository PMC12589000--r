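#!/usr/bin/env Rscript
# Stage 5 — assemble and validate the vaccine construct.
#
# The packaged published epitope inventory (18 HTL + 6 LBL + 12 CTL) is
# assembled under the linker schedule (signal-GPGPG-HTL...-KK-LBL...-AAY-
# CTL...-AAY-MITD), reverse-translated behind a Kozak context, flanked by
# the screened 5'UTR, a 3'UTR and a 120-nt poly(A) tail, then parsed back
# and validated (round-trip identity, linker counts, frame correctness).

library(mevax)

utr5 <- if (file.exists("results/utr_selected.txt"))
  readLines("results/utr_selected.txt")[1] else
  "GGGATCTTATTCCACCTTCTGAAGCTTCTGTCGAACCAGTTGTAAGGAGA"
# human beta-globin-type stabilizing 3'UTR segment (synthetic stand-in)
utr3 <- "GCTCGCTTTCTTGCTGTCCAATTTCTATTAAAGGTTCCTTTGTTCCCTAAGTCCAA"

bp <- construct_blueprint(utr5 = utr5, utr3 = utr3)
ep <- reference_epitopes()
cons <- assemble_protein(bp,
                         ep$sequence[ep$epitope_class == "HTL"],
                         ep$sequence[ep$epitope_class == "LBL"],
                         ep$sequence[ep$epitope_class == "CTL"])
cons <- assemble_mrna(cons, as_rna = FALSE)

parsed <- parse_construct(cons$protein, bp)
stopifnot(identical(parsed$protein, cons$protein))
report <- validate_construct(cons)
print(report)
stopifnot(all(report$pass))

message(sprintf("protein %d aa; mRNA %d nt; blocks HTL %d / LBL %d / CTL %d (T total %d)",
                nchar(cons$protein), nchar(cons$mrna),
                cons$block_counts["n_htl"], cons$block_counts["n_lbl"],
                cons$block_counts["n_ctl"],
                cons$block_counts["n_htl"] + cons$block_counts["n_ctl"]))

writeLines(c(">vaccine_construct_protein", cons$protein),
           "results/construct_protein.fasta")
writeLines(c(">vaccine_construct_mrna", chartr("T", "U", cons$mrna)),
           "results/construct_mrna.fasta")
write.table(cons$elements, "results/construct_features_protein.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cons$mrna_elements, "results/construct_features_mrna.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
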