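#!/usr/bin/env Rscript
# Stage 2 — triage the candidate epitopes.
#
# B-cell (LBL) candidates are first reduced to the top five per antigen by
# prediction score; all classes then pass the antigenicity / allergenicity
# / toxicity filter, CTL additionally the binding-rank and conservation
# rules and HTL the stricter conservation rule. The audit table records
# every rule outcome per candidate.

library(mevax)

cands <- read.delim("results/epitope_candidates.tsv",
                    stringsAsFactors = FALSE)
policy <- filter_policy()

lbl <- cands[cands$epitope_class == "LBL", ]
lbl_top <- do.call(rbind, lapply(split(lbl, lbl$source_protein),
                                 select_top_k, k = policy$lbl_top_k))
pool <- rbind(lbl_top, cands[cands$epitope_class != "LBL", ])

fl <- filter_epitopes(pool, policy)
write.table(fl$retained, "results/epitopes_retained.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(fl$audit, "results/epitope_filter_audit.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

s <- summarize_selection(fl$retained)
message(sprintf("retained %d / %d candidates (LBL %d, CTL %d, HTL %d; %d T-cell)",
                s$total, nrow(pool), s$per_class["LBL"], s$per_class["CTL"],
                s$per_class["HTL"], s$t_lymphocyte_total))
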