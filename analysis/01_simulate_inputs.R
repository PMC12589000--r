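#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic inputs for the design workflow.
#
# External epitope-prediction servers, HLA frequency databases and
# polysome-profiling libraries are not reproducible offline, so the
# workflow runs on synthetic stand-ins whose ground truth is known by
# construction: an epitope candidate table with should-pass labels, an
# allele world (frequencies + binding map), and a 5'UTR library whose mean
# ribosome load follows the documented uAUG/uORF generative model.

library(mevax)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)

cands <- gen_epitope_candidates(
  candidate_generator_spec(60L, pass_fraction = 0.4, seed = seed))
write.table(cands, "results/epitope_candidates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("epitope candidates: %d (%d designed to pass)",
                nrow(cands), sum(cands$should_pass)))

world <- gen_allele_world(4L, 6L, 30L, n_regions = 8L, seed = seed + 1L,
                          total_mass = 0.9, max_bound_alleles = 1L)
write_allele_world(world, "results/allele_frequencies.tsv",
                   "results/epitope_allele_map.tsv")
message(sprintf("allele world: %d loci x %d regions, %d epitopes mapped",
                length(unique(world$freq$locus)),
                length(unique(world$freq$region)),
                length(unique(world$binding$epitope))))

lib <- gen_mrl_library(mrl_generator_spec(5000L, noise_sd = 0.1,
                                          seed = seed + 2L))
write_mrl_csv(lib, "results/mrl_library.csv")
message(sprintf("MRL library: %d x %d nt, mean MRL %.3f (%d uAUG+, %d uORF+)",
                nrow(lib), nchar(lib$sequence[1]), mean(lib$mrl),
                sum(lib$uaug_count > 0), sum(lib$uorf_count > 0)))
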