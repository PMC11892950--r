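#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — paired litterbag/soil communities
# under warming and control (12 samples per group), a genome-trait reference
# covering ~22% of taxa, a functional-gene probe table with planted warming
# effects on cellulose genes, three years of daily forcing for warmed and
# control plots, and model-generated observation series.
#
# Everything downstream (02-07) reads only the files written here.

library(gmendr)

SEED <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_design(
  n_taxa = 400, n_samples_per_group = 12, seed = SEED,
  enrichment_effects = list(
    # cellulose specialists enriched in litterbags relative to soil
    list(taxa = sprintf("taxon%05d", 1:40), fold = 3, groups = c("WL", "CL"))
  ))
comm <- gen_paired_communities(design)
write_community_table(comm, file.path(out, "community.tsv"))
message(sprintf("communities: %d samples x %d taxa", nrow(comm$counts),
                ncol(comm$counts)))

ref <- gen_trait_reference(design, match_fraction = 0.2156)
write_trait_reference(ref, file.path(out, "trait_reference.tsv"))
message(sprintf("trait reference: %d of %d taxa matched (%.1f%%)",
                sum(ref$matched), nrow(ref), 100 * mean(ref$matched)))

probes <- gen_probe_table(
  n_probes = 1200, groups = comm$samples$group, detection_rate = 0.8,
  effect_map = list(endoglucanase = 3, cellobiase = 2.5, axe = 2,
                    amyA = 1.8, xylanase = 1.8),
  seed = derive_seed(SEED, 1))
write_probe_table(probes, file.path(out, "probes.tsv"))
message(sprintf("probe table: %d probes, %d genes", nrow(probes$intensity),
                length(unique(probes$annotation$gene))))

fdesign <- forcing_design(n_days = 1095, seed = derive_seed(SEED, 2))
for (w in c(FALSE, TRUE)) {
  nm <- if (w) "warmed" else "control"
  f <- gen_forcing(fdesign, warmed = w)
  write_forcing(f, file.path(out, sprintf("forcing_%s.csv", nm)))
  obs <- gen_observations(mend_params(), mend_state(), f,
                          seed = derive_seed(SEED, 3 + w))
  write_observations(obs, file.path(out, sprintf("observations_%s.csv", nm)))
}
message("forcing and observations written for control and warmed plots")
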