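#!/usr/bin/env Rscript

# Step 1 -- simulate the mapping population and its fiber phenotypes.
#
# A BC6F2 chromosome-segment substitution population of 184 families is
# simulated on a four-chromosome demo genome, with one planted
# fiber-strength QTL on A10 at 21.4 Mb sized to explain half of the trait
# variance. Phenotypes for the two correlated fiber traits are written for
# the next step. Everything downstream is reproducible from SEED.

suppressPackageStartupMessages(library(bulkseg))

SEED <- 2025L
QTL_CHROM <- "A10"
QTL_POS <- 21400000

dir.create("results", showWarnings = FALSE)

genome <- demo_genome()

# size the QTL effect against the realized donor doses at the locus
pop0 <- simulate_population(genome, sim_config(seed = SEED))
effect <- qtl_effect_for_variance(dose_at(pop0, QTL_CHROM, QTL_POS),
                                  resid_sd = 2.1, frac = 0.5)
cat(sprintf("planted QTL at %s:%d, additive effect %.2f cN/tex\n",
            QTL_CHROM, QTL_POS, effect))

cfg <- sim_config(seed = SEED,
                  qtl = data.frame(chrom = QTL_CHROM, pos_bp = QTL_POS,
                                   effect_strength = effect))
pop <- simulate_population(genome, cfg)
phen <- simulate_phenotypes(pop, cfg)

write_phenotypes_tsv(phen, "results/phenotypes.tsv")
cat(sprintf("wrote results/phenotypes.tsv (%d families)\n", nrow(phen)))
cat(sprintf("median introgressed segments per family: %d\n",
            as.integer(median(donor_segment_count(pop)))))
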