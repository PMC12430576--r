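#!/usr/bin/env Rscript

# Step 2 -- phenotype statistics, normality screen, extreme bulks, pooled
# sequencing.
#
# Summarizes both fiber traits, checks the |skewness| < 1 and |kurtosis| < 1
# screen that justifies bulked-segregant mapping, builds the 20-family
# superior (HC1) and 12-family inferior (HC2) fiber-strength bulks, and
# simulates pooled 30x sequencing of both bulks plus the two parents into a
# multi-sample VCF.

suppressPackageStartupMessages(library(bulkseg))

SEED <- 2025L
QTL_CHROM <- "A10"
QTL_POS <- 21400000

phen <- read_phenotypes_tsv("results/phenotypes.tsv")

summaries <- tibble::tibble(
  trait = c("fiber_length", "fiber_strength"),
  rbind(summarize_trait(phen$fiber_length),
        summarize_trait(phen$fiber_strength)))
summaries$normal <- c(normality_screen(summaries[1, ])$pass,
                      normality_screen(summaries[2, ])$pass)
write_track_tsv(summaries, "results/trait_summaries.tsv",
                header_comments = paste("seed:", SEED))
print(as.data.frame(summaries[, c("trait", "mean", "sd", "cv", "skewness",
                                  "kurtosis", "range", "normal")]),
      digits = 3, row.names = FALSE)

bulks <- select_extreme_bulks(phen, n_high = 20, n_low = 12)
bt <- tibble::tibble(
  family_id = c(bulks$HC1, bulks$HC2),
  bulk = rep(c("HC1", "HC2"), c(length(bulks$HC1), length(bulks$HC2))))
write_track_tsv(bt, "results/bulk_membership.tsv",
                header_comments = paste("seed:", SEED))
cat(sprintf("bulks: HC1 %d families (strength >= %.2f), HC2 %d (<= %.2f)\n",
            length(bulks$HC1),
            min(phen$fiber_strength[phen$family_id %in% bulks$HC1]),
            length(bulks$HC2),
            max(phen$fiber_strength[phen$family_id %in% bulks$HC2])))

# regenerate the identical population (same seed) and sequence the bulks
pop0 <- simulate_population(demo_genome(), sim_config(seed = SEED))
effect <- qtl_effect_for_variance(dose_at(pop0, QTL_CHROM, QTL_POS),
                                  resid_sd = 2.1, frac = 0.5)
cfg <- sim_config(seed = SEED,
                  qtl = data.frame(chrom = QTL_CHROM, pos_bp = QTL_POS,
                                   effect_strength = effect))
pop <- simulate_population(demo_genome(), cfg)
adt <- simulate_bulk_reads(pop, bulks, cfg)
write_vcf(adt, "results/bulks.vcf")
cat(sprintf("wrote results/bulks.vcf (%d sites)\n", nrow(adt)))
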