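g1 <- one_chrom_genome()

test_that("population and read simulation are bit-identical under a fixed seed", {
  cfg <- sim_config(n_families = 25, seed = 42)
  p1 <- simulate_population(g1, cfg)
  p2 <- simulate_population(g1, cfg)
  expect_identical(p1$doses, p2$doses)
  expect_identical(p1$donor_fraction, p2$donor_fraction)
  bulks <- list(HC1 = p1$family_id[1:5], HC2 = p1$family_id[6:9])
  expect_identical(simulate_bulk_reads(p1, bulks, cfg),
                   simulate_bulk_reads(p2, bulks, cfg))
})

test_that("configuration errors are caught", {
  expect_error(genome_spec(data.frame(name = character(0), length_bp = numeric(0),
                                      map_length_morgans = numeric(0))),
               "at least one chromosome")
  expect_error(genome_spec(data.frame(name = "c1", length_bp = 1e6,
                                      map_length_morgans = 1),
                           snp_positions = list(c1 = numeric(0))),
               "at least one SNP")
  expect_error(genome_spec(data.frame(name = "c1", length_bp = 1e6,
                                      map_length_morgans = 1),
                           snp_positions = list(c1 = c(10, 5))),
               "strictly increasing")
  expect_error(sim_config(env_sd = c(length = -1, strength = 1)), "env_sd")
  expect_error(simulate_population(
    g1, sim_config(qtl = data.frame(chrom = "A99", pos_bp = 1,
                                    effect_strength = 1))),
    "not declared")
})

test_that("zero map length transmits whole chromosomes", {
  g0 <- genome_spec(data.frame(name = "c1", length_bp = 1e6,
                               map_length_morgans = 0),
                    snp_spacing_bp = 1e5)
  pop <- simulate_population(g0, sim_config(n_families = 40,
                                            targets_per_family = 0, seed = 3))
  for (d in asplit(pop$doses$c1, 1)) {
    expect_length(unique(as.integer(d)), 1L)  # whole homologs, no recombinants
  }
})

test_that("expected donor fraction halves per backcross generation", {
  fr <- vapply(1:6, function(gn) {
    pop <- simulate_population(
      g1, sim_config(n_backcross = gn, n_families = 2000,
                     targets_per_family = 0, seed = 100 + gn))
    mean(pop$donor_fraction)
  }, 0)
  slope <- stats::coef(stats::lm(log2(fr) ~ seq_along(fr)))[2]
  expect_lt(abs(slope + 1), 0.1)
})

test_that("introgressed-region count per family is small under defaults", {
  pop <- simulate_population(demo_genome(), sim_config(seed = 11))
  expect_lte(median(donor_segment_count(pop)), 4)
})

test_that("phenotypes are Gaussian without QTLs and respect the residual model", {
  pop <- simulate_population(g1, sim_config(n_families = 2000, seed = 5))
  cfg <- sim_config(n_families = 2000, seed = 5)
  ph <- simulate_phenotypes(pop, cfg)
  for (tr in list(ph$fiber_length, ph$fiber_strength)) {
    s <- summarize_trait(tr)
    expect_lt(abs(s$skewness), 0.3)
    expect_lt(abs(s$kurtosis), 0.3)
  }
  # residual correlation near its configured value
  expect_lt(abs(stats::cor(ph$fiber_length, ph$fiber_strength) - 0.6), 0.1)
})

test_that("a planted QTL shifts the trait along donor dose", {
  pop <- simulate_population(g1, sim_config(n_families = 2000, seed = 6))
  cfg <- sim_config(n_families = 2000, seed = 6,
                    qtl = data.frame(chrom = "A10", pos_bp = 5e6,
                                     effect_strength = 2))
  ph <- simulate_phenotypes(pop, cfg)
  d <- dose_at(pop, "A10", 5e6)
  expect_gt(stats::cor(d, ph$fiber_strength), 0)
  expect_gt(stats::cor(d, ph$fiber_length), 0)
})

test_that("noise-free phenotypes take at most three values per trait", {
  pop <- simulate_population(g1, sim_config(n_families = 100, seed = 7))
  cfg <- sim_config(n_families = 100, seed = 7,
                    env_sd = c(length = 0, strength = 0),
                    qtl = data.frame(chrom = "A10", pos_bp = 5e6,
                                     effect_strength = 3))
  ph <- simulate_phenotypes(pop, cfg)
  expect_lte(length(unique(ph$fiber_strength)), 3L)
  expect_lte(length(unique(ph$fiber_length)), 3L)
})

test_that("bulk reads follow the true frequencies", {
  # a bulk of donor-free families (neutral backcrossing leaves most families
  # donor-free) yields zero donor reads everywhere when the error rate is 0
  cfg0 <- sim_config(n_families = 60, seed = 8, error_rate = 0,
                     targets_per_family = 0, bulk_depth_mean = 10000)
  pop0 <- simulate_population(g1, cfg0)
  zero_fams <- pop0$family_id[rowSums(pop0$doses$A10) == 0]
  expect_gte(length(zero_fams), 8)
  bulks <- list(HC1 = zero_fams[1:4], HC2 = zero_fams[5:8])
  adt <- simulate_bulk_reads(pop0, bulks, cfg0)
  expect_true(all(adt$hc1_donor == 0, na.rm = TRUE))
  # and at very high depth the observed index converges on the truth
  cfg <- sim_config(n_families = 60, seed = 8, error_rate = 0,
                    bulk_depth_mean = 10000)
  pop <- simulate_population(g1, cfg)
  bulks2 <- list(HC1 = pop$family_id[1:20], HC2 = pop$family_id[21:32])
  adt2 <- simulate_bulk_reads(pop, bulks2, cfg)
  tr <- snp_index_track(adt2)
  truth <- attr(adt2, "truth")
  expect_lt(max(abs(tr$index_hc1 - truth$true_freq_hc1), na.rm = TRUE), 0.02)
  expect_lt(max(abs(tr$index_hc2 - truth$true_freq_hc2), na.rm = TRUE), 0.02)
})

test_that("zero-depth draws are emitted as missing, not zero", {
  cfg <- sim_config(n_families = 30, seed = 9, bulk_depth_mean = 1,
                    parent_depth_mean = 1)
  pop <- simulate_population(g1, cfg)
  adt <- simulate_bulk_reads(pop, list(HC1 = pop$family_id[1:5],
                                       HC2 = pop$family_id[6:10]), cfg)
  expect_gt(sum(is.na(adt$hc1_donor)), 0)
  expect_identical(is.na(adt$hc1_donor), is.na(adt$hc1_recurrent))
  tr <- snp_index_track(adt)
  expect_true(all(is.na(tr$index_hc1[is.na(adt$hc1_donor)])))
})

test_that("bulk validation rejects bad memberships", {
  cfg <- sim_config(n_families = 10, seed = 1)
  pop <- simulate_population(g1, cfg)
  expect_error(simulate_bulk_reads(pop, list(HC1 = character(0),
                                             HC2 = pop$family_id[1:2]), cfg),
               "non-empty")
  expect_error(simulate_bulk_reads(pop, list(HC1 = pop$family_id[1:3],
                                             HC2 = pop$family_id[3:5]), cfg),
               "disjoint")
})

test_that("effect table and term map generators are consistent", {
  eff <- simulate_effect_table(g1, seed = 2)
  expect_identical(nrow(eff), length(g1$snp_positions$A10))
  expect_true(all(eff$class[is.na(eff$gene_id)] == "intergenic"))
  expect_true(all(!is.na(eff$gene_id[eff$class != "intergenic"])))
  # both genic and intergenic SNPs must actually occur
  expect_gt(sum(!is.na(eff$gene_id)), 0.3 * nrow(eff))
  expect_gt(sum(is.na(eff$gene_id)), 0.1 * nrow(eff))
  # gene ids are consistent with SNP coordinates (same 100 kb slot)
  slot <- floor((eff$pos[!is.na(eff$gene_id)] - 1) / 1e5) + 1
  expect_identical(eff$gene_id[!is.na(eff$gene_id)],
                   sprintf("GH_A10G%04d", slot))
  genes <- sort(unique(stats::na.omit(eff$gene_id)))
  tm <- simulate_term_map(genes, seed = 2)
  expect_true(all(tm$gene2term$term_id %in% tm$term_meta$term_id))
  expect_true(all(tm$gene2term$gene_id %in% genes))
})
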