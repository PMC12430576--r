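# Shared fixtures, built in code.

one_chrom_genome <- function(length_bp = 10e6, morgans = 1, spacing = 2e5,
                             name = "A10") {
  genome_spec(data.frame(name = name, length_bp = length_bp,
                         map_length_morgans = morgans),
              snp_spacing_bp = spacing)
}

# hand-built SNP-index track rows (already polarized)
make_track <- function(index_hc1, index_hc2, depth_hc1, depth_hc2,
                       chrom = "A10", pos = NULL) {
  n <- length(index_hc1)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = n)
  tibble::tibble(chrom = chrom, pos = pos,
                 depth_hc1 = depth_hc1, depth_hc2 = depth_hc2,
                 index_hc1 = index_hc1, index_hc2 = index_hc2,
                 delta = index_hc1 - index_hc2,
                 filter_status = "pass")
}

# hand-built window table ready for call_regions()
make_windows <- function(start, end, mean_delta, ci99_high = 0.3,
                         chrom = "A10") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 n_sites = 20L, mean_index_hc1 = NA_real_,
                 mean_index_hc2 = NA_real_, mean_delta = mean_delta,
                 mean_depth_hc1 = 30, mean_depth_hc2 = 30,
                 missing = FALSE,
                 ci95_low = -ci99_high * 0.8, ci95_high = ci99_high * 0.8,
                 ci99_low = -ci99_high, ci99_high = ci99_high)
}

# minimal VCF text with the four study samples
write_test_vcf <- function(records, path,
                           samples = c("P60", "P36", "HC1", "HC2")) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=A10>",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

study_roles <- c(P60 = "recurrent_parent", P36 = "donor_parent",
                 HC1 = "HC1", HC2 = "HC2")
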