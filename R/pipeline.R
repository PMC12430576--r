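#' Configuration of an end-to-end run
#'
#' Bundles every stage's parameters: the genome and simulation design (or, in
#' `"vcf"` mode, the input VCF and its sample-role map), bulk sizes, locus
#' filters, the window scan, the null model, and output options.
#'
#' @param mode `"synthetic"` (simulate the population and its sequencing) or
#'   `"vcf"` (start from a VCF with per-sample allele depths).
#' @param genome a [genome_spec()] (synthetic mode).
#' @param sim a [sim_config()] (synthetic mode); its seed drives all
#'   simulation randomness.
#' @param window a [window_spec()].
#' @param null a [null_model()].
#' @param n_high,n_low bulk sizes for rank-truncation selection (synthetic
#'   mode).
#' @param min_index,min_depth,index_rule,depth_rule site filters, see
#'   [filter_sites()].
#' @param confidence calling confidence (95 or 99).
#' @param tail calling tail, see [call_regions()].
#' @param vcf_path,sample_roles inputs for `"vcf"` mode, see
#'   [read_vcf_allele_depths()].
#' @param phenotype_path TSV of family phenotypes (`"vcf"` mode; optional).
#' @param effects effect table (tibble) or `NULL` to simulate one in synthetic
#'   mode.
#' @param term_map list(gene2term, term_meta) or `NULL` to simulate one.
#' @param out_dir directory for artifacts, or `NULL` to skip writing.
#' @param make_plots write the per-chromosome scan figure.
#' @param allow_empty_scan continue (with an empty window scan) when no site
#'   passes the filters, instead of raising; defaults to `TRUE` in synthetic
#'   mode, where sparse pass-filter tracks are an expected outcome of
#'   null-calibration designs, and `FALSE` for real data, where it signals a
#'   misconfigured run.
#' @export
run_config <- function(mode = c("synthetic", "vcf"),
                       genome = demo_genome(), sim = sim_config(),
                       window = window_spec(), null = null_model(),
                       n_high = 20, n_low = 12,
                       min_index = 0.5, min_depth = 5,
                       index_rule = "both", depth_rule = "either",
                       confidence = 99, tail = "positive",
                       vcf_path = NULL, sample_roles = NULL,
                       phenotype_path = NULL,
                       effects = NULL, term_map = NULL,
                       out_dir = NULL, make_plots = FALSE,
                       allow_empty_scan = NULL) {
  mode <- match.arg(mode)
  if (mode == "vcf") {
    if (is.null(vcf_path) || is.null(sample_roles)) {
      stop("vcf mode needs vcf_path and sample_roles")
    }
    if (!file.exists(vcf_path)) stop("vcf_path does not exist: ", vcf_path)
  }
  if (is.null(allow_empty_scan)) allow_empty_scan <- mode == "synthetic"
  structure(list(mode = mode, genome = genome, sim = sim, window = window,
                 null = null, n_high = n_high, n_low = n_low,
                 min_index = min_index, min_depth = min_depth,
                 index_rule = index_rule, depth_rule = depth_rule,
                 confidence = confidence, tail = tail,
                 vcf_path = vcf_path, sample_roles = sample_roles,
                 phenotype_path = phenotype_path,
                 effects = effects, term_map = term_map,
                 out_dir = out_dir, make_plots = make_plots,
                 allow_empty_scan = allow_empty_scan),
            class = "run_config")
}

# hash of the semantic configuration (paths and output switches excluded)
config_hash <- function(cfg) {
  sem <- cfg[setdiff(names(cfg), c("vcf_path", "phenotype_path", "out_dir",
                                   "make_plots"))]
  f <- tempfile()
  on.exit(unlink(f))
  dput(sem, file = f, control = c("all", "digits17"))
  unname(tools::md5sum(f))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full BSA-Seq analysis
#'
#' Executes the stages in order -- population simulation (or VCF import),
#' phenotype summaries and normality screen, extreme-bulk construction,
#' pooled-read simulation, SNP-index track, locus filters, window scan,
#' confidence envelopes, region calling, candidate-gene extraction and term
#' enrichment -- with a manifest of stagewise record counts. Deterministic
#' given the configured seeds. Any stage failure aborts with the stage named.
#'
#' @param cfg a [run_config()].
#' @return list with the `manifest` and every intermediate artifact
#'   (`phenotypes`, `summaries`, `bulks`, `adt`, `track`, `windows`,
#'   `regions`, `gene_report`, `enrichment`, `truth`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  manifest <- list(version = as.character(utils::packageVersion("bulkseg")),
                   config_hash = config_hash(cfg),
                   mode = cfg$mode,
                   seed = if (cfg$mode == "synthetic") cfg$sim$seed else cfg$null$seed)
  pop <- phen <- bulks <- truth <- NULL
  summaries <- NULL

  if (cfg$mode == "synthetic") {
    pop <- stage_try("simulate", simulate_population(cfg$genome, cfg$sim))
    phen <- stage_try("phenotypes", simulate_phenotypes(pop, cfg$sim))
    summaries <- stage_try("phenostats", {
      s_len <- summarize_trait(phen$fiber_length)
      s_str <- summarize_trait(phen$fiber_strength)
      tibble::tibble(trait = c("fiber_length", "fiber_strength"),
                     rbind(s_len, s_str),
                     normal = c(normality_screen(s_len)$pass,
                                normality_screen(s_str)$pass))
    })
    bulks <- stage_try("select_bulks",
                       select_extreme_bulks(phen, cfg$n_high, cfg$n_low))
    if (length(bulks$HC1) == 0L || length(bulks$HC2) == 0L) {
      stop("pipeline stage 'select_bulks' failed: empty bulk", call. = FALSE)
    }
    adt <- stage_try("simulate_reads", simulate_bulk_reads(pop, bulks, cfg$sim))
    truth <- attr(adt, "truth")
    manifest$n_families <- cfg$sim$n_families
  } else {
    adt <- stage_try("read_vcf",
                     read_vcf_allele_depths(cfg$vcf_path, cfg$sample_roles))
    if (nrow(adt) == 0L) {
      stop("pipeline stage 'read_vcf' failed: zero informative sites",
           call. = FALSE)
    }
    if (!is.null(cfg$phenotype_path)) {
      phen <- stage_try("phenotypes", read_phenotypes_tsv(cfg$phenotype_path))
    }
    manifest$sites_dropped <- attr(adt, "dropped")
    manifest$n_input_records <- attr(adt, "n_input")
  }

  manifest$n_bulk_hc1 <- if (!is.null(bulks)) length(bulks$HC1) else cfg$null$n_hc1
  manifest$n_bulk_hc2 <- if (!is.null(bulks)) length(bulks$HC2) else cfg$null$n_hc2

  track <- stage_try("snpindex", {
    t <- snp_index_track(adt)
    filter_sites(t, cfg$min_index, cfg$min_depth, cfg$index_rule, cfg$depth_rule)
  })
  manifest$sites_total <- nrow(track)
  manifest$sites_by_status <- stats::setNames(
    as.integer(table(factor(track$filter_status, levels = filter_status_levels))),
    filter_status_levels)
  manifest$sites_pass <- manifest$sites_by_status[["pass"]]
  if (manifest$sites_pass == 0L && !cfg$allow_empty_scan) {
    stop("pipeline stage 'filter' failed: no site passes the filters ",
         "(check parents, depths and the index rule)", call. = FALSE)
  }

  chrom_lengths <- if (cfg$mode == "synthetic") {
    stats::setNames(cfg$genome$chromosomes$length_bp, cfg$genome$chromosomes$name)
  } else NULL
  windows <- stage_try("scan", {
    w <- window_scan(track, cfg$window, chrom_lengths)
    attach_thresholds(w, cfg$null, track = track)
  })
  manifest$n_windows <- nrow(windows)
  manifest$n_windows_scored <- sum(!windows$missing)
  hi <- windows[[sprintf("ci%g_high", cfg$confidence)]]
  sig <- !windows$missing & !is.na(hi) & windows$mean_delta > hi
  manifest$n_windows_significant <- sum(sig, na.rm = TRUE)
  manifest$significant_window_fraction <-
    if (manifest$n_windows_scored > 0) {
      manifest$n_windows_significant / manifest$n_windows_scored
    } else 0

  regions <- stage_try("regions",
                       call_regions(windows, cfg$confidence, cfg$tail, track = track))
  manifest$n_regions <- nrow(regions)

  effects <- cfg$effects
  if (is.null(effects) && cfg$mode == "synthetic") {
    effects <- stage_try("effects", simulate_effect_table(cfg$genome, cfg$sim$seed))
  }
  gene_report <- NULL
  enrichment <- NULL
  if (!is.null(effects)) {
    gene_report <- stage_try("genes", genes_in_regions(regions, effects))
    manifest$n_candidate_sites <- nrow(gene_report$sites)
    manifest$n_candidate_genes <- length(gene_report$genes)
    term_map <- cfg$term_map
    if (is.null(term_map) && cfg$mode == "synthetic") {
      background <- sort(unique(stats::na.omit(effects$gene_id)))
      term_map <- simulate_term_map(background, seed = cfg$sim$seed)
    }
    if (!is.null(term_map) && length(gene_report$genes) > 0) {
      background <- sort(unique(stats::na.omit(effects$gene_id)))
      enrichment <- stage_try("enrich",
                              term_enrichment(gene_report$genes, background,
                                              term_map$gene2term, term_map$term_meta))
    }
  }

  out <- list(manifest = manifest, phenotypes = phen, summaries = summaries,
              bulks = bulks, adt = adt, track = track, windows = windows,
              regions = regions, gene_report = gene_report,
              enrichment = enrichment, truth = truth)

  if (!is.null(cfg$out_dir)) {
    stage_try("write", write_run_outputs(out, cfg))
  }
  out
}

write_run_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste("seed:", res$manifest$seed),
           paste("config_hash:", res$manifest$config_hash))
  if (!is.null(res$phenotypes)) {
    write_phenotypes_tsv(res$phenotypes, file.path(cfg$out_dir, "phenotypes.tsv"))
  }
  if (!is.null(res$summaries)) {
    write_track_tsv(res$summaries, file.path(cfg$out_dir, "trait_summaries.tsv"), hdr)
  }
  if (!is.null(res$bulks)) {
    bt <- tibble::tibble(
      family_id = c(res$bulks$HC1, res$bulks$HC2),
      bulk = c(rep("HC1", length(res$bulks$HC1)), rep("HC2", length(res$bulks$HC2))))
    write_track_tsv(bt, file.path(cfg$out_dir, "bulk_membership.tsv"), hdr)
  }
  if (cfg$mode == "synthetic") {
    write_vcf(res$adt, file.path(cfg$out_dir, "bulks.vcf"))
    if (!is.null(res$truth)) {
      write_track_tsv(res$truth, file.path(cfg$out_dir, "truth_frequencies.tsv"), hdr)
    }
  }
  write_track_tsv(res$track, file.path(cfg$out_dir, "snp_index_track.tsv"), hdr)
  write_track_tsv(res$windows, file.path(cfg$out_dir, "windows.tsv"), hdr)
  write_track_tsv(res$regions, file.path(cfg$out_dir, "regions.tsv"), hdr)
  if (nrow(res$regions)) {
    write_regions_bed(res$regions, file.path(cfg$out_dir, "regions.bed"))
  }
  if (!is.null(res$gene_report)) {
    write_track_tsv(res$gene_report$sites,
                    file.path(cfg$out_dir, "candidate_sites.tsv"), hdr)
  }
  if (!is.null(res$enrichment)) {
    write_track_tsv(res$enrichment, file.path(cfg$out_dir, "enrichment.tsv"), hdr)
  }
  if (isTRUE(cfg$make_plots)) {
    plot_tracks(res$track, res$windows, cfg$out_dir)
  }
  invisible(cfg$out_dir)
}
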