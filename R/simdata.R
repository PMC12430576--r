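#' Describe a genome for population simulation
#'
#' A genome is a set of chromosomes, each with a physical length, a genetic map
#' length, and a sorted list of positions of parent-differential SNPs. It is a
#' stand-in coordinate frame for the reference genome the bulks are aligned to.
#'
#' @param chromosomes data frame with columns `name`, `length_bp`,
#'   `map_length_morgans`.
#' @param snp_positions named list (one entry per chromosome) of strictly
#'   increasing 1-based SNP positions, or `NULL` to place SNPs on a regular
#'   grid of `snp_spacing_bp`.
#' @param snp_spacing_bp grid spacing used when `snp_positions` is `NULL`.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, snp_positions = NULL, snp_spacing_bp = 50000) {
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "length_bp", "map_length_morgans") %in% names(chromosomes)))
  if (nrow(chromosomes) < 1L) stop("genome must declare at least one chromosome")
  if (any(chromosomes$length_bp < 1)) stop("chromosome lengths must be positive")
  if (any(chromosomes$map_length_morgans < 0)) stop("map lengths must be >= 0")
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (is.null(snp_positions)) {
    snp_positions <- lapply(seq_len(nrow(chromosomes)), function(i) {
      seq(snp_spacing_bp, chromosomes$length_bp[i], by = snp_spacing_bp)
    })
    names(snp_positions) <- chromosomes$name
  }
  if (!setequal(names(snp_positions), chromosomes$name)) {
    stop("snp_positions names must match chromosome names")
  }
  for (nm in chromosomes$name) {
    p <- snp_positions[[nm]]
    L <- chromosomes$length_bp[chromosomes$name == nm]
    if (length(p) && (is.unsorted(p, strictly = TRUE) || p[1] < 1 || p[length(p)] > L)) {
      stop("SNP positions on ", nm, " must be strictly increasing within [1, length_bp]")
    }
  }
  if (sum(lengths(snp_positions)) == 0L) stop("genome must carry at least one SNP")
  structure(list(chromosomes = chromosomes, snp_positions = snp_positions[chromosomes$name]),
            class = "genome_spec")
}

#' Four-chromosome demonstration genome
#'
#' A reduced tetraploid-cotton-like coordinate frame: four chromosomes of 25 Mb
#' / 1 Morgan each with parent-differential SNPs every 50 kb. Chromosome names
#' follow the A-subgenome labelling convention.
#'
#' @param n_chrom number of chromosomes (1--4).
#' @param length_bp,map_length_morgans per-chromosome size.
#' @param snp_spacing_bp SNP grid spacing.
#' @export
demo_genome <- function(n_chrom = 4, length_bp = 25e6, map_length_morgans = 1,
                        snp_spacing_bp = 50000) {
  nm <- c("A07", "A08", "A09", "A10")[seq_len(n_chrom)]
  genome_spec(data.frame(name = nm, length_bp = length_bp,
                         map_length_morgans = map_length_morgans),
              snp_spacing_bp = snp_spacing_bp)
}

#' Simulation configuration
#'
#' Study-design parameters for the synthetic BC\eqn{_6}F\eqn{_2} population:
#' pedigree depth, family count, planted QTLs, trait noise, sequencing depths.
#'
#' @param n_backcross backcross generations between the F1 and the selfing step.
#' @param n_families number of BC\eqn{_n}F\eqn{_2} families.
#' @param qtl `NULL`, or a data frame with columns `chrom`, `pos_bp`,
#'   `effect_strength` (cN/tex) and optionally `effect_length` (mm; defaults to
#'   `0.6 * effect_strength * 0.5`, a shared pleiotropic effect). A homozygous
#'   donor genotype shifts the trait by the full effect, a heterozygote by half.
#' @param baseline named vector `c(length=, strength=)` of trait means
#'   (mm, cN/tex).
#' @param env_sd named vector of residual standard deviations per trait;
#'   the residual absorbs environment and polygenic background.
#' @param trait_cor correlation of the two traits' residuals.
#' @param targets_per_family number of donor segments per family retained by
#'   marker-assisted selection during backcrossing (0 = neutral backcrossing).
#' @param parent_depth_mean,bulk_depth_mean mean per-site sequencing depths.
#' @param error_rate symmetric per-read allele flip probability.
#' @param seed integer seed governing every stochastic step.
#' @export
sim_config <- function(n_backcross = 6, n_families = 184, qtl = NULL,
                       baseline = c(length = 29.6, strength = 33.7),
                       env_sd = c(length = 1.0, strength = 2.1),
                       trait_cor = 0.6, targets_per_family = 3,
                       parent_depth_mean = 20, bulk_depth_mean = 30,
                       error_rate = 0.001, seed = 1L) {
  stopifnot(n_backcross >= 0, n_families >= 1,
            parent_depth_mean > 0, bulk_depth_mean > 0,
            error_rate >= 0, error_rate < 0.5,
            targets_per_family >= 0)
  if (any(env_sd < 0)) stop("env_sd must be >= 0")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    stopifnot(all(c("chrom", "pos_bp", "effect_strength") %in% names(qtl)))
    if (is.null(qtl$effect_length)) qtl$effect_length <- 0.3 * qtl$effect_strength
  }
  structure(list(n_backcross = as.integer(n_backcross),
                 n_families = as.integer(n_families), qtl = qtl,
                 baseline = baseline, env_sd = env_sd, trait_cor = trait_cor,
                 targets_per_family = as.integer(targets_per_family),
                 parent_depth_mean = parent_depth_mean,
                 bulk_depth_mean = bulk_depth_mean,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

check_qtl_on_genome <- function(genome, qtl) {
  if (is.null(qtl)) return(invisible(TRUE))
  for (i in seq_len(nrow(qtl))) {
    ch <- as.character(qtl$chrom[i])
    if (!ch %in% genome$chromosomes$name) {
      stop("QTL chromosome ", ch, " is not declared in the genome")
    }
    L <- genome$chromosomes$length_bp[genome$chromosomes$name == ch]
    if (qtl$pos_bp[i] < 1 || qtl$pos_bp[i] > L) stop("QTL position off chromosome ", ch)
  }
  invisible(TRUE)
}

#' Simulate a backcross chromosome-segment substitution population
#'
#' Runs gametes through the pedigree F1 -> BC1 ... BC_n (each generation
#' crossed to a fully recurrent-parent gamete) -> one selfing, with Haldane
#' (Poisson, no-interference) crossovers at each chromosome's map length.
#' Each family descends from an independent lineage. When
#' `cfg$targets_per_family > 0`, each lineage is assigned that many uniformly
#' placed target loci and the backcross gamete is redrawn until it retains the
#' donor allele at all of them (marker-assisted segment retention, the way CSSL
#' libraries are built); the selfing meiosis is never conditioned, so target
#' loci segregate 1:2:1 among families.
#'
#' @param genome a [genome_spec()].
#' @param cfg a [sim_config()].
#' @return an object of class `bsa_population`: per-family donor segments and
#'   homolog pairs, per-chromosome dose matrices at the genome's SNPs
#'   (0/1/2 donor doses), per-family genome-wide donor fraction, and a truth
#'   record carrying the planted QTLs.
#' @export
simulate_population <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "sim_config"))
  check_qtl_on_genome(genome, cfg$qtl)
  set.seed(cfg$seed)
  chr <- genome$chromosomes
  n_chr <- nrow(chr)
  n_fam <- cfg$n_families

  # Target loci for marker-assisted retention: a CSSL library is designed to
  # tile the donor genome, so the k * n_families targets sit on an even grid
  # over the concatenated genome and family f takes grid points
  # f, f + n_families, ... -- neighbouring loci are covered by distinct
  # families and every region is covered by a near-constant number of lines.
  targets <- vector("list", n_fam)
  if (cfg$targets_per_family > 0L) {
    G <- sum(chr$length_bp)
    offs <- c(0, cumsum(chr$length_bp))[seq_len(n_chr)]
    k <- cfg$targets_per_family
    grid <- (seq_len(k * n_fam) - 0.5) * G / (k * n_fam)
    fam_order <- sample.int(n_fam)          # which family owns which stride
    for (f in seq_len(n_fam)) {
      gpos <- grid[fam_order[f] + (seq_len(k) - 1L) * n_fam]
      ci <- findInterval(gpos, c(offs, G))
      targets[[f]] <- data.frame(chrom = chr$name[ci],
                                 pos = pmax(1, floor(gpos - offs[ci]) + 1L))
    }
  }

  families <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    fam <- vector("list", n_chr)
    names(fam) <- chr$name
    for (c_i in seq_len(n_chr)) {
      L <- chr$length_bp[c_i]; M <- chr$map_length_morgans[c_i]
      tpos <- if (is.null(targets[[f]])) numeric(0) else
        targets[[f]]$pos[targets[[f]]$chrom == chr$name[c_i]]
      hap <- seg_full(L)           # F1 donor homolog; the other homolog is recurrent
      for (g in seq_len(cfg$n_backcross)) {
        best <- NULL; best_hit <- -1L
        for (try in seq_len(64L)) {
          cand <- meiosis_gamete(hap, seg_empty(), L, M)
          hit <- if (length(tpos)) sum(seg_contains(cand, tpos)) else 0L
          if (hit > best_hit) { best <- cand; best_hit <- hit }
          if (best_hit == length(tpos)) break
        }
        hap <- best
      }
      # selfing of the BC_nF1 (homologs: hap / recurrent), unconditioned
      fam[[c_i]] <- list(h1 = meiosis_gamete(hap, seg_empty(), L, M),
                         h2 = meiosis_gamete(hap, seg_empty(), L, M))
    }
    families[[f]] <- fam
  }

  doses <- lapply(seq_len(n_chr), function(c_i) {
    p <- genome$snp_positions[[c_i]]
    m <- matrix(0L, nrow = n_fam, ncol = length(p))
    for (f in seq_len(n_fam)) {
      m[f, ] <- seg_contains(families[[f]][[c_i]]$h1, p) +
        seg_contains(families[[f]][[c_i]]$h2, p)
    }
    m
  })
  names(doses) <- chr$name

  total_bp <- sum(chr$length_bp)
  donor_fraction <- vapply(families, function(fam) {
    sum(vapply(fam, function(h) seg_width(h$h1) + seg_width(h$h2), 0)) / (2 * total_bp)
  }, 0)

  structure(list(genome = genome, cfg = cfg, families = families,
                 doses = doses, donor_fraction = donor_fraction,
                 family_id = sprintf("F%03d", seq_len(n_fam)),
                 truth = list(qtl = cfg$qtl)),
            class = "bsa_population")
}

#' Donor dose of every family at an arbitrary genomic position
#'
#' @param pop a `bsa_population`.
#' @param chrom,pos locus (1-based).
#' @return integer vector of 0/1/2 donor doses, one per family.
#' @export
dose_at <- function(pop, chrom, pos) {
  vapply(pop$families, function(fam) {
    h <- fam[[as.character(chrom)]]
    if (is.null(h)) stop("chromosome ", chrom, " not in population")
    as.integer(seg_contains(h$h1, pos) + seg_contains(h$h2, pos))
  }, 0L)
}

#' Number of distinct introgressed regions per family
#'
#' Counts, for each family, the donor-origin segments of the homolog pair
#' merged per chromosome (overlapping homologous segments count once) --
#' the "segment count" a CSSL library would report.
#'
#' @param pop a `bsa_population`.
#' @return integer vector, one count per family.
#' @export
donor_segment_count <- function(pop) {
  vapply(pop$families, function(fam) {
    sum(vapply(fam, function(h) nrow(seg_union(h$h1, h$h2)), 0L))
  }, 0L)
}

#' QTL effect sized to explain a given fraction of trait variance
#'
#' Given the realized donor doses at a locus, returns the additive effect `a`
#' (trait shift of the homozygous donor genotype; heterozygote a/2) such that
#' the locus explains `frac` of the total trait variance against a residual
#' standard deviation `resid_sd`: `var(dose * a / 2) = frac/(1-frac) * resid_sd^2`.
#'
#' @param doses integer vector of 0/1/2 donor doses across families.
#' @param resid_sd residual (non-QTL) trait standard deviation.
#' @param frac target fraction of variance explained, in (0, 1).
#' @export
qtl_effect_for_variance <- function(doses, resid_sd, frac = 0.5) {
  stopifnot(frac > 0, frac < 1, resid_sd > 0)
  sd_d <- stats::sd(doses)
  if (sd_d == 0) stop("locus is monomorphic in this population; cannot size an effect")
  2 * resid_sd * sqrt(frac / (1 - frac)) / sd_d
}

#' Simulate fiber-quality phenotypes
#'
#' Trait model per family: `baseline + sum(dose_q * effect_q / 2) + residual`,
#' where the residuals of the two traits are bivariate normal with standard
#' deviations `cfg$env_sd` and correlation `cfg$trait_cor`. QTL effects are
#' shared across the traits (each QTL carries a strength and a length effect),
#' so the genetic and residual channels both contribute to the observed
#' length-strength correlation.
#'
#' @param pop a `bsa_population`.
#' @param cfg a [sim_config()]; its `qtl` (possibly `NULL`) defines the genetic
#'   architecture.
#' @return tibble with columns `family_id`, `fiber_length` (mm),
#'   `fiber_strength` (cN/tex); the per-family QTL dose matrix is attached as
#'   attribute `"qtl_dose"`.
#' @export
simulate_phenotypes <- function(pop, cfg = pop$cfg) {
  stopifnot(inherits(pop, "bsa_population"), inherits(cfg, "sim_config"))
  if (any(cfg$env_sd < 0)) stop("env_sd must be >= 0")
  set.seed(cfg$seed + 1L)
  n <- length(pop$families)
  g_len <- numeric(n); g_str <- numeric(n)
  qd <- NULL
  if (!is.null(cfg$qtl) && nrow(cfg$qtl) > 0) {
    qd <- sapply(seq_len(nrow(cfg$qtl)), function(i) {
      dose_at(pop, cfg$qtl$chrom[i], cfg$qtl$pos_bp[i])
    })
    qd <- matrix(qd, nrow = n)
    g_str <- as.vector(qd %*% (cfg$qtl$effect_strength / 2))
    g_len <- as.vector(qd %*% (cfg$qtl$effect_length / 2))
  }
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- cfg$trait_cor
  e_len <- cfg$env_sd[["length"]] * z1
  e_str <- cfg$env_sd[["strength"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
  out <- tibble::tibble(family_id = pop$family_id,
                        fiber_length = cfg$baseline[["length"]] + g_len + e_len,
                        fiber_strength = cfg$baseline[["strength"]] + g_str + e_str)
  attr(out, "qtl_dose") <- qd
  out
}

#' Simulate pooled sequencing of parents and extreme bulks
#'
#' For every SNP the true donor-allele frequency of a bulk is the summed donor
#' dose of its member families over `2 * bulk size` chromosomes. Per sample,
#' site depth is Poisson around the configured mean and donor-supporting reads
#' are binomial at the true frequency perturbed by the symmetric per-read error
#' rate; the parents are fixed (frequencies 0 and 1). A Poisson draw of zero
#' depth leaves the site missing (`NA`) for that sample.
#'
#' @param pop a `bsa_population`.
#' @param bulks named list `list(HC1 = ids, HC2 = ids)` of family ids; must be
#'   disjoint and non-empty.
#' @param cfg a [sim_config()].
#' @return an allele-depth table: tibble with one row per SNP, columns `chrom`,
#'   `pos`, allele bases, REF orientation, and `<role>_recurrent` /
#'   `<role>_donor` read counts for roles `p_rec`, `p_don`, `hc1`, `hc2`.
#'   True per-bulk donor frequencies are attached as attribute `"truth"`.
#' @export
simulate_bulk_reads <- function(pop, bulks, cfg = pop$cfg) {
  stopifnot(inherits(pop, "bsa_population"), inherits(cfg, "sim_config"))
  if (!all(c("HC1", "HC2") %in% names(bulks))) stop("bulks must name HC1 and HC2")
  i1 <- match(bulks$HC1, pop$family_id); i2 <- match(bulks$HC2, pop$family_id)
  if (anyNA(i1) || anyNA(i2)) stop("unknown family ids in bulks")
  if (length(i1) == 0L || length(i2) == 0L) stop("bulks must be non-empty")
  if (length(intersect(i1, i2))) stop("bulks must be disjoint")
  set.seed(cfg$seed + 2L)

  chr_names <- pop$genome$chromosomes$name
  per_chr <- lapply(chr_names, function(ch) {
    p <- pop$genome$snp_positions[[ch]]
    d <- pop$doses[[ch]]
    tibble::tibble(chrom = ch, pos = p,
                   true_freq_hc1 = colSums(d[i1, , drop = FALSE]) / (2 * length(i1)),
                   true_freq_hc2 = colSums(d[i2, , drop = FALSE]) / (2 * length(i2)))
  })
  sites <- do.call(rbind, per_chr)
  n <- nrow(sites)
  e <- cfg$error_rate

  draw <- function(freq, depth_mean) {
    depth <- stats::rpois(n, depth_mean)
    p <- freq * (1 - e) + (1 - freq) * e
    donor <- ifelse(depth > 0, stats::rbinom(n, depth, p), NA_integer_)
    depth[depth == 0] <- NA_integer_
    list(recurrent = depth - donor, donor = donor)
  }
  pr <- draw(rep(0, n), cfg$parent_depth_mean)
  pd <- draw(rep(1, n), cfg$parent_depth_mean)
  b1 <- draw(sites$true_freq_hc1, cfg$bulk_depth_mean)
  b2 <- draw(sites$true_freq_hc2, cfg$bulk_depth_mean)

  bases <- c("A", "C", "G", "T")
  rec_base <- sample(bases, n, replace = TRUE)
  don_base <- vapply(rec_base, function(b) sample(setdiff(bases, b), 1L), "")

  adt <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                        recurrent_base = rec_base, donor_base = unname(don_base),
                        ref_is_recurrent = stats::runif(n) < 0.5,
                        p_rec_recurrent = pr$recurrent, p_rec_donor = pr$donor,
                        p_don_recurrent = pd$recurrent, p_don_donor = pd$donor,
                        hc1_recurrent = b1$recurrent, hc1_donor = b1$donor,
                        hc2_recurrent = b2$recurrent, hc2_donor = b2$donor)
  attr(adt, "truth") <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                                       true_freq_hc1 = sites$true_freq_hc1,
                                       true_freq_hc2 = sites$true_freq_hc2)
  attr(adt, "bulk_sizes") <- c(HC1 = length(i1), HC2 = length(i2))
  adt
}

effect_classes <- c("exonic_nonsynonymous", "exonic_synonymous", "stopgain",
                    "stoploss", "intronic", "intergenic", "other")

#' Simulate a variant-effect annotation table
#'
#' Lays a regular gene grid over the genome (one gene model every
#' `gene_spacing_bp`) and assigns each SNP a functional class with genome-like
#' proportions dominated by intergenic, intronic and synonymous changes; SNPs
#' with a genic class carry the id of their grid gene. Used by the synthetic
#' pipeline route; real analyses supply their own annotation table.
#'
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @param gene_spacing_bp gene grid spacing.
#' @return tibble `chrom`, `pos`, `gene_id`, `class` (one row per SNP), plus a
#'   `"genes"` attribute with the gene grid.
#' @export
simulate_effect_table <- function(genome, seed = 1L, gene_spacing_bp = 100000) {
  stopifnot(inherits(genome, "genome_spec"))
  set.seed(seed + 3L)
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(c_i) {
    ch <- genome$chromosomes$name[c_i]
    L <- genome$chromosomes$length_bp[c_i]
    p <- genome$snp_positions[[ch]]
    n_genes <- max(1L, ceiling(L / gene_spacing_bp))
    gid <- sprintf("GH_%sG%04d", ch, seq_len(n_genes))
    slot <- pmin(floor((p - 1) / gene_spacing_bp) + 1L, n_genes)
    cls <- sample(
      c("intergenic", "intronic", "exonic_synonymous", "exonic_nonsynonymous",
        "stopgain", "stoploss", "other"),
      length(p), replace = TRUE,
      prob = c(0.35, 0.29, 0.14, 0.15, 0.010, 0.004, 0.046))
    tibble::tibble(chrom = ch, pos = p,
                   gene_id = ifelse(cls == "intergenic", NA_character_,
                                    gid[slot]),
                   class = cls)
  })
  eff <- do.call(rbind, out)
  genes <- unique(stats::na.omit(eff$gene_id))
  attr(eff, "genes") <- genes
  eff
}

#' Simulate a gene-to-term annotation map
#'
#' Random gene/term incidences over the four standard namespaces, for
#' exercising the enrichment step on synthetic runs.
#'
#' @param genes character vector of gene ids.
#' @param n_terms number of distinct terms.
#' @param mean_terms_per_gene expected annotation count per gene.
#' @param seed integer seed.
#' @return list with tibbles `gene2term` (`gene_id`, `term_id`) and
#'   `term_meta` (`term_id`, `namespace`, `description`).
#' @export
simulate_term_map <- function(genes, n_terms = 40, mean_terms_per_gene = 4,
                              seed = 1L) {
  set.seed(seed + 4L)
  ns <- sample(c("BP", "MF", "CC", "pathway"), n_terms, replace = TRUE,
               prob = c(0.4, 0.25, 0.2, 0.15))
  term_id <- sprintf("T%04d", seq_len(n_terms))
  # skewed term popularity, as in real ontologies
  pop_w <- stats::rexp(n_terms) + 0.1
  g2t <- lapply(genes, function(g) {
    k <- stats::rpois(1, mean_terms_per_gene)
    k <- min(max(k, 1L), n_terms)
    tibble::tibble(gene_id = g,
                   term_id = sample(term_id, k, prob = pop_w))
  })
  list(gene2term = do.call(rbind, g2t),
       term_meta = tibble::tibble(term_id = term_id, namespace = ns,
                                  description = paste("synthetic term", term_id)))
}
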