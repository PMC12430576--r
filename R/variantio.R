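#' Write an allele-depth table as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with per-sample `AD` (ref,alt read counts) and `DP`
#' for the two parents and two bulks. REF/ALT orientation follows the table's
#' `ref_is_recurrent` flag, so the file exercises both polarities; sites
#' missing in a sample are written as `.`.
#'
#' @param adt allele-depth table from [simulate_bulk_reads()] or
#'   [read_vcf_allele_depths()].
#' @param path output path.
#' @param sample_names VCF sample names for the roles
#'   (recurrent parent, donor parent, superior bulk, inferior bulk).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(adt, path,
                      sample_names = c(p_rec = "P60", p_don = "P36",
                                       hc1 = "HC1", hc2 = "HC2")) {
  stopifnot(all(c("p_rec", "p_don", "hc1", "hc2") %in% names(sample_names)))
  ref <- ifelse(adt$ref_is_recurrent, adt$recurrent_base, adt$donor_base)
  alt <- ifelse(adt$ref_is_recurrent, adt$donor_base, adt$recurrent_base)
  fmt_sample <- function(rec, don) {
    a1 <- ifelse(adt$ref_is_recurrent, rec, don)   # ref-supporting reads
    a2 <- ifelse(adt$ref_is_recurrent, don, rec)
    dp <- rec + don
    ifelse(is.na(dp), ".", paste0(a1, ",", a2, ":", dp))
  }
  cols <- c("p_rec", "p_don", "hc1", "hc2")
  body <- vapply(cols, function(r) {
    fmt_sample(adt[[paste0(r, "_recurrent")]], adt[[paste0(r, "_donor")]])
  }, character(nrow(adt)))
  body <- matrix(body, nrow = nrow(adt))
  chroms <- unique(adt$chrom)
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", chroms, ">"),
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", unname(sample_names[cols])), collapse = "\t"))
  lines <- paste(adt$chrom, adt$pos, ".", ref, alt, ".", "PASS", ".", "AD:DP",
                 body[, 1], body[, 2], body[, 3], body[, 4], sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

parse_ad <- function(ad) {
  # "x,y" -> matrix(ref, alt); "." or NA -> NA
  out <- matrix(NA_integer_, nrow = length(ad), ncol = 2L)
  ok <- !is.na(ad) & ad != "." & grepl(",", ad, fixed = TRUE)
  if (any(ok)) {
    sp <- strsplit(ad[ok], ",", fixed = TRUE)
    out[ok, 1L] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
    out[ok, 2L] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2L)))
  }
  out
}

#' Read per-sample allele depths from a VCF and polarize by parents
#'
#' Loads biallelic SNP records with per-sample `AD`, then polarizes each site
#' so that the "donor allele" is the allele homozygous (at the given purity)
#' in the donor-parent sample and the opposite allele is homozygous in the
#' recurrent parent. No assumption is made about which parent matches the
#' reference genome. Records that are multi-allelic, non-SNP, lack parent
#' depth, or whose parents are not (near-)opposite homozygotes are dropped,
#' with per-reason counts attached as attribute `"dropped"`.
#'
#' @param path VCF file.
#' @param sample_roles named character vector mapping VCF sample names to the
#'   four roles `"recurrent_parent"`, `"donor_parent"`, `"HC1"`, `"HC2"`.
#' @param min_parent_purity minimum major-allele read fraction for a parent to
#'   count as homozygous (default 0.9).
#' @return allele-depth table (see [simulate_bulk_reads()] for columns).
#' @export
read_vcf_allele_depths <- function(path, sample_roles,
                                   min_parent_purity = 0.9) {
  roles_needed <- c("recurrent_parent", "donor_parent", "HC1", "HC2")
  if (!setequal(unname(sample_roles), roles_needed)) {
    stop("sample_roles must map samples to exactly the roles: ",
         paste(roles_needed, collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(v@gt) == 0L) stop("VCF has no records")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("AD", fmt))) {
    bad <- which(!grepl("AD", fmt))[1]
    stop("record ", fix[bad, "CHROM"], ":", fix[bad, "POS"], " has no AD field")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  missing_samples <- setdiff(names(sample_roles), colnames(ad))
  if (length(missing_samples)) {
    stop("samples not in VCF: ", paste(missing_samples, collapse = ", "))
  }
  role_of <- stats::setNames(names(sample_roles), unname(sample_roles))
  AD <- lapply(roles_needed, function(r) parse_ad(ad[, role_of[[r]]]))
  names(AD) <- roles_needed

  n <- nrow(fix)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & grepl(",", alt, fixed = TRUE)] <- "multiallelic"
  reason[is.na(reason) & (nchar(ref) != 1L | nchar(alt) != 1L |
                            !ref %in% c("A", "C", "G", "T") |
                            !alt %in% c("A", "C", "G", "T"))] <- "not_snp"

  pr <- AD$recurrent_parent; pd <- AD$donor_parent
  pr_dp <- pr[, 1] + pr[, 2]; pd_dp <- pd[, 1] + pd[, 2]
  no_parent <- is.na(pr_dp) | is.na(pd_dp) | pr_dp == 0 | pd_dp == 0
  reason[is.na(reason) & no_parent] <- "parent_missing"

  # major allele (1 = REF, 2 = ALT) and its purity, per parent
  maj <- function(m) ifelse(m[, 1] >= m[, 2], 1L, 2L)
  purity <- function(m) pmax(m[, 1], m[, 2]) / (m[, 1] + m[, 2])
  pr_maj <- maj(pr); pd_maj <- maj(pd)
  informative <- !no_parent & pr_maj != pd_maj &
    purity(pr) >= min_parent_purity & purity(pd) >= min_parent_purity
  reason[is.na(reason) & !informative] <- "non_informative"

  keep <- is.na(reason)
  dropped <- table(factor(reason[!keep],
                          levels = c("multiallelic", "not_snp", "parent_missing",
                                     "non_informative")))
  donor_is_alt <- pd_maj == 2L

  pick <- function(m) {
    # (recurrent_reads, donor_reads) given donor allele identity
    rec <- ifelse(donor_is_alt, m[, 1], m[, 2])
    don <- ifelse(donor_is_alt, m[, 2], m[, 1])
    list(rec = rec, don = don)
  }
  b1 <- pick(AD$HC1); b2 <- pick(AD$HC2); p1 <- pick(pr); p2 <- pick(pd)

  adt <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    recurrent_base = ifelse(donor_is_alt, ref, alt),
    donor_base = ifelse(donor_is_alt, alt, ref),
    ref_is_recurrent = donor_is_alt,
    p_rec_recurrent = p1$rec, p_rec_donor = p1$don,
    p_don_recurrent = p2$rec, p_don_donor = p2$don,
    hc1_recurrent = b1$rec, hc1_donor = b1$don,
    hc2_recurrent = b2$rec, hc2_donor = b2$don)[keep, ]
  adt <- adt[order(adt$chrom, adt$pos), ]
  if (anyDuplicated(paste(adt$chrom, adt$pos))) stop("duplicate site keys in VCF")
  attr(adt, "dropped") <- stats::setNames(as.integer(dropped), names(dropped))
  attr(adt, "n_input") <- n
  adt
}

#' Write candidate regions as BED
#'
#' 1-based inclusive regions `[start, end]` become 0-based half-open BED lines
#' `(start-1, end)`. Score is the region's peak |delta(SNP-index)| scaled by
#' 1000 and clamped to \code{[0, 1000]}.
#'
#' @param regions region tibble from [call_regions()] (needs `chrom`, `start`,
#'   `end`, `region_id`, `peak_delta`).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions)) {
    o <- order(regions$chrom, regions$start)
    if (!identical(o, seq_len(nrow(regions)))) stop("regions must be sorted")
  }
  score <- if (nrow(regions)) pmin(pmax(round(abs(regions$peak_delta) * 1000), 0), 1000) else integer(0)
  d <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                  end = regions$end, name = regions$region_id,
                  score = score, strand = ".")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Lossless TSV round trip for tracks and tables
#'
#' Writes any plain tibble as TSV with a `#coltypes` comment line so that
#' [read_track_tsv()] restores column classes exactly; extra `#`-prefixed
#' header comments (e.g. the seed) are passed through.
#'
#' @param track a tibble/data frame of atomic columns.
#' @param path file path.
#' @param header_comments optional character vector written as leading
#'   `# `-prefixed lines.
#' @rdname track_tsv
#' @export
write_track_tsv <- function(track, path, header_comments = character(0)) {
  types <- vapply(track, function(x) class(x)[1], "")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  writeLines(paste0("#coltypes\t", paste(names(types), types, sep = "=", collapse = "\t")), con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname track_tsv
#' @export
read_track_tsv <- function(path) {
  lines <- readLines(path)
  ct_line <- grep("^#coltypes\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character")
  if (length(ct_line)) {
    spec <- strsplit(sub("^#coltypes\t", "", ct_line[1]), "\t")[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    for (p in kv) {
      nm <- p[1]; cls <- p[2]
      if (nm %in% names(d)) {
        d[[nm]] <- switch(cls,
                          integer = as.integer(d[[nm]]),
                          numeric = as.numeric(d[[nm]]),
                          logical = as.logical(d[[nm]]),
                          factor = factor(d[[nm]]),
                          d[[nm]])
      }
    }
  }
  tibble::as_tibble(d)
}
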