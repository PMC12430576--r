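#' Per-bulk SNP-index
#'
#' The fraction of a bulk's reads at a site carrying the donor-parent allele:
#' 0 means the bulk matches the recurrent parent, 1 means fully donor.
#' Vectorized; a site with zero (or missing) total depth yields `NA`, never 0.
#'
#' @param donor_reads,total_reads non-negative integer vectors,
#'   `donor_reads <= total_reads`.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @export
snp_index <- function(donor_reads, total_reads) {
  if (any(donor_reads > total_reads, na.rm = TRUE)) {
    stop("donor_reads cannot exceed total_reads")
  }
  if (any(donor_reads < 0 | total_reads < 0, na.rm = TRUE)) stop("negative read counts")
  out <- donor_reads / total_reads
  out[is.na(total_reads) | (!is.na(total_reads) & total_reads == 0)] <- NA_real_
  out
}

#' Delta(SNP-index) between the two extreme bulks
#'
#' `index(HC1, superior bulk) - index(HC2, inferior bulk)`, in `[-1, 1]`;
#' deviates from 0 near a trait-associated locus.
#'
#' @param index_hc1,index_hc2 SNP-index values in `[0, 1]`.
#' @export
delta_snp_index <- function(index_hc1, index_hc2) {
  if (any(index_hc1 < 0 | index_hc1 > 1, na.rm = TRUE) ||
      any(index_hc2 < 0 | index_hc2 > 1, na.rm = TRUE)) {
    stop("SNP-index values must lie in [0, 1]")
  }
  index_hc1 - index_hc2
}

#' Build a per-site SNP-index track from allele depths
#'
#' @param adt allele-depth table ([simulate_bulk_reads()] /
#'   [read_vcf_allele_depths()]).
#' @return tibble with per-site `index_hc1`, `index_hc2`, `delta`, bulk depths
#'   and a `filter_status` column initialized to `"pass"`.
#' @export
snp_index_track <- function(adt) {
  d1 <- adt$hc1_recurrent + adt$hc1_donor
  d2 <- adt$hc2_recurrent + adt$hc2_donor
  i1 <- snp_index(adt$hc1_donor, d1)
  i2 <- snp_index(adt$hc2_donor, d2)
  tibble::tibble(chrom = adt$chrom, pos = adt$pos,
                 depth_hc1 = d1, depth_hc2 = d2,
                 index_hc1 = i1, index_hc2 = i2,
                 delta = delta_snp_index(i1, i2),
                 filter_status = "pass")
}

filter_status_levels <- c("pass", "low_index_both", "low_depth",
                          "missing_in_pool", "non_informative")

#' Apply the locus reliability filters
#'
#' Removes (flags) loci whose SNP-index is below `min_index` in both pools,
#' loci with depth below `min_depth`, and loci missing in either pool. An
#' index below 0.5 in only one pool is exactly the association signal sought,
#' so the index rule binds to both pools by default, while a single
#' low-coverage pool already makes the contrast unreliable, so the depth rule
#' binds to either pool by default; both groupings are switchable. Each failing
#' site carries exactly one primary reason, assessed in the order
#' low_index_both, low_depth, missing_in_pool. Never raises.
#'
#' @param track a [snp_index_track()].
#' @param min_index index cutoff (default 0.5).
#' @param min_depth depth cutoff in reads (default 5).
#' @param index_rule `"both"` (default) or `"either"`: how many pools must be
#'   below `min_index` for removal.
#' @param depth_rule `"either"` (default) or `"both"`.
#' @return the track with `filter_status` set; no rows are removed.
#' @export
filter_sites <- function(track, min_index = 0.5, min_depth = 5,
                         index_rule = c("both", "either"),
                         depth_rule = c("either", "both")) {
  index_rule <- match.arg(index_rule)
  depth_rule <- match.arg(depth_rule)
  lo1 <- track$index_hc1 < min_index
  lo2 <- track$index_hc2 < min_index
  low_index <- if (index_rule == "both") lo1 & lo2 else lo1 | lo2
  low_index[is.na(low_index)] <- FALSE
  d1 <- track$depth_hc1 < min_depth
  d2 <- track$depth_hc2 < min_depth
  low_depth <- if (depth_rule == "either") d1 | d2 else d1 & d2
  low_depth[is.na(low_depth)] <- FALSE
  missing <- is.na(track$index_hc1) | is.na(track$index_hc2)
  status <- rep("pass", nrow(track))
  status[missing] <- "missing_in_pool"
  # the index and depth rules are assessed on fully observed sites, in order:
  # low_index_both takes precedence over low_depth
  status[!missing & low_depth] <- "low_depth"
  status[!missing & low_index] <- "low_index_both"
  track$filter_status <- status
  track
}

#' Sliding-window scan specification
#'
#' @param window_size_bp window width (default 1 Mb).
#' @param step_bp step between window starts (default 100 kb); must not exceed
#'   the window size.
#' @param min_sites minimum pass-filter sites for a window mean to be
#'   reported (default 10).
#' @export
window_spec <- function(window_size_bp = 1e6, step_bp = 1e5, min_sites = 10) {
  stopifnot(window_size_bp > 0, step_bp > 0, min_sites >= 1)
  if (step_bp > window_size_bp) stop("step must not exceed the window size")
  structure(list(window_size_bp = window_size_bp, step_bp = step_bp,
                 min_sites = min_sites), class = "window_spec")
}

#' Sliding-window means of SNP-index and delta(SNP-index)
#'
#' Windows tile each chromosome from position 1 at the given step (1-based
#' inclusive coordinates, last window clipped at the chromosome end).
#' Per-window statistics are unweighted means over member pass-filter sites;
#' windows with fewer than `spec$min_sites` sites are flagged `missing` and
#' excluded from region calling.
#'
#' @param track a filtered [snp_index_track()].
#' @param spec a [window_spec()].
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @return window tibble with means, mean depths and the `missing` flag; the
#'   spec is attached as attribute `"spec"`.
#' @export
window_scan <- function(track, spec = window_spec(), chrom_lengths = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  pass <- track[track$filter_status == "pass", ]
  chroms <- unique(track$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(track$pos[track$chrom == ch]), 0)
  }
  res <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1, max(1, L), by = spec$step_bp)
    ends <- pmin(starts + spec$window_size_bp - 1, L)
    s <- pass[pass$chrom == ch, ]
    s <- s[order(s$pos), ]
    pos <- s$pos
    # cumulative sums give O(1) window means over the sorted site list
    cs <- function(x) cumsum(ifelse(is.na(x), 0, x))
    c_i1 <- cs(s$index_hc1); c_i2 <- cs(s$index_hc2); c_d <- cs(s$delta)
    c_d1 <- cs(s$depth_hc1); c_d2 <- cs(s$depth_hc2)
    lo <- findInterval(starts - 0.5, pos)       # sites strictly before start
    hi <- findInterval(ends + 0.5, pos)         # sites at or before end
    n <- hi - lo
    wmean <- function(c_x) {
      tot <- ifelse(hi > 0, c_x[pmax(hi, 1L)], 0) - ifelse(lo > 0, c_x[pmax(lo, 1L)], 0)
      ifelse(n > 0, tot / n, NA_real_)
    }
    tibble::tibble(chrom = ch, start = starts, end = ends, n_sites = n,
                   mean_index_hc1 = wmean(c_i1), mean_index_hc2 = wmean(c_i2),
                   mean_delta = wmean(c_d),
                   mean_depth_hc1 = wmean(c_d1), mean_depth_hc2 = wmean(c_d2),
                   missing = n < spec$min_sites)
  })
  out <- do.call(rbind, res)
  attr(out, "spec") <- spec
  out
}

#' Null model for the delta(SNP-index) confidence envelope
#'
#' @param method `"simulation"` (depth-aware null simulation, the QTL-seq
#'   convention) or `"label_permutation"` (site-wise shuffling of the two
#'   bulks' read-count pairs, yielding a global envelope).
#' @param n_reps replicates (default 10,000; at least 1,000 for production
#'   use).
#' @param n_hc1,n_hc2 bulk sizes in families (defaults 20 and 12; each
#'   contributes two chromosomes).
#' @param seed integer seed for the envelope draws.
#' @export
null_model <- function(method = c("simulation", "label_permutation"),
                       n_reps = 10000, n_hc1 = 20, n_hc2 = 12, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1, n_hc1 >= 1, n_hc2 >= 1)
  structure(list(method = method, n_reps = as.integer(n_reps),
                 n_hc1 = as.integer(n_hc1), n_hc2 = as.integer(n_hc2),
                 seed = as.integer(seed)), class = "null_model")
}

# nearest-rank (inverse ECDF) empirical quantile
quantile_nearest_rank <- function(x, p) {
  x <- sort(x)
  x[pmin(pmax(ceiling(p * length(x)), 1L), length(x))]
}

# one batch of simulated null deltas at a fixed depth pair: per replicate each
# bulk's allele frequency is drawn by sampling 2*n chromosomes at the
# segregating-site expectation 0.5, then reads are binomial at that frequency
sim_null_delta <- function(depth_hc1, depth_hc2, n_hc1, n_hc2, n_reps) {
  f1 <- stats::rbinom(n_reps, 2L * n_hc1, 0.5) / (2 * n_hc1)
  f2 <- stats::rbinom(n_reps, 2L * n_hc2, 0.5) / (2 * n_hc2)
  i1 <- stats::rbinom(n_reps, depth_hc1, f1) / depth_hc1
  i2 <- stats::rbinom(n_reps, depth_hc2, f2) / depth_hc2
  i1 - i2
}

#' Simulated null thresholds for delta(SNP-index)
#'
#' Empirical `(alpha/2, 1 - alpha/2)` nearest-rank quantiles of the no-QTL
#' null distribution of site-level delta(SNP-index) at the given read depths,
#' from `null$n_reps` Monte-Carlo replicates (see [null_model()]).
#'
#' @param depth_hc1,depth_hc2 per-bulk read depths (scalars, >= 1).
#' @param null a [null_model()].
#' @param confidence confidence level in percent, strictly between 0 and 100.
#' @return named numeric `c(lower, upper)`.
#' @export
null_thresholds <- function(depth_hc1, depth_hc2, null = null_model(),
                            confidence = 99) {
  stopifnot(inherits(null, "null_model"), depth_hc1 >= 1, depth_hc2 >= 1)
  if (confidence <= 0 || confidence >= 100) stop("confidence must be in (0, 100)")
  set.seed(null$seed)
  d <- sim_null_delta(depth_hc1, depth_hc2, null$n_hc1, null$n_hc2, null$n_reps)
  a <- 1 - confidence / 100
  c(lower = quantile_nearest_rank(d, a / 2),
    upper = quantile_nearest_rank(d, 1 - a / 2))
}

#' Exact null distribution of delta(SNP-index) (enumeration oracle)
#'
#' Exhaustively enumerates the finite null distribution: bulk frequencies over
#' the exact Binomial(2n, 0.5)/2n support, read counts over Binomial(depth, f)
#' outcomes, and the product distribution of the two bulks' index difference.
#' Intended for validating the Monte-Carlo sampler at small depths.
#'
#' @inheritParams null_thresholds
#' @return list with sorted `delta` values, their `prob`, and `cdf`.
#' @export
null_delta_exact <- function(depth_hc1, depth_hc2, n_hc1 = 20, n_hc2 = 12) {
  read_dist <- function(depth, n_fam) {
    j <- 0:(2 * n_fam)
    wf <- stats::dbinom(j, 2 * n_fam, 0.5)
    f <- j / (2 * n_fam)
    r <- 0:depth
    # P(reads = r) = sum_f P(f) * dbinom(r, depth, f)
    p <- vapply(r, function(rr) sum(wf * stats::dbinom(rr, depth, f)), 0)
    list(x = r / depth, p = p)
  }
  d1 <- read_dist(depth_hc1, n_hc1)
  d2 <- read_dist(depth_hc2, n_hc2)
  delta <- outer(d1$x, d2$x, `-`)
  prob <- outer(d1$p, d2$p)
  o <- order(as.vector(delta))
  v <- as.vector(delta)[o]; p <- as.vector(prob)[o]
  # collapse ties
  grp <- cumsum(c(TRUE, diff(v) > 1e-12))
  v2 <- tapply(v, grp, `[`, 1L)
  p2 <- tapply(p, grp, sum)
  list(delta = as.numeric(v2), prob = as.numeric(p2), cdf = cumsum(as.numeric(p2)))
}

#' Quantile of the exact null distribution
#'
#' Smallest support value whose exact CDF reaches `p` (the population analogue
#' of the nearest-rank empirical quantile).
#'
#' @param exact result of [null_delta_exact()].
#' @param p probability in (0, 1).
#' @export
exact_null_quantile <- function(exact, p) {
  exact$delta[which(exact$cdf >= p - 1e-12)[1]]
}

#' Attach per-window confidence envelopes
#'
#' Windows inherit the null thresholds for their mean per-bulk depths
#' (rounded to the nearest read; depth-stratified, computed once per distinct
#' depth pair). With `method = "label_permutation"` a single global envelope is
#' computed by randomly swapping each site's bulk labels and pooling the
#' resulting deltas. Adds `ci95_low/high` and `ci99_low/high` columns.
#'
#' @param windows a [window_scan()] result.
#' @param null a [null_model()].
#' @param track the filtered site track (required for label permutation).
#' @param confidences confidence levels in percent (default 95 and 99).
#' @export
attach_thresholds <- function(windows, null = null_model(), track = NULL,
                              confidences = c(95, 99)) {
  stopifnot(inherits(null, "null_model"))
  for (cf in confidences) {
    windows[[sprintf("ci%g_low", cf)]] <- NA_real_
    windows[[sprintf("ci%g_high", cf)]] <- NA_real_
  }
  set.seed(null$seed)
  if (null$method == "label_permutation") {
    if (is.null(track)) stop("label_permutation needs the site track")
    pass <- track[track$filter_status == "pass", ]
    if (nrow(pass) == 0L) return(windows)
    swap <- stats::runif(null$n_reps * nrow(pass)) < 0.5
    i1 <- rep(pass$index_hc1, null$n_reps)
    i2 <- rep(pass$index_hc2, null$n_reps)
    d <- ifelse(swap, i2 - i1, i1 - i2)
    for (cf in confidences) {
      a <- 1 - cf / 100
      windows[[sprintf("ci%g_low", cf)]] <- quantile_nearest_rank(d, a / 2)
      windows[[sprintf("ci%g_high", cf)]] <- quantile_nearest_rank(d, 1 - a / 2)
    }
    return(windows)
  }
  dd1 <- pmax(1, round(windows$mean_depth_hc1))
  dd2 <- pmax(1, round(windows$mean_depth_hc2))
  key <- paste(dd1, dd2)
  ok <- !windows$missing & !is.na(windows$mean_depth_hc1) & !is.na(windows$mean_depth_hc2)
  for (k in unique(key[ok])) {
    idx <- which(key == k & ok)
    d <- sim_null_delta(dd1[idx[1]], dd2[idx[1]], null$n_hc1, null$n_hc2, null$n_reps)
    for (cf in confidences) {
      a <- 1 - cf / 100
      windows[[sprintf("ci%g_low", cf)]][idx] <- quantile_nearest_rank(d, a / 2)
      windows[[sprintf("ci%g_high", cf)]][idx] <- quantile_nearest_rank(d, 1 - a / 2)
    }
  }
  windows
}

#' Call candidate regions from significant windows
#'
#' A window is significant when its mean delta(SNP-index) exceeds the upper
#' envelope at the requested confidence (positive tail by default, matching
#' positive regulation by the donor allele; `tail = "both"` also calls the
#' negative tail). Significant windows on a chromosome separated by at most
#' `gap_bp` merge into one region (overlapping windows merge automatically);
#' region span is `end - start` in bp.
#'
#' @param windows thresholded windows from [attach_thresholds()].
#' @param confidence 95 or 99 (default 99).
#' @param tail `"positive"` (default) or `"both"`.
#' @param gap_bp maximum merge gap; defaults to the scan's step.
#' @param track optional site track, used to count member pass sites.
#' @return tibble of regions: `region_id`, `chrom`, `start`, `end`, `span_bp`,
#'   `n_windows`, `peak_start`, `peak_end`, `peak_delta`, `n_sites`.
#' @export
call_regions <- function(windows, confidence = 99, tail = c("positive", "both"),
                         gap_bp = NULL, track = NULL) {
  tail <- match.arg(tail)
  hi <- windows[[sprintf("ci%g_high", confidence)]]
  lo <- windows[[sprintf("ci%g_low", confidence)]]
  if (is.null(hi)) stop("no thresholds at ", confidence, "% attached")
  if (is.null(gap_bp)) {
    spec <- attr(windows, "spec")
    gap_bp <- if (is.null(spec)) 0 else spec$step_bp
  }
  sig <- !windows$missing & !is.na(hi) & windows$mean_delta > hi
  if (tail == "both") sig <- sig | (!windows$missing & !is.na(lo) & windows$mean_delta < lo)
  sig[is.na(sig)] <- FALSE
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch & sig, ]
    if (nrow(w) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(start = w$start, end = w$end),
                          min.gapwidth = gap_bp + 1)
    for (i in seq_len(length(ir))) {
      s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
      member <- w[w$start >= s & w$end <= e, ]
      pk <- member[which.max(member$mean_delta), ]
      n_sites <- if (!is.null(track)) {
        sum(track$filter_status == "pass" & track$chrom == ch &
              track$pos >= s & track$pos <= e)
      } else NA_integer_
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = s, end = e, span_bp = e - s,
        n_windows = nrow(member), peak_start = pk$start, peak_end = pk$end,
        peak_delta = pk$mean_delta, n_sites = n_sites)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(region_id = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0), span_bp = numeric(0),
                          n_windows = integer(0), peak_start = numeric(0),
                          peak_end = numeric(0), peak_delta = numeric(0),
                          n_sites = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  tibble::tibble(region_id = sprintf("region_%02d", seq_len(nrow(res))), res)
}
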