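#' Summary statistics for a quantitative fiber trait
#'
#' Returns the descriptive statistics conventionally tabulated for a mapping
#' population: mean, sample standard deviation, coefficient of variation
#' (percent), skewness and excess kurtosis (adjusted Fisher-Pearson,
#' bias-corrected -- the SPSS/Excel convention, `e1071` type 2), extremes and
#' range. Constant input is flagged degenerate: sd and CV are 0 and the moment
#' ratios are reported as `NA` rather than propagating 0/0.
#'
#' @param values numeric vector, `n >= 2`, all finite.
#' @return one-row tibble with columns `mean`, `sd`, `cv`, `skewness`,
#'   `kurtosis`, `max`, `min`, `range`, `n`, `degenerate`.
#' @export
summarize_trait <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  m <- mean(values)
  degenerate <- s == 0
  tibble::tibble(
    mean = m, sd = s,
    cv = if (degenerate) 0 else 100 * s / m,
    skewness = if (degenerate || length(values) < 3L) NA_real_ else
      e1071::skewness(values, type = 2),
    kurtosis = if (degenerate || length(values) < 4L) NA_real_ else
      e1071::kurtosis(values, type = 2),
    max = max(values), min = min(values), range = max(values) - min(values),
    n = length(values), degenerate = degenerate)
}

#' Normality screen on trait moments
#'
#' The quantitative-trait screen used before bulk construction: a trait is
#' treated as approximately normal when both |skewness| and |excess kurtosis|
#' are strictly below 1. This is the heuristic screen, not a formal test.
#'
#' @param summary a row from [summarize_trait()].
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
normality_screen <- function(summary) {
  if (isTRUE(summary$degenerate) || is.na(summary$skewness) || is.na(summary$kurtosis)) {
    return(list(pass = FALSE, reasons = "degenerate"))
  }
  reasons <- character(0)
  if (!(abs(summary$skewness) < 1)) reasons <- c(reasons, "skewness")
  if (!(abs(summary$kurtosis) < 1)) reasons <- c(reasons, "kurtosis")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Threshold rule for extreme-bulk membership
#'
#' Conjunctive truncation thresholds: the superior bulk requires fiber length
#' AND strength strictly above its cutoffs, the inferior bulk strictly below
#' its cutoffs. Defaults are the study thresholds (30.5/31 high, 29.5/30 low;
#' mm and cN/tex).
#'
#' @param length_gt,strength_gt superior-bulk lower cutoffs (exclusive).
#' @param length_lt,strength_lt inferior-bulk upper cutoffs (exclusive).
#' @export
bulk_rule <- function(length_gt = 30.5, strength_gt = 31,
                      length_lt = 29.5, strength_lt = 30) {
  if (!(length_gt > length_lt && strength_gt > strength_lt)) {
    stop("bulk rules overlap: high cutoffs must exceed low cutoffs")
  }
  structure(list(length_gt = length_gt, strength_gt = strength_gt,
                 length_lt = length_lt, strength_lt = strength_lt),
            class = "bulk_rule")
}

#' Assign families to extreme bulks by threshold rule
#'
#' HC1 (superior) collects families with both traits strictly above the high
#' cutoffs; HC2 (inferior) both strictly below the low cutoffs; everything
#' else is unassigned. Boundary values satisfy neither strict inequality.
#' Set semantics: the result is independent of row order and idempotent.
#'
#' @param table tibble with `family_id`, `fiber_length`, `fiber_strength`.
#' @param rule a [bulk_rule()].
#' @return list with character vectors `HC1`, `HC2`, `unassigned`.
#' @export
select_bulks <- function(table, rule = bulk_rule()) {
  stopifnot(inherits(rule, "bulk_rule"))
  if (nrow(table) == 0L) {
    warning("empty phenotype table: empty bulk assignment")
    return(list(HC1 = character(0), HC2 = character(0), unassigned = character(0)))
  }
  if (anyDuplicated(table$family_id)) stop("family_id must be unique")
  hi <- table$fiber_length > rule$length_gt & table$fiber_strength > rule$strength_gt
  lo <- table$fiber_length < rule$length_lt & table$fiber_strength < rule$strength_lt
  out <- list(HC1 = as.character(table$family_id[hi]),
              HC2 = as.character(table$family_id[lo]),
              unassigned = as.character(table$family_id[!hi & !lo]))
  if (length(out$HC1) == 0L || length(out$HC2) == 0L) {
    warning("one of the bulks is empty; downstream BSA cannot proceed")
  }
  out
}

#' Assign fixed-size extreme bulks by rank truncation
#'
#' Selects the `n_high` families with the largest and the `n_low` with the
#' smallest value of the ranking trait (fiber strength by default; ties broken
#' by the other trait, then by id for determinism). Guarantees the study's
#' bulk sizes on any population, which the threshold rule cannot.
#'
#' @param table phenotype tibble as in [select_bulks()].
#' @param n_high,n_low bulk sizes (defaults 20 / 12).
#' @param trait ranking trait, `"fiber_strength"` or `"fiber_length"`.
#' @return list with `HC1`, `HC2`, `unassigned` family-id vectors.
#' @export
select_extreme_bulks <- function(table, n_high = 20, n_low = 12,
                                 trait = "fiber_strength") {
  stopifnot(trait %in% c("fiber_strength", "fiber_length"))
  if (n_high + n_low > nrow(table)) stop("bulk sizes exceed the population")
  other <- setdiff(c("fiber_strength", "fiber_length"), trait)
  o <- order(table[[trait]], table[[other]], table$family_id, decreasing = TRUE)
  ids <- as.character(table$family_id[o])
  taken <- c(seq_len(n_high), length(ids) - seq_len(n_low) + 1L)
  list(HC1 = ids[seq_len(n_high)],
       HC2 = rev(ids)[seq_len(n_low)],
       unassigned = ids[-taken])
}

#' Read / write a phenotype table as TSV
#'
#' Columns `family_id`, `fiber_length_mm`, `fiber_strength_cN_tex` on disk;
#' in memory the units live in the documentation and the columns are
#' `fiber_length` / `fiber_strength`.
#'
#' @param path file path.
#' @rdname phenotype_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(family_id = as.character(d$family_id),
                 fiber_length = d$fiber_length_mm,
                 fiber_strength = d$fiber_strength_cN_tex)
}

#' @param table phenotype tibble.
#' @rdname phenotype_tsv
#' @export
write_phenotypes_tsv <- function(table, path) {
  d <- data.frame(family_id = table$family_id,
                  fiber_length_mm = table$fiber_length,
                  fiber_strength_cN_tex = table$fiber_strength)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
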