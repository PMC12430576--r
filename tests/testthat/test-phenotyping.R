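test_that("trait summaries reproduce the tabulated range identities", {
  # population extremes as printed for the mapping population
  len <- c(32.71, 26.73, 29.5, 30.1, 28.9, 31.2)
  s <- summarize_trait(len)
  expect_equal(s$range, 5.98)
  expect_equal(s$max, 32.71)
  expect_equal(s$min, 26.73)
  str <- c(38.70, 26.70, 33.1, 35.4, 30.2)
  expect_equal(summarize_trait(str)$range, 12.00)
})

test_that("moment estimators follow the bias-corrected convention", {
  x <- c(-1, 0, 1)
  s <- summarize_trait(x)
  expect_equal(s$mean, 0)
  expect_equal(s$skewness, 0)
  # independent closed-form check of the adjusted Fisher-Pearson skewness
  y <- c(2, 4, 4, 4, 5, 5, 7, 9)
  n <- length(y)
  m2 <- mean((y - mean(y))^2); m3 <- mean((y - mean(y))^3)
  g1 <- m3 / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(summarize_trait(y)$skewness, G1)
  m4 <- mean((y - mean(y))^4)
  g2 <- m4 / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(summarize_trait(y)$kurtosis, G2)
})

test_that("summary identities hold on random inputs", {
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:50, 1), mean = stats::runif(1, 10, 40), sd = stats::runif(1, 0.5, 5))
    s <- summarize_trait(x)
    expect_identical(s$range, s$max - s$min)
    expect_equal(s$cv, 100 * s$sd / s$mean)
    expect_identical(s$n, length(x))
  }
})

test_that("degenerate input is flagged, not NaN-propagated", {
  s <- summarize_trait(rep(3.2, 10))
  expect_true(s$degenerate)
  expect_identical(s$sd, 0)
  expect_identical(s$cv, 0)
  expect_true(is.na(s$skewness))
  scr <- normality_screen(s)
  expect_false(scr$pass)
  expect_identical(scr$reasons, "degenerate")
  expect_error(summarize_trait(3), "at least 2")
  expect_error(summarize_trait(c(1, NA)), "finite")
})

test_that("the |moment| < 1 normality screen is strict", {
  expect_true(normality_screen(tibble::tibble(skewness = 0.07, kurtosis = -0.38,
                                              degenerate = FALSE))$pass)
  expect_true(normality_screen(tibble::tibble(skewness = -0.20, kurtosis = -0.19,
                                              degenerate = FALSE))$pass)
  r <- normality_screen(tibble::tibble(skewness = 1.0, kurtosis = 0,
                                       degenerate = FALSE))
  expect_false(r$pass)
  expect_identical(r$reasons, "skewness")
})

test_that("simulated populations pass the normality screen in most runs", {
  pop <- simulate_population(one_chrom_genome(), sim_config(seed = 1))
  pass <- vapply(1:100, function(s) {
    ph <- simulate_phenotypes(pop, sim_config(seed = 1000 + s))
    normality_screen(summarize_trait(ph$fiber_length))$pass &&
      normality_screen(summarize_trait(ph$fiber_strength))$pass
  }, NA)
  expect_gte(mean(pass), 0.9)
})

test_that("threshold bulks follow both strict conjunctions", {
  tab <- tibble::tibble(family_id = paste0("F", 1:5),
                        fiber_length = c(31.0, 30.6, 29.0, 29.4, 30.0),
                        fiber_strength = c(32.0, 31.5, 29.5, 30.5, 30.5))
  b <- select_bulks(tab, bulk_rule())
  expect_setequal(b$HC1, c("F1", "F2"))
  expect_identical(b$HC2, "F3")           # F4 fails strength < 30
  expect_setequal(b$unassigned, c("F4", "F5"))
  # partition + disjointness
  expect_setequal(c(b$HC1, b$HC2, b$unassigned), tab$family_id)
  expect_length(intersect(b$HC1, b$HC2), 0)
})

test_that("bulk selection has set semantics", {
  set.seed(2)
  tab <- tibble::tibble(family_id = sprintf("F%03d", 1:80),
                        fiber_length = stats::rnorm(80, 30, 1.2),
                        fiber_strength = stats::rnorm(80, 31, 2.2))
  b1 <- select_bulks(tab)
  b2 <- select_bulks(tab[sample(80), ])          # order independence
  expect_setequal(b1$HC1, b2$HC1)
  expect_setequal(b1$HC2, b2$HC2)
  sub <- tab[tab$family_id %in% c(b1$HC1, b1$HC2), ]
  b3 <- select_bulks(sub)                        # idempotence on selected rows
  expect_setequal(b3$HC1, b1$HC1)
  expect_setequal(b3$HC2, b1$HC2)
  expect_length(intersect(b1$HC1, b1$HC2), 0)
})

test_that("degenerate bulk selections warn", {
  expect_warning(b <- select_bulks(tibble::tibble(family_id = character(0),
                                                  fiber_length = numeric(0),
                                                  fiber_strength = numeric(0))),
                 "empty")
  expect_length(b$HC1, 0)
  expect_error(bulk_rule(length_gt = 29, length_lt = 30), "overlap")
})

test_that("rank truncation returns the requested extremes", {
  set.seed(3)
  tab <- tibble::tibble(family_id = sprintf("F%03d", 1:50),
                        fiber_length = stats::rnorm(50, 30, 1),
                        fiber_strength = stats::rnorm(50, 31, 2))
  b <- select_extreme_bulks(tab, n_high = 10, n_low = 6)
  expect_length(b$HC1, 10)
  expect_length(b$HC2, 6)
  expect_length(intersect(b$HC1, b$HC2), 0)
  expect_setequal(c(b$HC1, b$HC2, b$unassigned), tab$family_id)
  expect_gt(min(tab$fiber_strength[tab$family_id %in% b$HC1]),
            max(tab$fiber_strength[tab$family_id %in% b$HC2]))
  expect_error(select_extreme_bulks(tab, n_high = 40, n_low = 20), "exceed")
})

test_that("phenotype TSV round-trips", {
  tab <- tibble::tibble(family_id = c("F001", "F002"),
                        fiber_length = c(29.56, 31.02),
                        fiber_strength = c(33.69, 35.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes_tsv(tab, f)
  expect_equal(read_phenotypes_tsv(f), tab)
})
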