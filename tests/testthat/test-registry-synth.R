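test_that("parameter validation rejects impossible configurations", {
  expect_error(simulation_params(a2 = 0.7, c2 = 0.5, seed = 1), "a2")
  expect_error(simulation_params(baseline_prevalence = 0.6, seed = 1),
               "prevalence")
  expect_error(simulation_params(n_clusters = 0, seed = 1), "n_clusters")
  expect_error(simulation_params(seed = NULL), "seed")
  expect_error(simulate_pair_phenotypes(1, c(0, 0), 10), "rho")
})

test_that("identical seeds yield identical registries", {
  p <- simulation_params(n_clusters = 500, seed = 99)
  expect_identical(simulate_registry(p), simulate_registry(p))
  r3 <- simulate_registry(simulation_params(n_clusters = 500, seed = 100))
  expect_false(identical(simulate_registry(p)$affected, r3$affected))
})

test_that("prevalence tracks the birth-year-dependent threshold", {
  # pure-noise liability at median threshold: affected fraction ~ 0.5
  reg <- simulate_registry(simulation_params(
    n_clusters = 10000, a2 = 0, c2 = 0, baseline_prevalence = 0.4999,
    seed = 7))
  n <- nrow(reg)
  expect_lt(abs(mean(reg$affected) - 0.5), 3 * sqrt(0.25 / n))

  # with a slope, each birth-year slice follows pnorm(-t(year))
  p <- simulation_params(n_clusters = 60000, a2 = 0.3, c2 = 0.1,
                         baseline_prevalence = 0.1,
                         birth_year_slope = 0.02, seed = 8)
  reg <- simulate_registry(p)
  for (yr in c(1955, 1980, 2005)) {
    sl <- reg[reg$birth_year == yr, ]
    expected <- pnorm(-(p$baseline_threshold + 0.02 * (yr - 1980)))
    se <- sqrt(expected * (1 - expected) / nrow(sl))
    expect_lt(abs(mean(sl$affected) - expected), 3 * se)
  }
})

test_that("sibling liability correlations match the kinship structure", {
  # pure additive liability: full sibs correlate 0.5, half sibs 0.25
  reg <- simulate_registry(simulation_params(
    n_clusters = 40000, a2 = 1, c2 = 0,
    cluster_type_mix = c(full_2 = 0.5, full_3 = 0, full_4 = 0,
                         mixed = 0.5),
    baseline_prevalence = 0.1, seed = 17))
  cl <- sibling_clusters(reg)
  pairs <- select_study_pairs(cl, reg, seed = 18)
  pp <- pair_phenotypes(pairs, reg)
  liab <- setNames(reg$liability, reg$person_id)
  for (s in c("full", "paternal_half", "maternal_half")) {
    sel <- pp[pp$relationship == s, ]
    r <- cor(liab[sel$index_id], liab[sel$sibling_id])
    k <- kinship_coefficient(s)
    expect_lt(abs(r - k), 3 / sqrt(nrow(sel)))
  }
})

test_that("estimated pair correlation converges to k_A*a2 + c2", {
  # full-sib-only registry under an AE truth at low prevalence; the
  # tetrachoric fit on the collapsed pairs recovers 0.5*a2
  p <- simulation_params(n_clusters = 1e6, a2 = 0.29, c2 = 0,
                         cluster_type_mix = c(full_2 = 1, full_3 = 0,
                                              full_4 = 0, mixed = 0),
                         baseline_prevalence = 0.0017, seed = 27)
  reg <- simulate_registry(p)
  # size-2 clusters: children are emitted consecutively, so pair rows up
  stopifnot(nrow(reg) == 2e6)
  a1 <- reg$affected[seq(1, 2e6, by = 2)]
  a2 <- reg$affected[seq(2, 2e6, by = 2)]
  k <- a1 + a2
  tab <- pair_table(sum(k == 2), sum(k == 1), sum(k == 0), "full")
  fit <- fit_tetrachoric(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho - 0.5 * 0.29), 3 * fit$se_rho)
})

test_that("direct pair-phenotype simulation matches orthant probabilities", {
  # independence at the median cut: each raw cell is a quarter
  tab <- simulate_pair_phenotypes(0, c(0, 0), 1e5, seed = 5)
  expect_lt(abs(tab$n10 / tab$total - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_lt(abs(tab$n11 / tab$total - 0.25), 3 * sqrt(0.1875 / 1e5))

  # near-comonotone liabilities leave almost no discordant pairs
  tab <- simulate_pair_phenotypes(0.9999, c(1, 1), 1e5, seed = 6)
  expect_lt(tab$n10 / tab$total, 0.005)

  # rare-trait cell fraction matches the orthant probability
  t <- qnorm(1 - 0.0017)
  tab <- simulate_pair_phenotypes(0.18, c(t, t), 2e6, seed = 7)
  p11 <- orthant_upper(t, t, 0.18)
  expect_lt(abs(tab$n11 / tab$total - p11), 3 * sqrt(p11 / 2e6))
})

test_that("registry files round-trip through TSV", {
  reg <- simulate_registry(simulation_params(n_clusters = 100, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(back$person_id, reg$person_id)
  expect_equal(back$affected, reg$affected)
  expect_false("liability" %in% names(back))
})
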