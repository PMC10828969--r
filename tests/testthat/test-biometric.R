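test_that("implied pair correlation follows the sharing coefficients", {
  expect_equal(implied_pair_correlation(0.28, 0, "full"), 0.14)
  expect_equal(implied_pair_correlation(0, 0.3, "maternal_half"), 0.3)
  expect_equal(implied_pair_correlation(0.4, 0.1, "paternal_half"), 0.2)
  expect_equal(kinship_coefficient(c("full", "half")), c(0.5, 0.25))
  expect_error(implied_pair_correlation(0.8, 0.3, "full"), "<= 1")
  expect_error(kinship_coefficient("cousin"), "unknown")
})

test_that("joint likelihood reduces to independent binomials at a2=c2=0", {
  tabs <- list(full = pair_table(12, 80, 400, "full"),
               half = pair_table(3, 40, 300, "half"))
  t <- 0.6
  got <- joint_neg_loglik(c(0, 0, t), tabs)
  p <- 1 - pnorm(t)
  closed <- -sum(vapply(tabs, function(tb)
    tb$n11 * log(p^2) + tb$n10 * log(2 * p * (1 - p)) +
      tb$n00 * log((1 - p)^2), numeric(1)))
  expect_equal(got, closed, tolerance = 1e-10)
})

test_that("joint likelihood is smooth in a2", {
  tabs <- nst_pair_counts()
  f <- function(a2) joint_neg_loglik(c(a2, 0.01, 2.9), tabs)
  g1 <- (f(0.3 + 1e-5) - f(0.3 - 1e-5)) / 2e-5
  g2 <- (f(0.3 + 1e-6) - f(0.3 - 1e-6)) / 2e-6
  expect_equal(g1, g2, tolerance = 1e-3)
  expect_equal(g1, numDeriv::grad(f, 0.3), tolerance = 1e-3)
})

test_that("infeasible variance components hit the optimizer sentinel", {
  tabs <- nst_pair_counts()
  expect_equal(joint_neg_loglik(c(1, 0.9, 2.9), tabs), 1e10)
})

test_that("AE on full siblings alone equals twice the tetrachoric rho", {
  tab <- nst_pair_counts()$full
  rho_hat <- fit_tetrachoric(tab)$rho
  ae <- fit_biometric(list(full = tab), model = "AE")
  expect_true(ae$converged)
  expect_equal(ae$a2, 2 * rho_hat, tolerance = 1e-3)
  expect_equal(ae$a2 + ae$e2, 1, tolerance = 1e-8)
})

test_that("ACE is refused for a single sharing coefficient", {
  expect_error(fit_biometric(list(full = nst_pair_counts()$full),
                             model = "ACE"), "flat")
})

test_that("likelihood is flat along k_A*a2 + c2 = constant with one stratum", {
  tab <- list(full = pair_table(30, 200, 2000, "full"))
  target <- 0.5 * 0.2 + 0.05  # implied rho 0.15
  vals <- vapply(seq(0, 2 * target, length.out = 7), function(c2)
    joint_neg_loglik(c((target - c2) / 0.5, c2, 1.2), tab), numeric(1))
  expect_lt(max(vals) - min(vals), 1e-8)
})

test_that("joint ACE estimates respect normalization and ordering", {
  tabs <- nst_pair_counts()
  ace <- fit_biometric(tabs, model = "ACE")
  ae <- fit_biometric(tabs, model = "AE")
  expect_true(ace$converged && ae$converged)
  expect_equal(ace$a2 + ace$c2 + ace$e2, 1, tolerance = 1e-8)
  expect_gte(ace$a2, 0); expect_gte(ace$c2, 0)
  # ACE nests AE, so its maximized likelihood cannot be lower, and neither
  # can exceed the sum of per-stratum saturated tetrachoric likelihoods
  expect_gte(ace$loglik, ae$loglik - 1e-6)
  sat <- sum(vapply(tabs, function(tb) fit_tetrachoric(tb)$loglik,
                    numeric(1)))
  expect_lte(ace$loglik, sat + 1e-6)
})

test_that("likelihood-ratio comparison behaves at and away from the null", {
  tabs <- nst_pair_counts()
  ace <- fit_biometric(tabs, model = "ACE")
  ae <- fit_biometric(tabs, model = "AE")
  lr <- likelihood_ratio(ace, ae)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 1)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  # equal log-likelihoods must give statistic 0 and p = 1
  ace0 <- ace; ace0$loglik <- ae$loglik
  lr0 <- likelihood_ratio(ace0, ae)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(likelihood_ratio(ae, ae), "more free parameters")
})

test_that("pair-level biometric fit recovers a simulated AE truth", {
  set.seed(61)
  a2 <- 0.4; t0 <- qnorm(1 - 0.08)
  strata <- list(
    full = simulate_adjusted_pairs(30000, 0.5 * a2, t0, 0.015),
    paternal_half = simulate_adjusted_pairs(12000, 0.25 * a2, t0, 0.015))
  ae <- fit_biometric(strata, model = "AE")
  expect_true(ae$converged)
  expect_lt(abs(ae$a2 - a2), 3 * ae$se_a2)
  expect_gt(ae$threshold_params[["beta1"]], 0.005)
})
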