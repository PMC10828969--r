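#' Additive-genetic sharing coefficient for a relationship stratum
#'
#' Full siblings share half of their additive genetic factors, half
#' siblings a quarter; shared environment is taken as fully shared for
#' every sibling type.
#'
#' @param relationship character vector of stratum labels; `"full"` maps to
#'   0.5, any label containing `"half"` to 0.25.
#' @return numeric vector of sharing coefficients.
#' @export
kinship_coefficient <- function(relationship) {
  r <- as.character(relationship)
  out <- ifelse(r == "full", 0.5,
                ifelse(grepl("half", r, fixed = TRUE), 0.25, NA_real_))
  if (anyNA(out)) stop("unknown relationship label: ",
                       paste(unique(r[is.na(out)]), collapse = ", "))
  out
}

#' Latent pair correlation implied by variance components
#'
#' Under the ACE decomposition the liability correlation of a sibling pair
#' is `k_A * a2 + c2`, where `k_A` is the additive-genetic sharing
#' coefficient of the relationship (0.5 full, 0.25 half) and shared
#' environment is fully shared.
#'
#' @param a2 standardized additive-genetic variance (`>= 0`).
#' @param c2 standardized shared-environment variance (`>= 0`;
#'   `a2 + c2 <= 1`).
#' @param relationship stratum label(s), see [kinship_coefficient()].
#' @return implied latent correlation(s).
#' @examples
#' implied_pair_correlation(0.28, 0, "full") # 0.14
#' @export
implied_pair_correlation <- function(a2, c2, relationship) {
  if (a2 < 0 || c2 < 0 || a2 + c2 > 1 + 1e-12)
    stop("variance components must satisfy a2 >= 0, c2 >= 0, a2 + c2 <= 1")
  kinship_coefficient(relationship) * a2 + c2
}

# ---- joint likelihood ------------------------------------------------------

.stratum_is_pairs <- function(x) is.data.frame(x)

.check_strata <- function(data) {
  if (inherits(data, "pair_table")) data <- list(data)
  if (!is.list(data) || length(data) == 0L) stop("no strata supplied")
  nm <- names(data)
  out <- lapply(seq_along(data), function(i) {
    x <- data[[i]]
    if (.stratum_is_pairs(x)) {
      rel <- if (!is.null(x$relationship)) as.character(x$relationship[1])
             else if (!is.null(attr(x, "relationship")))
               attr(x, "relationship")
             else if (!is.null(nm) && nzchar(nm[i])) nm[i]
      if (is.null(rel))
        stop("pair-level stratum needs a relationship (name or column)")
      attr(x, "relationship") <- rel
      x
    } else {
      x <- .as_pair_table(x)
      if (!is.null(nm) && nzchar(nm[i])) x$relationship <- nm[i]
      x
    }
  })
  setNames(out, vapply(out, .stratum_relationship, character(1)))
}

.stratum_relationship <- function(x)
  if (.stratum_is_pairs(x)) attr(x, "relationship") else x$relationship

#' Joint negative log-likelihood of the biometric liability model
#'
#' Sums, over relationship strata, the liability-threshold pair likelihood
#' with the latent correlation structurally replaced by
#' `k_A * a2 + c2` ([implied_pair_correlation()]). Collapsed strata use the
#' exchangeable common-cutoff likelihood; pair-level strata (data frames
#' with member birth years) use member-specific cutoffs
#' `beta0 + beta1 * (year - reference_year)`.
#'
#' `theta` is `c(a2, c2, beta0)` when all strata are collapsed tables and
#' `c(a2, c2, beta0, beta1)` when any stratum is pair-level (collapsed
#' strata then use `beta0` alone). Infeasible parameters (implied
#' correlation at or beyond 1, or a nonpositive cell probability) return a
#' large sentinel value so optimizers treat them as out of bounds.
#'
#' @param theta numeric parameter vector, see Details.
#' @param data named list of strata: `pair_table` objects and/or pair-level
#'   data frames with columns `affected1`, `affected2`, `birth_year1`,
#'   `birth_year2`; names (or a `relationship` column) give the stratum
#'   labels.
#' @param reference_year centering year for the birth-year slope.
#' @return the negative log-likelihood (scalar).
#' @export
joint_neg_loglik <- function(theta, data, reference_year = 1980) {
  data <- .check_strata(data)
  any_pairs <- any(vapply(data, .stratum_is_pairs, logical(1)))
  npar_expect <- if (any_pairs) 4L else 3L
  if (length(theta) != npar_expect)
    stop("theta must have length ", npar_expect, " for these strata")
  a2 <- theta[1]; c2 <- theta[2]; b0 <- theta[3]
  b1 <- if (any_pairs) theta[4] else 0

  total <- 0
  for (x in data) {
    rho <- kinship_coefficient(.stratum_relationship(x)) * a2 + c2
    if (rho >= 1 - 1e-10 || rho <= -1 + 1e-10) return(1e10)
    if (.stratum_is_pairs(x)) {
      agg <- aggregate(list(w = rep(1, nrow(x))),
                       by = list(y1 = x$birth_year1, y2 = x$birth_year2,
                                 a1 = x$affected1, a2 = x$affected2),
                       FUN = sum)
      v <- .tetra_adj_nll(c(b0, b1, atanh(rho)), agg, reference_year)
    } else {
      v <- .tetra_nll(c(b0, atanh(rho)), x$n11, x$n10, x$n00)
    }
    if (v >= 1e10) return(1e10)
    total <- total + v
  }
  total
}

# ---- model fitting ---------------------------------------------------------

#' Fit an ACE or AE liability-threshold model across sibling strata
#'
#' Maximizes the joint likelihood of [joint_neg_loglik()] over the
#' standardized variance components (and threshold parameters), with the
#' components constrained nonnegative. `e2` is `1 - a2 - c2` by
#' construction. Confidence intervals are delta-method intervals from the
#' inverse observed information evaluated at the constrained optimum
#' without re-imposing the bounds, so a component estimated on the boundary
#' (typically `c2 = 0`) can show a lower confidence bound slightly below
#' zero — the conventional presentation of biometric model software.
#'
#' Identifiability: separating `a2` from `c2` requires at least two strata
#' with distinct additive sharing (full plus at least one half-sibling
#' stratum); a single-stratum ACE request is refused because the likelihood
#' is flat along `k_A * a2 + c2 = constant`.
#'
#' @inheritParams joint_neg_loglik
#' @param model `"ACE"` or `"AE"` (AE fixes `c2 = 0`).
#' @param conf_level confidence level for the delta-method intervals.
#' @param start_a2 multistart values for the additive component.
#' @return an object of class `biometric_fit`: list with `model`, `a2`,
#'   `c2`, `e2`, `se_*`, `ci_*` (each `c(lower, upper)`),
#'   `threshold_params`, `loglik`, `npar`, `converged`, `n_pairs`,
#'   `strata`.
#' @examples
#' tabs <- nst_pair_counts()
#' fit_biometric(tabs, model = "AE")
#' @export
fit_biometric <- function(data, model = c("ACE", "AE"),
                          reference_year = 1980, conf_level = 0.95,
                          start_a2 = c(0.1, 0.3, 0.6)) {
  model <- match.arg(model)
  data <- .check_strata(data)
  ks <- vapply(data, function(x)
    kinship_coefficient(.stratum_relationship(x)), numeric(1))
  if (model == "ACE" && length(unique(ks)) < 2L)
    stop("ACE is not identifiable from a single sharing coefficient: ",
         "the likelihood is flat along k_A*a2 + c2 = constant; ",
         "supply both full- and half-sibling strata or fit AE")

  any_pairs <- any(vapply(data, .stratum_is_pairs, logical(1)))
  prev <- individual_prevalence(pool_pair_tables(lapply(data, function(x)
    if (.stratum_is_pairs(x)) .collapse_pairs(x) else x)))
  t0 <- qnorm(1 - min(max(prev, 1e-12), 1 - 1e-12))

  # free parameters: (a2[, c2], beta0[, beta1])
  free_c2 <- model == "ACE"
  expand <- function(par) {
    a2 <- par[1]
    c2 <- if (free_c2) par[2] else 0
    th <- par[(1L + free_c2 + 1L):length(par)]
    c(a2, c2, th)
  }
  obj <- function(par) joint_neg_loglik(expand(par), data, reference_year)

  lower <- c(0, if (free_c2) 0, -10, if (any_pairs) -1)
  upper <- c(1, if (free_c2) 1, 10, if (any_pairs) 1)
  fits <- lapply(start_a2, function(a0) {
    p0 <- c(a0, if (free_c2) 0.05, t0, if (any_pairs) 0)
    out <- try(optim(p0, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(out, "try-error"))
      out <- optim(pmin(pmax(p0, lower), upper), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 5000))
    # Nelder-Mead polish from the L-BFGS-B solution (free of bound kinks)
    pol <- optim(out$par, function(p) {
      if (any(p < lower) || any(p > upper)) return(1e10)
      obj(p)
    }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 5000))
    if (pol$value <= out$value + 1e-8) pol else out
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  par <- best$par
  theta <- expand(par)
  a2 <- theta[1]; c2 <- theta[2]; e2 <- 1 - a2 - c2

  # observed information on the free-parameter scale, unconstrained
  np <- length(par)
  se <- rep(NA_real_, np); cov_ac <- 0
  H <- try(numDeriv::hessian(obj, par), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
      if (free_c2) cov_ac <- V[1, 2]
    }
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_a2 <- se[1]
  se_c2 <- if (free_c2) se[2] else 0
  se_e2 <- if (free_c2) sqrt(se_a2^2 + se_c2^2 + 2 * cov_ac) else se_a2
  ci <- function(est, s) if (is.na(s)) c(NA_real_, NA_real_)
        else c(est - z * s, est + z * s)

  n_pairs <- sum(vapply(data, function(x)
    if (.stratum_is_pairs(x)) nrow(x) else x$total, numeric(1)))
  th <- theta[3:length(theta)]
  names(th) <- c("beta0", if (any_pairs) "beta1")

  structure(list(model = model, a2 = a2, c2 = c2, e2 = e2,
                 se_a2 = se_a2, se_c2 = if (free_c2) se_c2 else NA_real_,
                 se_e2 = se_e2,
                 ci_a2 = ci(a2, se_a2),
                 ci_c2 = if (free_c2) ci(c2, se_c2) else c(NA_real_, NA_real_),
                 ci_e2 = ci(e2, se_e2),
                 threshold_params = th, reference_year = reference_year,
                 loglik = -best$value, npar = np,
                 converged = best$convergence == 0,
                 n_pairs = n_pairs,
                 strata = vapply(data, .stratum_relationship, character(1))),
            class = "biometric_fit")
}

#' @export
print.biometric_fit <- function(x, ...) {
  fmt <- function(est, ci) {
    if (anyNA(ci)) sprintf("%.2f", est)
    else sprintf("%.2f (%.2f-%.2f)", est, ci[1], ci[2])
  }
  cat(sprintf("%s liability-threshold model (%s strata, %.0f pairs)\n",
              x$model, paste(x$strata, collapse = "+"), x$n_pairs))
  cat("  a2 =", fmt(x$a2, x$ci_a2),
      if (x$model == "ACE") paste("\n  c2 =", fmt(x$c2, x$ci_c2)) else "",
      "\n  e2 =", fmt(x$e2, x$ci_e2), "\n")
  cat(sprintf("  loglik = %.2f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Likelihood-ratio comparison of nested biometric fits
#'
#' Computes `2 * (loglik_full - loglik_reduced)` with a chi-square
#' reference whose degrees of freedom equal the parameter difference.
#' Because the dropped shared-environment component sits on the boundary of
#' its parameter space under the null, the chi-square p-value is
#' conservative (the usual boundary caveat for variance components).
#'
#' @param fit_full,fit_reduced `biometric_fit` objects on the same data,
#'   with the reduced model nested in the full one (AE within ACE).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "biometric_fit"),
            inherits(fit_reduced, "biometric_fit"))
  if (fit_full$npar <= fit_reduced$npar)
    stop("fit_full must have more free parameters than fit_reduced")
  if (!(fit_reduced$model == "AE" && fit_full$model == "ACE"))
    stop("only AE-within-ACE comparisons are supported")
  if (fit_full$n_pairs != fit_reduced$n_pairs)
    stop("fits appear to use different data (pair counts differ)")
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6) stop("reduced model fits better than full: not nested ",
                         "or optimization failed")
  stat <- max(0, stat)
  df <- fit_full$npar - fit_reduced$npar
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}
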