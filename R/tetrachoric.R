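# Exchangeable collapsed-table negative log-likelihood. Parameters on the
# optimizer scale: par = (t, atanh(rho)). Out-of-range cell probabilities
# return a large sentinel so optim never sees -Inf.
.tetra_nll <- function(par, n11, n10, n00) {
  cells <- .exch_cells(par[1], tanh(par[2]))
  if (any(cells <= 0)) return(1e10)
  -(n11 * log(cells[["p11"]]) + n10 * log(2 * cells[["p10"]]) +
      n00 * log(cells[["p00"]]))
}

#' Maximum-likelihood tetrachoric correlation from a collapsed pair table
#'
#' Fits the exchangeable liability-threshold model to a collapsed 2x2
#' sibling-pair table: both members' liabilities are standard normal with a
#' common cutoff `t` and latent correlation `rho`, and the multinomial
#' likelihood over (both affected, discordant, neither) is maximized over
#' `(t, rho)`. The discordant cell probability is doubled because member
#' order is not observed.
#'
#' Optimization runs on a transformed scale (`t` directly; `atanh(rho)` for
#' the correlation) from several starting correlations, which guards
#' against the flat likelihoods that arise in very sparse tables. Standard
#' errors come from the numerically differentiated observed information at
#' the optimum; the correlation's standard error is mapped back to the
#' natural scale by the delta method.
#'
#' @param t a `pair_table` (or anything [pair_table()]-like).
#' @param start_rho numeric vector of starting correlations for multistart.
#' @return an object of class `tetrachoric_fit`: list with `rho`,
#'   `threshold`, `prevalence` (implied `1 - pnorm(threshold)`), `se_rho`,
#'   `se_threshold`, `loglik`, `converged`, `n_pairs`, `table`.
#' @examples
#' fit_tetrachoric(pair_table(25, 5934, 1742569, "full"))
#' @export
fit_tetrachoric <- function(t, start_rho = c(0, 0.3, -0.3)) {
  tab <- .as_pair_table(t)
  if (tab$total <= 0) stop("empty pair table")
  if (tab$n11 == 0 && tab$n10 == 0) {
    # no affected members at all: threshold escapes to +Inf and rho is
    # pushed to its lower boundary; report the boundary, unconverged
    return(structure(list(rho = -1, threshold = Inf, prevalence = 0,
                          se_rho = NA_real_, se_threshold = NA_real_,
                          loglik = 0, converged = FALSE,
                          n_pairs = tab$total, table = tab),
                     class = "tetrachoric_fit"))
  }
  if (sum(c(tab$n11, tab$n10, tab$n00) > 0) < 2L)
    stop("need at least two nonzero cells to fit a tetrachoric correlation")

  prev <- individual_prevalence(tab)
  t0 <- qnorm(1 - min(max(prev, 1e-12), 1 - 1e-12))

  fits <- lapply(start_rho, function(r0) {
    optim(c(t0, atanh(r0)), .tetra_nll, n11 = tab$n11, n10 = tab$n10,
          n00 = tab$n00, method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 5000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  rho <- tanh(best$par[2])

  se <- c(NA_real_, NA_real_)
  H <- try(numDeriv::hessian(.tetra_nll, best$par, n11 = tab$n11,
                             n10 = tab$n10, n00 = tab$n00), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0))
      se <- sqrt(diag(V))
  }

  structure(list(rho = rho, threshold = best$par[1],
                 prevalence = pnorm(best$par[1], lower.tail = FALSE),
                 se_rho = se[2] * (1 - rho^2), se_threshold = se[1],
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 n_pairs = tab$total, table = tab),
            class = "tetrachoric_fit")
}

#' @export
print.tetrachoric_fit <- function(x, ...) {
  cat(sprintf("Tetrachoric fit [%s]: rho = %.4f (SE %.4f)\n",
              x$table$relationship, x$rho, x$se_rho))
  cat(sprintf("  threshold = %.4f (prevalence %.3g), loglik = %.2f, n = %.0f%s\n",
              x$threshold, x$prevalence, x$loglik, x$n_pairs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# Pair-level adjusted likelihood. Pairs are grouped by unique (t1, t2)
# cutoff combinations so the bivariate orthant is evaluated once per group.
.tetra_adj_nll <- function(par, d, ref_year) {
  rho <- tanh(par[3])
  t1 <- par[1] + par[2] * (d$y1 - ref_year)
  t2 <- par[1] + par[2] * (d$y2 - ref_year)
  key <- paste(round(t1, 12), round(t2, 12))
  grp <- match(key, unique(key))
  u <- !duplicated(grp)
  p11u <- orthant_upper(t1[u], t2[u], rho)
  p11 <- p11u[grp]
  m1 <- pnorm(t1, lower.tail = FALSE)
  m2 <- pnorm(t2, lower.tail = FALSE)
  lik <- ifelse(d$a1 == 1 & d$a2 == 1, p11,
         ifelse(d$a1 == 1 & d$a2 == 0, m1 - p11,
         ifelse(d$a1 == 0 & d$a2 == 1, m2 - p11,
                1 - m1 - m2 + p11)))
  if (any(lik <= 0)) return(1e10)
  -sum(d$w * log(lik))
}

#' Tetrachoric correlation with a birth-year-adjusted threshold
#'
#' Fits the pair-level liability-threshold likelihood in which each
#' member's cutoff depends linearly on birth year,
#' `t_i = beta0 + beta1 * (birth_year_i - reference_year)`, jointly with the
#' latent correlation `rho`. This absorbs cohort trends in prevalence that
#' would otherwise bias the correlation when birth years correlate within
#' pairs.
#'
#' @param pairs data frame with one row per pair: affection flags
#'   `affected1`, `affected2` (0/1) and birth years `birth_year1`,
#'   `birth_year2`.
#' @param reference_year calendar year at which the intercept `beta0` is
#'   anchored (default 1980).
#' @param start_rho starting correlations for multistart.
#' @return a `tetrachoric_fit` whose `threshold_params` field holds
#'   `(beta0, beta1)`; `threshold` and `prevalence` refer to the reference
#'   year.
#' @export
fit_tetrachoric_adjusted <- function(pairs, reference_year = 1980,
                                     start_rho = c(0, 0.3, -0.3)) {
  need <- c("affected1", "affected2", "birth_year1", "birth_year2")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no pairs supplied")

  years <- c(pairs$birth_year1, pairs$birth_year2)
  if (length(unique(years)) == 1L) {
    warning("no variation in birth year: slope not identifiable, ",
            "falling back to the unadjusted fit")
    tab0 <- .collapse_pairs(pairs)
    fit <- fit_tetrachoric(tab0, start_rho = start_rho)
    fit$threshold_params <- c(beta0 = fit$threshold, beta1 = 0)
    return(fit)
  }

  # aggregate identical (year1, year2, outcome) rows into weights
  agg <- aggregate(list(w = rep(1, nrow(pairs))),
                   by = list(y1 = pairs$birth_year1, y2 = pairs$birth_year2,
                             a1 = pairs$affected1, a2 = pairs$affected2),
                   FUN = sum)

  prev <- mean(c(pairs$affected1, pairs$affected2))
  t0 <- qnorm(1 - min(max(prev, 1e-12), 1 - 1e-12))
  fits <- lapply(start_rho, function(r0) {
    optim(c(t0, 0, atanh(r0)), .tetra_adj_nll, d = agg,
          ref_year = reference_year, method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 5000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  rho <- tanh(best$par[3])

  se <- rep(NA_real_, 3)
  H <- try(numDeriv::hessian(.tetra_adj_nll, best$par, d = agg,
                             ref_year = reference_year), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) se <- sqrt(diag(V))
  }

  tab <- .collapse_pairs(pairs)
  structure(list(rho = rho, threshold = best$par[1],
                 prevalence = pnorm(best$par[1], lower.tail = FALSE),
                 threshold_params = c(beta0 = best$par[1], beta1 = best$par[2]),
                 se_rho = se[3] * (1 - rho^2), se_threshold = se[1],
                 se_beta1 = se[2], reference_year = reference_year,
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 n_pairs = nrow(pairs), table = tab),
            class = "tetrachoric_fit")
}

.collapse_pairs <- function(pairs, relationship = "pair") {
  k <- pairs$affected1 + pairs$affected2
  pair_table(sum(k == 2), sum(k == 1), sum(k == 0),
             relationship = relationship)
}
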