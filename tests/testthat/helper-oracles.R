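# Independent oracles and fixture builders shared across tests.

# Exhaustive grid-search oracle for the exchangeable tetrachoric MLE.
# Independent of the package's likelihood code path: the both-affected cell
# probability is obtained from the Plackett identity
#   d/drho P(X>t, Y>t; rho) = phi2(t, t; rho)
# by cumulative trapezoidal integration of the bivariate normal density
# over the rho grid, starting from the independence value (1 - pnorm(t))^2.
tetra_grid_oracle <- function(n11, n10, n00, step = 1e-3,
                              t_range = c(-3, 3), rho_max = 0.999) {
  rho <- seq(-rho_max, rho_max, by = step)
  i0 <- which.min(abs(rho))  # rho = 0
  h <- diff(rho)
  ts <- seq(t_range[1], t_range[2], by = step)
  best <- c(t = NA_real_, rho = NA_real_, ll = -Inf)
  for (t in ts) {
    dens <- exp(-(t^2 - 2 * rho * t^2 + t^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
    panel <- (dens[-1] + dens[-length(dens)]) / 2 * h
    cumint <- c(0, cumsum(panel))          # integral from rho[1] to rho[i]
    p11 <- (1 - pnorm(t))^2 + (cumint - cumint[i0])
    p1 <- 1 - pnorm(t)
    p10 <- p1 - p11
    p00 <- 1 - 2 * p1 + p11
    ok <- p11 > 0 & p10 > 0 & p00 > 0
    if (!any(ok)) next
    ll <- rep(-Inf, length(rho))
    ll[ok] <- n11 * log(p11[ok]) + n10 * log(2 * p10[ok]) +
      n00 * log(p00[ok])
    j <- which.max(ll)
    if (ll[j] > best["ll"]) best <- c(t = t, rho = rho[j], ll = ll[j])
  }
  best
}

# Random multinomial pair table drawn from an interior (t, rho); used by the
# oracle-equivalence property test.
random_pair_table <- function(total = 200) {
  repeat {
    t <- runif(1, -0.8, 0.8)
    r <- runif(1, -0.5, 0.5)
    p11 <- sibherit::orthant_upper(t, t, r)
    p1 <- 1 - pnorm(t)
    cells <- as.vector(stats::rmultinom(1, total,
                                        c(p11, 2 * (p1 - p11),
                                          1 - 2 * p1 + p11)))
    # keep clearly interior tables so both routes have an interior optimum
    if (all(cells >= 2)) return(pair_table(cells[1], cells[2], cells[3]))
  }
}

# Pair-level data with correlated liabilities, member-specific birth years
# and a linear birth-year threshold trend; pairs' birth years are close
# (sibling-like) so within-pair years correlate.
simulate_adjusted_pairs <- function(n_pairs, rho, beta0, beta1,
                                    year_range = c(1950, 2010),
                                    ref_year = 1980, max_gap = 6) {
  y1 <- sample(year_range[1]:year_range[2], n_pairs, replace = TRUE)
  gap <- sample(1:max_gap, n_pairs, replace = TRUE)
  y2 <- pmin(pmax(y1 + gap * sample(c(-1, 1), n_pairs, replace = TRUE),
                  year_range[1]), year_range[2])
  l1 <- rnorm(n_pairs)
  l2 <- rho * l1 + sqrt(1 - rho^2) * rnorm(n_pairs)
  data.frame(affected1 = as.integer(l1 > beta0 + beta1 * (y1 - ref_year)),
             affected2 = as.integer(l2 > beta0 + beta1 * (y2 - ref_year)),
             birth_year1 = y1, birth_year2 = y2)
}

# Minimal registry builder for hand-made pedigree fixtures.
make_records <- function(person_id, mother_id, father_id,
                         birth_year = NULL, is_twin = FALSE,
                         affected = 0) {
  n <- length(person_id)
  data.frame(person_id = person_id, mother_id = mother_id,
             father_id = father_id,
             sex = rep("female", n),
             birth_year = if (is.null(birth_year)) rep(1980, n)
                          else birth_year,
             is_twin = rep(is_twin, length.out = n),
             affected = rep(affected, length.out = n),
             stringsAsFactors = FALSE)
}
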