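#' Upper-orthant probability of a standard bivariate normal
#'
#' Computes `P(X > t1, Y > t2)` where `(X, Y)` is bivariate standard normal
#' with correlation `rho`. This is the probability mass of the
#' "both-affected" cell under the liability-threshold model when the two
#' liabilities are cut at `t1` and `t2`.
#'
#' The interior case is delegated to the deterministic bivariate algorithm
#' of [mvtnorm::pmvnorm()] (`TVPACK`), accurate to well below `1e-10`.
#' The degenerate correlations `rho = 1` (comonotone liabilities) and
#' `rho = -1` are handled by their closed forms.
#'
#' @param t1,t2 liability cutoffs (finite numerics; recycled to a common
#'   length).
#' @param rho latent correlation in `[-1, 1]` (recycled likewise).
#' @return numeric vector of probabilities.
#' @examples
#' orthant_upper(0, 0, 0)      # 0.25
#' orthant_upper(0, 0, 0.5)    # 1/3
#' orthant_upper(1.5, 1.5, 1)  # 1 - pnorm(1.5)
#' @export
orthant_upper <- function(t1, t2, rho) {
  n <- max(length(t1), length(t2), length(rho))
  t1 <- rep_len(t1, n); t2 <- rep_len(t2, n); rho <- rep_len(rho, n)
  if (any(!is.finite(t1)) || any(!is.finite(t2)))
    stop("cutoffs must be finite")
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("|rho| must be <= 1")
  vapply(seq_len(n), function(i) .orthant1(t1[i], t2[i], rho[i]), numeric(1))
}

.orthant1 <- function(t1, t2, rho) {
  if (rho >= 1) return(pnorm(max(t1, t2), lower.tail = FALSE))
  if (rho <= -1) return(max(0, pnorm(-t2) - pnorm(t1)))
  if (abs(rho) < .Machine$double.eps)
    return(pnorm(t1, lower.tail = FALSE) * pnorm(t2, lower.tail = FALSE))
  p <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf),
                        corr = matrix(c(1, rho, rho, 1), 2),
                        algorithm = mvtnorm::TVPACK())
  max(0, as.numeric(p))
}

# Cell probabilities (P11, P10, P00) of the exchangeable collapsed table at a
# common cutoff t: P10 is the probability of one specific ordered discordant
# outcome, so the discordant cell carries 2*P10.
.exch_cells <- function(t, rho) {
  p11 <- .orthant1(t, t, rho)
  p1 <- pnorm(t, lower.tail = FALSE)
  c(p11 = p11, p10 = p1 - p11, p00 = 1 - 2 * p1 + p11)
}
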