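#' Parameters for the synthetic registry generator
#'
#' Collects and validates everything [simulate_registry()] needs: how many
#' family clusters to generate, the mix of cluster types, the liability
#' variance decomposition, and the birth-year-dependent threshold.
#'
#' The defaults emulate a rare phenotype in a registry-scale sibling study:
#' individual prevalence about 0.17%, about 16% of clusters containing a
#' half-sibling relation with roughly two-thirds of those paternal, birth
#' years uniform over 1950--2010, and an AE-type decomposition with
#' liability heritability 0.29.
#'
#' @param n_clusters number of family clusters (`>= 1`).
#' @param cluster_type_mix named proportions over cluster types
#'   `full_2`, `full_3`, `full_4` (full-sibling-only clusters of that size)
#'   and `mixed` (clusters containing at least one half-sibling relation).
#'   Normalized to sum 1. The full-only defaults follow a truncated
#'   geometric over sizes 2--4 — a convenience, not an inference about any
#'   real sibship-size distribution.
#' @param paternal_half_fraction proportion of mixed clusters whose
#'   half-relation is paternal (shared father) rather than maternal.
#' @param a2,c2 standardized additive-genetic and shared-environment
#'   liability variances (`a2 >= 0`, `c2 >= 0`, `a2 + c2 <= 1`);
#'   `e2 = 1 - a2 - c2`.
#' @param baseline_prevalence trait prevalence at the reference year, in
#'   `(0, 0.5)`; sets the baseline liability threshold
#'   `qnorm(1 - baseline_prevalence)`. Alternatively pass
#'   `baseline_threshold` directly (probit scale); exactly one of the two.
#' @param baseline_threshold liability threshold at the reference year.
#' @param birth_year_slope linear birth-year effect on the threshold,
#'   liability units per year (positive slope lowers prevalence for later
#'   cohorts).
#' @param birth_year_range inclusive calendar-year range for birth years.
#' @param birth_year_weights optional per-year sampling weights (length
#'   `diff(birth_year_range) + 1`); default uniform.
#' @param reference_year year at which the baseline threshold applies.
#' @param seed RNG seed (mandatory: the generator must be reproducible).
#' @return validated list of class `sim_params`.
#' @export
simulation_params <- function(n_clusters = 1000,
                              cluster_type_mix = c(full_2 = 0.48,
                                                   full_3 = 0.24,
                                                   full_4 = 0.12,
                                                   mixed = 0.16),
                              paternal_half_fraction = 0.66,
                              a2 = 0.29, c2 = 0,
                              baseline_prevalence = 0.0017,
                              baseline_threshold = NULL,
                              birth_year_slope = 0,
                              birth_year_range = c(1950, 2010),
                              birth_year_weights = NULL,
                              reference_year = 1980,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (a2 < 0 || c2 < 0 || a2 + c2 > 1)
    stop("need a2 >= 0, c2 >= 0 and a2 + c2 <= 1")
  types <- c("full_2", "full_3", "full_4", "mixed")
  if (!all(types %in% names(cluster_type_mix)))
    stop("cluster_type_mix must name ", paste(types, collapse = ", "))
  cluster_type_mix <- cluster_type_mix[types] / sum(cluster_type_mix[types])
  if (is.null(baseline_threshold)) {
    if (baseline_prevalence <= 0 || baseline_prevalence >= 0.5)
      stop("baseline_prevalence must be in (0, 0.5)")
    baseline_threshold <- qnorm(1 - baseline_prevalence)
  } else {
    baseline_prevalence <- pnorm(baseline_threshold, lower.tail = FALSE)
  }
  if (paternal_half_fraction < 0 || paternal_half_fraction > 1)
    stop("paternal_half_fraction must be in [0, 1]")
  stopifnot(length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2])
  n_years <- birth_year_range[2] - birth_year_range[1] + 1
  if (is.null(birth_year_weights)) birth_year_weights <- rep(1, n_years)
  if (length(birth_year_weights) != n_years || any(birth_year_weights < 0))
    stop("birth_year_weights must be ", n_years, " nonnegative values")
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_type_mix = cluster_type_mix,
                 paternal_half_fraction = paternal_half_fraction,
                 a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
                 baseline_threshold = baseline_threshold,
                 baseline_prevalence = baseline_prevalence,
                 birth_year_slope = birth_year_slope,
                 birth_year_range = as.integer(birth_year_range),
                 birth_year_weights = birth_year_weights,
                 reference_year = reference_year,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a registry population with kinship-structured liabilities
#'
#' Generates family clusters of children with explicit mother/father
#' identifiers and a binary phenotype produced by the liability-threshold
#' model the downstream analysis assumes. Each child's liability is
#' `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E` where the additive value `A` is
#' built from latent parental values,
#' `A = (A_mother + A_father)/2 + m` with Mendelian deviation
#' `m ~ N(0, 1/2)`, so that `cor(A)` is exactly 0.5 between full siblings
#' and 0.25 between half siblings; `C` is drawn once per cluster and fully
#' shared; `E` is individual. A child is affected when the liability
#' exceeds `baseline_threshold + birth_year_slope * (year - reference_year)`.
#'
#' Parents are latent: only children are emitted, with `is_twin` always
#' `FALSE` (twin pairs are excluded from the design). The sibling liability
#' correlation implied by the construction is `k_A * a2 + c2` with
#' `k_A = 0.5` (full) or `0.25` (half).
#'
#' @param params a `sim_params` object from [simulation_params()].
#' @return data frame with one row per child: `person_id`, `mother_id`,
#'   `father_id`, `sex`, `birth_year`, `is_twin`, `affected`, plus a
#'   diagnostic `liability` column (drop before writing registry files with
#'   [write_registry()], which does so automatically).
#' @examples
#' reg <- simulate_registry(simulation_params(n_clusters = 50, seed = 1))
#' head(reg)
#' @export
simulate_registry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  type <- sample(names(p$cluster_type_mix), p$n_clusters, replace = TRUE,
                 prob = p$cluster_type_mix)
  size_probs <- p$cluster_type_mix[c("full_2", "full_3", "full_4")]
  if (sum(size_probs) <= 0) size_probs <- c(0.48, 0.24, 0.12)
  size <- ifelse(type == "full_2", 2L, ifelse(type == "full_3", 3L,
                 ifelse(type == "full_4", 4L,
                        sample(2:4, p$n_clusters, replace = TRUE,
                               prob = size_probs))))
  paternal <- type == "mixed" &
    runif(p$n_clusters) < p$paternal_half_fraction

  n_kids <- sum(size)
  cl <- rep(seq_len(p$n_clusters), size)
  within <- sequence(size)

  # mixed clusters: two sibships sharing one parent; each child lands in
  # sibship 1 or 2, with at least one child in each (first two children are
  # pinned to different sibships, the rest assigned at random)
  sibship <- rep(1L, n_kids)
  mixed_row <- type[cl] == "mixed"
  sibship[mixed_row & within == 2L] <- 2L
  extra <- mixed_row & within > 2L
  sibship[extra] <- sample(1:2, sum(extra), replace = TRUE)

  # parent identifiers: full-only clusters have one mother and one father;
  # mixed clusters duplicate the non-shared parent across sibships
  mother_id <- ifelse(mixed_row & !paternal[cl],
                      sprintf("M%07d", cl),
                      sprintf("M%07d_%d", cl,
                              ifelse(mixed_row, sibship, 1L)))
  father_id <- ifelse(mixed_row & paternal[cl],
                      sprintf("F%07d", cl),
                      sprintf("F%07d_%d", cl,
                              ifelse(mixed_row, sibship, 1L)))

  # latent parental additive values: shared parent one draw per cluster,
  # non-shared parent one draw per sibship
  A_shared <- rnorm(p$n_clusters)[cl]
  A_side <- matrix(rnorm(2 * p$n_clusters), p$n_clusters, 2)
  A_other <- A_side[cbind(cl, sibship)]
  A <- (A_shared + A_other) / 2 + rnorm(n_kids, sd = sqrt(0.5))
  C <- rnorm(p$n_clusters)[cl]
  E <- rnorm(n_kids)
  liab <- sqrt(p$a2) * A + sqrt(p$c2) * C + sqrt(p$e2) * E

  years <- p$birth_year_range[1]:p$birth_year_range[2]
  by <- sample(years, n_kids, replace = TRUE, prob = p$birth_year_weights)
  cutoff <- p$baseline_threshold +
    p$birth_year_slope * (by - p$reference_year)

  data.frame(person_id = sprintf("P%08d", seq_len(n_kids)),
             mother_id = mother_id, father_id = father_id,
             sex = sample(c("male", "female"), n_kids, replace = TRUE),
             birth_year = by, is_twin = FALSE,
             affected = as.integer(liab > cutoff),
             liability = liab,
             stringsAsFactors = FALSE)
}

#' Simulate collapsed pair phenotypes directly from the latent model
#'
#' A fast shortcut that bypasses pedigree structure: draws `n_pairs`
#' bivariate standard-normal liabilities with correlation `rho`,
#' dichotomizes each member at its cutoff, and collapses to an
#' exchangeable count table. The expected cell fractions equal the
#' bivariate-normal orthant probabilities, so this is the generator of
#' choice for testing the tetrachoric and biometric fitters at
#' registry-scale pair counts.
#'
#' @param rho latent correlation, `|rho| < 1`.
#' @param thresholds length-2 numeric cutoffs (use equal values for the
#'   exchangeable common-threshold model).
#' @param n_pairs number of pairs (`>= 1`).
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @param relationship label for the returned table.
#' @return a `pair_table`.
#' @examples
#' simulate_pair_phenotypes(0.145, rep(qnorm(1 - 0.0017), 2), 1e5, seed = 1)
#' @export
simulate_pair_phenotypes <- function(rho, thresholds, n_pairs, seed = NULL,
                                     relationship = "pair") {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  stopifnot(length(thresholds) == 2L, all(is.finite(thresholds)))
  if (!is.null(seed)) set.seed(seed)
  n11 <- 0; n10 <- 0; n00 <- 0
  chunk <- 2e6
  left <- n_pairs
  while (left > 0) {
    m <- min(chunk, left)
    y1 <- rnorm(m)
    y2 <- rho * y1 + sqrt(1 - rho^2) * rnorm(m)
    k <- (y1 > thresholds[1]) + (y2 > thresholds[2])
    n11 <- n11 + sum(k == 2L); n10 <- n10 + sum(k == 1L)
    n00 <- n00 + sum(k == 0L)
    left <- left - m
  }
  pair_table(n11, n10, n00, relationship = relationship)
}

#' Write / read a registry table
#'
#' Tab-separated text with a header row and columns `person_id`,
#' `mother_id`, `father_id`, `sex`, `birth_year`, `is_twin`, `affected`.
#'
#' @param records registry data frame.
#' @param path file path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the registry data frame.
#' @export
write_registry <- function(records, path) {
  cols <- c("person_id", "mother_id", "father_id", "sex", "birth_year",
            "is_twin", "affected")
  stopifnot(all(cols %in% names(records)))
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  cols <- c("person_id", "mother_id", "father_id", "sex", "birth_year",
            "is_twin", "affected")
  if (!all(cols %in% names(out)))
    stop("registry file must have columns: ", paste(cols, collapse = ", "))
  out$is_twin <- as.logical(out$is_twin)
  out
}
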