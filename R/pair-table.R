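#' Collapsed exchangeable pair-count table
#'
#' A `pair_table` holds the collapsed counts of sibling pairs for one
#' relationship stratum: `n11` pairs with both members affected, `n10`
#' discordant pairs, `n00` pairs with neither member affected. Member order
#' within a pair is not observed, so the table is exchangeable and the
#' discordant cell pools both orderings.
#'
#' @param n11,n10,n00 nonnegative integer counts.
#' @param relationship stratum label (e.g. `"full"`, `"maternal_half"`,
#'   `"paternal_half"`, or a pooled label).
#' @return an object of class `pair_table`: a list with fields
#'   `relationship`, `n11`, `n10`, `n00`, `total`.
#' @examples
#' pair_table(25, 5934, 1742569, relationship = "full")
#' @export
pair_table <- function(n11, n10, n00, relationship = "pair") {
  counts <- c(n11 = n11, n10 = n10, n00 = n00)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers")
  structure(list(relationship = as.character(relationship),
                 n11 = as.double(round(n11)), n10 = as.double(round(n10)),
                 n00 = as.double(round(n00)),
                 total = as.double(round(n11 + n10 + n00))),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table [%s]: n11 = %.0f, n10 = %.0f, n00 = %.0f (total %.0f)\n",
              x$relationship, x$n11, x$n10, x$n00, x$total))
  invisible(x)
}

#' @export
as.data.frame.pair_table <- function(x, ...) {
  data.frame(relationship = x$relationship, n11 = x$n11, n10 = x$n10,
             n00 = x$n00, stringsAsFactors = FALSE)
}

.as_pair_table <- function(x) {
  if (inherits(x, "pair_table")) return(x)
  if (is.list(x) && all(c("n11", "n10", "n00") %in% names(x)))
    return(pair_table(x$n11, x$n10, x$n00,
                      if (!is.null(x$relationship)) x$relationship else "pair"))
  stop("cannot interpret input as a pair table")
}

#' Pool pair tables by summing counts
#'
#' Merges two or more strata (e.g. maternal and paternal half-siblings)
#' into a single collapsed table.
#'
#' @param ... `pair_table` objects, or a single list of them.
#' @param relationship label for the pooled stratum.
#' @return a `pair_table`.
#' @examples
#' pool_pair_tables(pair_table(1, 330, 116967, "maternal_half"),
#'                  pair_table(1, 670, 225525, "paternal_half"),
#'                  relationship = "half")
#' @export
pool_pair_tables <- function(..., relationship = "pooled") {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1]], "pair_table"))
    tabs <- tabs[[1]]
  tabs <- lapply(tabs, .as_pair_table)
  pair_table(sum(vapply(tabs, `[[`, 0, "n11")),
             sum(vapply(tabs, `[[`, 0, "n10")),
             sum(vapply(tabs, `[[`, 0, "n00")),
             relationship = relationship)
}

#' Collapse selected sibling pairs into per-stratum count tables
#'
#' Joins the affection status of both members of each selected pair and
#' tallies concordant-affected, discordant and concordant-unaffected pairs
#' within each relationship stratum.
#'
#' @param pairs data frame of selected pairs with columns `index_id`,
#'   `sibling_id`, `relationship` (as returned by [select_study_pairs()]).
#' @param records registry data frame with columns `person_id` and
#'   `affected` (as returned by [simulate_registry()] or [read_registry()]).
#' @return named list of `pair_table` objects, one per stratum present.
#' @export
build_pair_table <- function(pairs, records) {
  stopifnot(is.data.frame(pairs), is.data.frame(records))
  if (nrow(pairs) == 0L) return(list())
  aff <- setNames(records$affected, records$person_id)
  a1 <- aff[as.character(pairs$index_id)]
  a2 <- aff[as.character(pairs$sibling_id)]
  if (anyNA(a1) || anyNA(a2))
    stop("pair member missing from records")
  strata <- sort(unique(as.character(pairs$relationship)))
  out <- lapply(strata, function(s) {
    sel <- pairs$relationship == s
    k <- a1[sel] + a2[sel]
    pair_table(sum(k == 2), sum(k == 1), sum(k == 0), relationship = s)
  })
  setNames(out, strata)
}

#' Probandwise (casewise) concordance
#'
#' The probability that the sibling of an affected proband is also
#' affected: `2*n11 / (2*n11 + n10)`. Each both-affected pair contributes
#' two probands, each discordant pair one.
#'
#' @param t a `pair_table` (or list with `n11`, `n10`, `n00`).
#' @return concordance rate in `[0, 1]`.
#' @examples
#' probandwise_concordance(pair_table(25, 5934, 1742569)) # 0.00836
#' @export
probandwise_concordance <- function(t) {
  t <- .as_pair_table(t)
  d <- 2 * t$n11 + t$n10
  if (d <= 0) stop("no affected individuals: concordance undefined")
  2 * t$n11 / d
}

#' Pairwise concordance
#'
#' The proportion of pairs with at least one affected member in which both
#' are affected: `n11 / (n11 + n10)`. Always less than or equal to the
#' probandwise rate; provided for comparison.
#'
#' @inheritParams probandwise_concordance
#' @return concordance rate in `[0, 1]`.
#' @export
pairwise_concordance <- function(t) {
  t <- .as_pair_table(t)
  if (t$n11 + t$n10 <= 0) stop("no affected individuals: concordance undefined")
  t$n11 / (t$n11 + t$n10)
}

#' Individual-level prevalence implied by a pair table
#'
#' The affected fraction among pair members, `(2*n11 + n10) / (2*total)`,
#' counting each member of each pair once. Used to initialize the liability
#' threshold in the tetrachoric fit.
#'
#' @inheritParams probandwise_concordance
#' @return proportion in `[0, 1]`.
#' @export
individual_prevalence <- function(t) {
  t <- .as_pair_table(t)
  if (t$total <= 0) stop("empty pair table")
  (2 * t$n11 + t$n10) / (2 * t$total)
}

#' Per-stratum descriptive summary of pair tables
#'
#' @param tables list of `pair_table` objects (e.g. from
#'   [build_pair_table()] or [nst_pair_counts()]).
#' @return data frame with counts, individual prevalence, and probandwise
#'   and pairwise concordance per stratum (concordances are `NA` where no
#'   member is affected).
#' @export
describe_pair_tables <- function(tables) {
  if (inherits(tables, "pair_table")) tables <- list(tables)
  tables <- lapply(tables, .as_pair_table)
  do.call(rbind, lapply(tables, function(t) {
    has_aff <- 2 * t$n11 + t$n10 > 0
    data.frame(relationship = t$relationship, n11 = t$n11, n10 = t$n10,
               n00 = t$n00, total = t$total,
               prevalence = individual_prevalence(t),
               concordance_probandwise =
                 if (has_aff) probandwise_concordance(t) else NA_real_,
               concordance_pairwise =
                 if (has_aff) pairwise_concordance(t) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Nervous system tumor pair counts from a nationwide sibling study
#'
#' Collapsed sibling-pair counts of nervous system tumor diagnoses from a
#' nationwide Swedish birth-cohort (1950--2010) registry study that
#' analyzed full-, maternal half- and paternal half-sibling pairs under a
#' one-pair-per-family-cluster random selection scheme. Two datasets are
#' available: the randomly `"selected"` analysis pairs (one pair per
#' cluster) and `"all_pairs"` enumerated before selection. These tables are
#' the package's built-in worked example of a rare trait (individual
#' prevalence about 0.17%).
#'
#' @param dataset `"selected"` (default) or `"all_pairs"`.
#' @return named list of three `pair_table` objects: `full`,
#'   `maternal_half`, `paternal_half`.
#' @examples
#' tabs <- nst_pair_counts()
#' probandwise_concordance(tabs$full)
#' @export
nst_pair_counts <- function(dataset = c("selected", "all_pairs")) {
  dataset <- match.arg(dataset)
  counts <- switch(dataset,
    selected = list(full          = c(25, 5934, 1742569),
                    maternal_half = c(1, 330, 116967),
                    paternal_half = c(1, 670, 225525)),
    all_pairs = list(full          = c(53, 15185, 4127789),
                     maternal_half = c(4, 3668, 1260820),
                     paternal_half = c(8, 5148, 1611074)))
  mapply(function(x, nm) pair_table(x[1], x[2], x[3], relationship = nm),
         counts, names(counts), SIMPLIFY = FALSE)
}
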