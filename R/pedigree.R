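#' Build family clusters from parent links
#'
#' A family cluster is a connected component of the sibling relation
#' "shares at least one parent": children are linked through common mother
#' or father identifiers, and linkage is transitive (a child full-sib to A
#' and half-sib to B places all three in one cluster). Children with no
#' siblings are not returned.
#'
#' @param records registry data frame with columns `person_id`,
#'   `mother_id`, `father_id` (parent ids must be present for every row).
#' @return data frame with one row per clustered child: `person_id`,
#'   `cluster_id` (integer, arbitrary but stable for a given input), and
#'   `kind` (`"full_only"` if every within-cluster pair shares both
#'   parents, else `"mixed"`).
#' @examples
#' reg <- simulate_registry(simulation_params(n_clusters = 20, seed = 2))
#' table(sibling_clusters(reg)$kind)
#' @export
sibling_clusters <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("person_id", "mother_id", "father_id") %in% names(records)))
  pid <- as.character(records$person_id)
  mid <- as.character(records$mother_id)
  fid <- as.character(records$father_id)
  if (anyDuplicated(pid)) stop("person_id must be unique")
  if (any(is.na(mid)) || any(is.na(fid)) || any(!nzchar(mid)) ||
      any(!nzchar(fid)))
    stop("both parent ids are required for every record")
  if (any(pid == mid | pid == fid))
    stop("record lists itself as its own parent")
  if (any(mid == fid)) stop("mother_id and father_id must differ")

  # bipartite child-parent graph; components with >= 2 children are clusters
  parent <- c(paste0("m:", mid), paste0("f:", fid))
  child <- rep(paste0("p:", pid), 2)
  g <- igraph::graph_from_edgelist(cbind(child, parent), directed = FALSE)
  comp <- igraph::components(g)$membership
  vn <- names(comp)
  is_child <- startsWith(vn, "p:")
  df <- data.frame(person_id = substring(vn[is_child], 3),
                   comp = comp[is_child], stringsAsFactors = FALSE)
  sizes <- table(df$comp)
  df <- df[df$comp %in% names(sizes)[sizes >= 2], , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(person_id = character(), cluster_id = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  df$cluster_id <- match(df$comp, sort(unique(df$comp)))

  idx <- match(df$person_id, pid)
  one_mother <- tapply(mid[idx], df$cluster_id,
                       function(x) length(unique(x)) == 1L)
  one_father <- tapply(fid[idx], df$cluster_id,
                       function(x) length(unique(x)) == 1L)
  full_only <- as.vector(one_mother & one_father)
  names(full_only) <- names(one_mother)
  df$kind <- unname(ifelse(full_only[as.character(df$cluster_id)],
                           "full_only", "mixed"))
  df <- df[order(df$cluster_id, df$person_id),
           c("person_id", "cluster_id", "kind")]
  rownames(df) <- NULL
  df
}

#' Classify the relationship of two siblings
#'
#' @param a,b single-row data frames or lists with `mother_id` and
#'   `father_id`.
#' @return `"full"` (both parents shared), `"maternal_half"` (mother only)
#'   or `"paternal_half"` (father only).
#' @export
classify_pair <- function(a, b) {
  same_m <- as.character(a$mother_id) == as.character(b$mother_id)
  same_f <- as.character(a$father_id) == as.character(b$father_id)
  if (same_m && same_f) return("full")
  if (same_m) return("maternal_half")
  if (same_f) return("paternal_half")
  stop("individuals share no parent: not siblings")
}

#' Randomly select one analyzed sibling pair per family cluster
#'
#' Implements the one-pair-per-cluster design. In a cluster containing only
#' full siblings, an index person is drawn uniformly and one of their full
#' siblings is drawn uniformly as the partner. In a mixed cluster (one
#' containing at least one half-sibling relation) the index is drawn
#' uniformly among members who have at least one half-sibling, and the
#' partner uniformly among the index's paternal half-siblings if any exist,
#' otherwise among the maternal half-siblings — the paternal side is
#' prioritized because paternal half-siblings are the more numerous type in
#' general populations. Twin partners (`is_twin` set and sharing the
#' index's birth year) are never selected; a cluster with no eligible
#' partner yields no pair.
#'
#' A single seeded RNG stream is consumed in cluster-id order, so identical
#' input and seed reproduce identical pairs.
#'
#' @param clusters output of [sibling_clusters()].
#' @param records the registry data frame the clusters were built from.
#' @param seed RNG seed (required).
#' @return data frame of vertex-disjoint pairs, one per eligible cluster:
#'   `index_id`, `sibling_id`, `relationship`, `k_additive` (0.5 full /
#'   0.25 half), `k_shared_env` (always 1).
#' @export
select_study_pairs <- function(clusters, records, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(is.data.frame(clusters),
            all(c("person_id", "cluster_id", "kind") %in% names(clusters)))
  set.seed(seed)
  idx <- match(clusters$person_id, as.character(records$person_id))
  if (anyNA(idx)) stop("cluster member missing from records")
  info <- data.frame(person_id = clusters$person_id,
                     cluster_id = clusters$cluster_id,
                     kind = clusters$kind,
                     mother_id = as.character(records$mother_id)[idx],
                     father_id = as.character(records$father_id)[idx],
                     birth_year = records$birth_year[idx],
                     is_twin = if ("is_twin" %in% names(records))
                       as.logical(records$is_twin)[idx] else FALSE,
                     stringsAsFactors = FALSE)

  pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  out <- lapply(split(info, info$cluster_id), function(cm) {
    n <- nrow(cm)
    same_m <- outer(cm$mother_id, cm$mother_id, "==")
    same_f <- outer(cm$father_id, cm$father_id, "==")
    full <- same_m & same_f; diag(full) <- FALSE
    half <- xor(same_m, same_f)
    # twin exclusion: partner with is_twin flag and the index's birth year
    twin_block <- outer(cm$birth_year, cm$birth_year, "==") &
      matrix(cm$is_twin, n, n, byrow = TRUE)

    if (cm$kind[1] == "full_only") {
      eligible <- seq_len(n)
    } else {
      eligible <- which(rowSums(half) > 0)
    }
    if (length(eligible) == 0L) return(NULL)
    i <- pick1(eligible)
    if (cm$kind[1] == "full_only") {
      cand <- which(full[i, ] & !twin_block[i, ])
    } else {
      pat <- which(half[i, ] & same_f[i, ] & !twin_block[i, ])
      mat <- which(half[i, ] & same_m[i, ] & !twin_block[i, ])
      cand <- if (length(pat) > 0) pat else mat
    }
    if (length(cand) == 0L) return(NULL)
    j <- pick1(cand)
    data.frame(index_id = cm$person_id[i], sibling_id = cm$person_id[j],
               relationship = classify_pair(cm[i, ], cm[j, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(index_id = character(), sibling_id = character(),
                      relationship = character(), stringsAsFactors = FALSE)
  out$k_additive <- if (nrow(out)) kinship_coefficient(out$relationship)
                    else numeric(0)
  out$k_shared_env <- if (nrow(out)) 1 else numeric(0)
  rownames(out) <- NULL
  out
}

#' Attach member phenotypes and birth years to selected pairs
#'
#' Convenience join producing the pair-level layout expected by
#' [fit_tetrachoric_adjusted()] and the pair-level path of
#' [fit_biometric()].
#'
#' @param pairs output of [select_study_pairs()].
#' @param records registry data frame.
#' @return `pairs` with added columns `affected1`, `affected2`,
#'   `birth_year1`, `birth_year2`.
#' @export
pair_phenotypes <- function(pairs, records) {
  i1 <- match(as.character(pairs$index_id), as.character(records$person_id))
  i2 <- match(as.character(pairs$sibling_id), as.character(records$person_id))
  if (anyNA(i1) || anyNA(i2)) stop("pair member missing from records")
  pairs$affected1 <- records$affected[i1]
  pairs$affected2 <- records$affected[i2]
  pairs$birth_year1 <- records$birth_year[i1]
  pairs$birth_year2 <- records$birth_year[i2]
  pairs
}

#' Write / read a selected-pairs table
#'
#' Tab-separated text with header `index_id`, `sibling_id`,
#' `relationship` (extra columns are preserved).
#'
#' @param pairs pairs data frame.
#' @param path file path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` the
#'   data frame.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(c("index_id", "sibling_id", "relationship") %in% names(pairs)))
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) read.delim(path, stringsAsFactors = FALSE)
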