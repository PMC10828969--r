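#' Read / write per-stratum pair-count tables
#'
#' Tab-separated text with header `relationship`, `n11`, `n10`, `n00`, one
#' row per stratum.
#'
#' @param path file path.
#' @param tables named list of `pair_table` objects.
#' @return `read_pair_tables()` returns a named list of `pair_table`
#'   objects; `write_pair_tables()` returns `path` invisibly.
#' @export
read_pair_tables <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("relationship", "n11", "n10", "n00")
  if (!all(need %in% names(df)))
    stop("pair-table file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    pair_table(df$n11[i], df$n10[i], df$n00[i], df$relationship[i]))
  setNames(out, df$relationship)
}

#' @rdname read_pair_tables
#' @export
write_pair_tables <- function(tables, path) {
  if (inherits(tables, "pair_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.log_msg <- function(con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the sibling-heritability pipeline
#'
#' Orchestrates the analysis stages — simulate a registry, build clusters
#' and select study pairs, collapse and describe pair tables, fit
#' tetrachoric correlations per stratum, and fit ACE/AE biometric models —
#' writing per-stage TSV outputs, a machine-readable `results.json`
#' (including the resolved configuration for provenance), and a run log.
#' Identical configurations and seeds reproduce identical outputs.
#'
#' @param config a named list, or path to a YAML/JSON file holding one,
#'   with fields:
#'   \describe{
#'     \item{mode}{one of `"simulate"`, `"select_pairs"`, `"describe"`,
#'       `"tetrachoric"`, `"fit"`, `"all"`.}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{integer seed; required for `simulate`, `select_pairs`
#'       and `all`.}
#'     \item{registry}{path to a registry TSV (when not simulating).}
#'     \item{pairs}{path to a selected-pairs TSV (for `describe` onward).}
#'     \item{pair_tables}{path to a collapsed pair-count TSV; alternative
#'       input for `describe`, `tetrachoric` and `fit`.}
#'     \item{model}{`"ACE"`, `"AE"` or `"both"` (default).}
#'     \item{adjust_birth_year}{logical; use the pair-level birth-year
#'       threshold model where pair-level data are available.}
#'     \item{reference_year}{centering year, default 1980.}
#'     \item{sim}{list of overrides passed to [simulation_params()].}
#'   }
#' @param overrides named list merged over `config` (used by the command
#'   line wrapper for flag overrides).
#' @return invisibly, the results list written to `results.json`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config <- modifyList(config, overrides)
  defaults <- list(mode = "all", model = "both", adjust_birth_year = FALSE,
                   reference_year = 1980, out_dir = ".")
  config <- modifyList(defaults, config)
  modes <- c("simulate", "select_pairs", "describe", "tetrachoric", "fit",
             "all")
  if (!config$mode %in% modes)
    stop("mode must be one of: ", paste(modes, collapse = ", "))
  stages <- if (config$mode == "all") modes[1:5] else config$mode
  stochastic <- any(c("simulate", "select_pairs") %in% stages)
  if (stochastic && is.null(config$seed))
    stop("a seed is required for stochastic stages")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  .log_msg(con, "sibherit ", as.character(utils::packageVersion("sibherit")),
           " | mode=", config$mode,
           if (!is.null(config$seed)) paste0(" | seed=", config$seed))

  results <- list(config = config)
  registry <- NULL; pairs <- NULL; tables <- NULL
  t_start <- Sys.time()

  if ("simulate" %in% stages) {
    sim_args <- c(config$sim, list(seed = config$seed))
    sim_args <- sim_args[!duplicated(names(sim_args))]
    params <- do.call(simulation_params, sim_args)
    registry <- simulate_registry(params)
    path <- file.path(config$out_dir, "registry.tsv")
    write_registry(registry, path)
    .log_msg(con, "simulate: ", nrow(registry), " individuals -> ", path)
    results$simulate <- list(n_individuals = nrow(registry),
                             prevalence = mean(registry$affected))
  }

  if ("select_pairs" %in% stages) {
    if (is.null(registry)) {
      if (is.null(config$registry)) stop("select_pairs needs a registry")
      registry <- read_registry(config$registry)
    }
    clusters <- sibling_clusters(registry)
    pairs <- select_study_pairs(clusters, registry,
                                seed = config$seed + 1L)
    path <- file.path(config$out_dir, "pairs.tsv")
    write_pairs(pairs, path)
    .log_msg(con, "select_pairs: ", nrow(pairs), " pairs (",
             length(unique(clusters$cluster_id)), " clusters) -> ", path)
    results$select_pairs <- as.list(table(pairs$relationship))
  }

  needs_tables <- any(c("describe", "tetrachoric", "fit") %in% stages)
  if (needs_tables && is.null(tables)) {
    if (is.null(pairs) && !is.null(config$pairs))
      pairs <- read_pairs(config$pairs)
    if (is.null(registry) && !is.null(config$registry))
      registry <- read_registry(config$registry)
    if (!is.null(pairs) && !is.null(registry)) {
      tables <- build_pair_table(pairs, records = registry)
      pairs <- pair_phenotypes(pairs, registry)
    } else if (!is.null(config$pair_tables)) {
      tables <- read_pair_tables(config$pair_tables)
    } else {
      stop("describe/tetrachoric/fit need pairs + registry, or pair_tables")
    }
    write_pair_tables(tables, file.path(config$out_dir, "pair_tables.tsv"))
  }

  if ("describe" %in% stages) {
    summ <- describe_pair_tables(tables)
    halves <- grepl("half", names(tables))
    if (sum(halves) > 1)
      summ <- rbind(summ, describe_pair_tables(
        pool_pair_tables(tables[halves], relationship = "half_pooled")))
    path <- file.path(config$out_dir, "descriptives.tsv")
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
    .log_msg(con, "describe -> ", path)
    results$describe <- summ
  }

  if ("tetrachoric" %in% stages) {
    fit_one <- function(tab, pr = NULL) {
      f <- if (config$adjust_birth_year && !is.null(pr))
        fit_tetrachoric_adjusted(pr, reference_year = config$reference_year)
      else fit_tetrachoric(tab)
      data.frame(relationship = tab$relationship, rho = f$rho,
                 se_rho = f$se_rho, threshold = f$threshold,
                 loglik = f$loglik, converged = f$converged,
                 stringsAsFactors = FALSE)
    }
    tt <- do.call(rbind, lapply(names(tables), function(s) {
      pr <- if (!is.null(pairs)) pairs[pairs$relationship == s, ] else NULL
      fit_one(tables[[s]], pr)
    }))
    halves <- grepl("half", names(tables))
    if (sum(halves) > 1)
      tt <- rbind(tt, fit_one(pool_pair_tables(tables[halves],
                                               relationship = "half_pooled")))
    path <- file.path(config$out_dir, "tetrachoric.tsv")
    write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    .log_msg(con, "tetrachoric -> ", path)
    results$tetrachoric <- tt
  }

  if ("fit" %in% stages) {
    fit_data <- if (config$adjust_birth_year && !is.null(pairs))
      split(pairs, pairs$relationship) else tables
    models <- if (config$model == "both") c("ACE", "AE") else config$model
    fits <- lapply(models, function(m) {
      f <- fit_biometric(fit_data, model = m,
                         reference_year = config$reference_year)
      if (!f$converged) stop(m, " fit did not converge")
      .log_msg(con, m, ": a2=", round(f$a2, 4), " c2=", round(f$c2, 4),
               " e2=", round(f$e2, 4))
      list(model = m, a2 = f$a2, c2 = f$c2, e2 = f$e2,
           ci_a2 = f$ci_a2, ci_c2 = f$ci_c2, ci_e2 = f$ci_e2,
           threshold_params = as.list(f$threshold_params),
           loglik = f$loglik, npar = f$npar,
           aic = 2 * f$npar - 2 * f$loglik)
    })
    names(fits) <- models
    if (length(models) == 2L) {
      full <- fit_biometric(fit_data, model = "ACE",
                            reference_year = config$reference_year)
      red <- fit_biometric(fit_data, model = "AE",
                           reference_year = config$reference_year)
      results$likelihood_ratio <- likelihood_ratio(full, red)
    }
    results$fits <- fits
    est <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model, a2 = f$a2, c2 = f$c2, e2 = f$e2,
                 a2_lo = f$ci_a2[1], a2_hi = f$ci_a2[2],
                 loglik = f$loglik, aic = f$aic)))
    write.table(est, file.path(config$out_dir, "biometric.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  results$elapsed_sec <- as.numeric(difftime(Sys.time(), t_start,
                                             units = "secs"))
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  .log_msg(con, "done in ", round(results$elapsed_sec, 2), "s -> ",
           file.path(config$out_dir, "results.json"))
  invisible(results)
}
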