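#' Configuration for an end-to-end pipeline run
#'
#' Either `sim` (a [cohort_sim_config()]) or the three input paths must be
#' given. Per-stage permutation counts default to desk-scale values; raise
#' them for production runs.
#'
#' @param sim a [cohort_sim_config()] to simulate the cohort, or `NULL`.
#' @param table_path,metadata_path,taxonomy_path input files when not
#'   simulating.
#' @param outdir output directory for artifacts.
#' @param seed master seed for every stochastic stage.
#' @param stages stages whose artifacts are written; prerequisites are
#'   still computed.
#' @param rarefy_depth rarefaction depth (`NA` skips rarefaction).
#' @param min_total rare-OTU filter threshold.
#' @param n_bins equal-frequency time bins.
#' @param core_threshold core prevalence threshold.
#' @param n_perm permutations for the permutation tests.
#' @param n_iter_r2 non-core subsets for [core_variance_explained()].
#' @param mtv_config an [mtv_lmm_config()].
#' @param mtv_taxa optional subset of taxa for the mixed model.
#' @param ar_set_size,ar_n_iter random-predictor-set null parameters.
#' @return a classed list of settings.
#' @export
pipeline_config <- function(sim = cohort_sim_config(),
                            table_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL,
                            outdir = tempfile("microsucc_run_"),
                            seed = 1L,
                            stages = c("io", "qc", "core", "persistence",
                                       "delivery", "com", "mtvlmm"),
                            rarefy_depth = 10000L, min_total = 3L,
                            n_bins = 58L, core_threshold = 0.8,
                            n_perm = 199L, n_iter_r2 = 50L,
                            mtv_config = mtv_lmm_config(),
                            mtv_taxa = NULL,
                            ar_set_size = 50L, ar_n_iter = 100L) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- as.list(environment())
  if (is.null(sim) && (is.null(table_path) || is.null(metadata_path)))
    stop("either a sim config or input paths are required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full succession analysis pipeline
#'
#' Executes the stages in dependency order (io -> qc -> core ->
#' persistence -> delivery -> com -> mtvlmm), writes per-stage TSV/JSON
#' artifacts for the stages selected in the config plus a top-level
#' `summary.json`, and returns the summary invisibly. Runs are
#' deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  want <- function(st) st %in% config$stages
  summary <- list(seed = config$seed)
  wr_tsv <- function(df, name)
    utils::write.table(df, file.path(config$outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wr_json <- function(x, name)
    jsonlite::write_json(x, file.path(config$outdir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- config
  cfg_out$mtv_config <- unclass(cfg_out$mtv_config)
  if (!is.null(cfg_out$sim)) cfg_out$sim <- unclass(cfg_out$sim)
  wr_json(unclass(cfg_out), "config.json")

  ## io ------------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    table <- sim$table
    truth <- sim$truth
    if (want("io")) write_cohort(table, config$outdir, "simulated")
  } else {
    table <- load_cohort(config$table_path, config$metadata_path,
                         config$taxonomy_path)
  }
  summary$n_samples_raw <- nrow(table$counts)
  summary$n_otus_raw <- ncol(table$counts)

  ## qc ------------------------------------------------------------------
  table <- filter_rare(table, config$min_total)
  if (!is.na(config$rarefy_depth))
    table <- suppressWarnings(rarefy(table, config$rarefy_depth,
                                     seed = config$seed))
  table <- suppressMessages(assign_time_bins(table, n_bins = config$n_bins))
  writeLines(paste(attr(table$metadata, "bin_edges"), collapse = "\t"),
             file.path(config$outdir, "bin_edges.tsv"))
  if (want("qc")) {
    spur <- flag_spurious(table, rate = config$sim$error_rate %||% 0.0024)
    wr_tsv(spur, "spurious_calls.tsv")
    summary$n_flagged_spurious <- sum(spur$flagged)
  }
  summary$n_samples <- nrow(table$counts)
  summary$n_otus <- ncol(table$counts)

  ## core ----------------------------------------------------------------
  core <- identify_core(table, config$core_threshold)
  summary$n_core <- length(core$core_otu_ids)
  summary$core_share <- core$share
  if (!is.null(truth)) {
    truth_core <- truth$otus$otu_id[truth$otus$is_core]
    pool <- colnames(table$counts)
    called <- pool %in% core$core_otu_ids
    is_true <- pool %in% truth_core
    summary$core_sensitivity <- sum(called & is_true) / sum(is_true)
    summary$core_specificity <- sum(!called & !is_true) / sum(!is_true)
  }
  if (want("core")) {
    wr_tsv(data.frame(otu_id = names(core$prevalence),
                      prevalence = core$prevalence,
                      is_core = names(core$prevalence) %in%
                        core$core_otu_ids), "core.tsv")
    fat <- first_appearance_test(table, core, n_perm = config$n_perm,
                                 seed = config$seed)
    dbt <- diet_breadth_test(table, core, n_perm = max(100L, config$n_perm),
                             seed = config$seed)
    cve <- core_variance_explained(table, core, n_iter = config$n_iter_r2,
                                   seed = config$seed)
    summary$core_first_day_mean <- fat$observed
    summary$core_first_day_p <- fat$p
    summary$core_frac_most_diets <- dbt$frac_most_diets
    summary$r2_core <- cve$r2_core
    summary$r2_noncore_mean <- cve$null_mean
    summary$r2_p <- cve$p
    wr_json(summary[c("n_core", "core_share", "core_first_day_mean",
                      "core_first_day_p", "core_frac_most_diets",
                      "r2_core", "r2_noncore_mean", "r2_p")],
            "core_summary.json")
  }

  ## persistence ---------------------------------------------------------
  arrivals <- build_arrival_table(table)
  if (want("persistence")) {
    wr_tsv(arrivals$otus, "arrival_table.tsv")
    art <- arrival_rate_test(table, n_perm = config$n_perm,
                             seed = config$seed)
    curves <- persistence_by_arrival_day(arrivals, core$core_otu_ids)
    prt <- persistence_ratio_test(table, core$core_otu_ids,
                                  n_perm = max(100L, config$n_perm),
                                  seed = config$seed)
    wr_tsv(curves, "persistence_curves.tsv")
    summary$arrival_slope <- art$slope
    summary$arrival_slope_null_mean <- art$null_mean
    summary$arrival_slope_p <- art$p
    summary$persistence_ratio_core <- prt$mean_core
    summary$persistence_ratio_noncore <- prt$mean_noncore
    summary$persistence_ratio_p <- prt$p
    wr_json(summary[c("arrival_slope", "arrival_slope_null_mean",
                      "arrival_slope_p", "persistence_ratio_core",
                      "persistence_ratio_noncore", "persistence_ratio_p")],
            "persistence_summary.json")
  }

  ## delivery ------------------------------------------------------------
  if (want("delivery")) {
    balanced <- balance_cohorts(table, seed = config$seed)
    balanced <- balanced[, colSums(balanced$counts) > 0]
    iv <- indval(balanced, n_perm = max(999L, config$n_perm),
                 seed = config$seed)
    wr_tsv(iv, "indval.tsv")
    summary$n_indval_significant <- sum(iv$p < 0.05)
    sets <- first_day_otu_sets(table)
    chi <- unique_species_chi2(sets[[1]], sets[[2]])
    summary$first_day_counts <- as.list(chi$counts)
    summary$first_day_total <- chi$total
    summary$first_day_chi2 <- chi$statistic
    summary$first_day_p <- chi$p
    if (!is.null(table$taxonomy)) {
      phyla <- intersect(c("Actinobacteria", "Bacteroidetes", "Firmicutes",
                           "Proteobacteria"), table$taxonomy$phylum)
      ptc <- phylum_time_comparison(table, phyla = phyla,
                                    n_resample = config$n_perm,
                                    seed = config$seed)
      wr_tsv(ptc$tests, "phylum_com_tests.tsv")
      wr_tsv(ptc$counts, "phylum_bin_counts.tsv")
    }
    wr_json(summary[c("n_indval_significant", "first_day_total",
                      "first_day_chi2", "first_day_p")],
            "delivery_summary.json")
  }

  ## com -----------------------------------------------------------------
  if (want("com")) {
    vag <- table[table$metadata$delivery_mode == "vaginal", ]
    cs <- table[table$metadata$delivery_mode == "c-section", ]
    com_v <- com_table(vag)
    com_c <- com_table(cs)
    shared <- intersect(com_v$otu_id[!is.na(com_v$com_weighted)],
                        com_c$otu_id[!is.na(com_c$com_weighted)])
    cv <- com_v$com_weighted[match(shared, com_v$otu_id)]
    cc <- com_c$com_weighted[match(shared, com_c$otu_id)]
    wr_tsv(data.frame(otu_id = shared, com_vaginal = cv,
                      com_csection = cc), "com_by_mode.tsv")
    shift <- com_cluster_and_shift(cv, cc, seed = config$seed)
    ord <- com_order_correlation(cv, cc)
    summary$com_mean_vaginal <- shift$mean_vaginal
    summary$com_mean_csection <- shift$mean_csection
    summary$com_shift_t <- shift$t
    summary$com_shift_p <- shift$p
    summary$com_order_rho <- ord$rho
    summary$com_order_p <- ord$p
    wr_json(summary[c("com_mean_vaginal", "com_mean_csection",
                      "com_shift_t", "com_shift_p", "com_order_rho",
                      "com_order_p")], "com_summary.json")
  }

  ## mtvlmm --------------------------------------------------------------
  if (want("mtvlmm")) {
    fits <- fit_mtv_lmm_all(table, config$mtv_config,
                            taxa = config$mtv_taxa)
    wr_tsv(fits, "mtvlmm_fits.tsv")
    calls <- call_autoregressive(table, fits, config$mtv_config,
                                 set_size = config$ar_set_size,
                                 n_iter = config$ar_n_iter,
                                 seed = config$seed)
    summary$n_autoregressive <- length(calls$called)
    summary$ar_cutoff <- calls$cutoff
    summary$median_r_test <- stats::median(fits$r_test[fits$fitted],
                                           na.rm = TRUE)
    if (!is.null(truth)) {
      truth_ar <- truth$otus$otu_id[truth$otus$is_ar]
      fit_pool <- fits$taxon[fits$fitted]
      tp <- sum(calls$called %in% truth_ar)
      summary$ar_sensitivity <-
        tp / max(1, sum(fit_pool %in% truth_ar))
      summary$ar_false_call_rate <- if (length(calls$called))
        1 - tp / length(calls$called) else 0
      core_or_ar <- truth$otus$otu_id[truth$otus$is_ar |
                                        truth$otus$is_core]
      summary$ar_called_core_or_ar_frac <- if (length(calls$called))
        mean(calls$called %in% core_or_ar) else NA
    }
    wr_json(summary[intersect(names(summary),
                              c("n_autoregressive", "ar_cutoff",
                                "median_r_test", "ar_sensitivity",
                                "ar_false_call_rate",
                                "ar_called_core_or_ar_frac"))],
            "mtvlmm_summary.json")
  }

  wr_json(summary, "summary.json")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
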