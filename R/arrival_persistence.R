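#' Per-OTU arrival records
#'
#' For every OTU observed at least once, the pooled (any animal) first and
#' last day of presence, the span `delta = last - first`, the number of
#' samples with presence, and per-animal first/last day matrices.
#'
#' @param table a [cohort_table()].
#' @return an `arrival_table`: list with data.frame `otus` (`otu_id`,
#'   `first_day`, `last_day`, `delta`, `n_samples_present`) and matrices
#'   `first_by_animal` / `last_by_animal` (animals x OTUs, `NA` where an
#'   animal never carries the OTU).
#' @export
build_arrival_table <- function(table) {
  pres <- presence_matrix(table)
  days <- table$metadata$day_of_life
  seen <- colSums(pres) > 0
  pres <- pres[, seen, drop = FALSE]
  day_mat <- ifelse(pres, days, NA_real_)
  first <- apply(day_mat, 2, min, na.rm = TRUE)
  last <- apply(day_mat, 2, max, na.rm = TRUE)
  animal <- table$metadata$animal_id
  firsts <- rowsum_min(day_mat, animal)
  lasts <- rowsum_max(day_mat, animal)
  structure(list(
    otus = data.frame(otu_id = colnames(pres), first_day = first,
                      last_day = last, delta = last - first,
                      n_samples_present = colSums(pres),
                      stringsAsFactors = FALSE, row.names = NULL),
    first_by_animal = firsts, last_by_animal = lasts),
    class = "arrival_table")
}

rowsum_min <- function(day_mat, groups) {
  g <- unique(groups)
  out <- matrix(NA_real_, length(g), ncol(day_mat),
                dimnames = list(g, colnames(day_mat)))
  for (k in seq_along(g)) {
    block <- day_mat[groups == g[k], , drop = FALSE]
    v <- suppressWarnings(apply(block, 2, min, na.rm = TRUE))
    v[!is.finite(v)] <- NA_real_
    out[k, ] <- v
  }
  out
}

rowsum_max <- function(day_mat, groups) {
  g <- unique(groups)
  out <- matrix(NA_real_, length(g), ncol(day_mat),
                dimnames = list(g, colnames(day_mat)))
  for (k in seq_along(g)) {
    block <- day_mat[groups == g[k], , drop = FALSE]
    v <- suppressWarnings(apply(block, 2, max, na.rm = TRUE))
    v[!is.finite(v)] <- NA_real_
    out[k, ] <- v
  }
  out
}

#' Arrival-rate slope against a bin-shuffle null
#'
#' Counts, per time bin, the OTUs whose pooled first presence falls in
#' that bin, fits an ordinary least-squares slope of count on bin index
#' (or on bin midpoint day), and compares it with a null built by
#' shuffling the sample-to-bin labels and recomputing.
#'
#' @param table a [cohort_table()] with time bins assigned.
#' @param n_perm number of shuffles (default 1000, >= 100).
#' @param seed optional integer seed.
#' @param regressor `"index"` (default) regresses on the bin index,
#'   `"midpoint"` on the mean day of each bin.
#' @return a list with `counts` (per-bin new-OTU counts), `slope`,
#'   `null_slopes`, `null_mean` and the two-sided empirical `p`
#'   (`(b + 1) / (B + 1)` with `b` the permutations at least as far from
#'   the null mean as the observed slope).
#' @export
arrival_rate_test <- function(table, n_perm = 1000L, seed = NULL,
                              regressor = c("index", "midpoint")) {
  stopifnot(n_perm >= 100)
  regressor <- match.arg(regressor)
  md <- table$metadata
  if (is.null(md$time_bin)) stop("assign time bins first")
  bins <- md$time_bin
  n_bins <- max(bins) + 1L
  if (n_bins < 3) stop("need at least 3 bins")
  pres <- presence_matrix(table)
  seen <- colSums(pres) > 0
  pres <- pres[, seen, drop = FALSE]
  # triplet layout: per OTU, the rows where it is present
  idx_by_otu <- apply(pres, 2, which, simplify = FALSE)
  xreg <- if (regressor == "index") {
    seq_len(n_bins) - 1
  } else {
    mids <- tapply(md$day_of_life, bins, mean)
    as.numeric(mids[as.character(seq_len(n_bins) - 1)])
  }
  counts_for <- function(bin_labels) {
    first_bin <- vapply(idx_by_otu, function(ix) min(bin_labels[ix]), 1L)
    tabulate(first_bin + 1L, n_bins)
  }
  slope_of <- function(cnt) unname(stats::coef(stats::lm(cnt ~ xreg))[2])
  counts <- counts_for(bins)
  slope <- slope_of(counts)
  if (!is.null(seed)) set.seed(seed)
  null_slopes <- vapply(seq_len(n_perm),
                        function(b) slope_of(counts_for(sample(bins))), 1)
  centre <- mean(null_slopes)
  b <- sum(abs(null_slopes - centre) >= abs(slope - centre))
  list(counts = counts, slope = slope, null_slopes = null_slopes,
       null_mean = centre, p = (b + 1) / (n_perm + 1))
}

#' Mean persistence by day of first appearance
#'
#' For each first-appearance day, the mean over qualifying OTUs of their
#' persistence `min(delta, window)` -- the span between first and last
#' observed presence capped by the observation window -- reported
#' separately for core and non-core OTUs. OTUs first appearing after
#' `max_first_day` are discarded (sparser late sampling), as are OTUs
#' present in fewer than `min_samples` samples.
#'
#' @param arrivals an `arrival_table` from [build_arrival_table()].
#' @param core_ids character vector of core OTU ids.
#' @param window persistence cap in days (default 600).
#' @param max_first_day latest admissible first-appearance day (default 430).
#' @param min_samples minimum samples with presence (1, 5, 10, 20 or 30).
#' @return a data.frame (`first_day`, `group`, `n`, `mean_persistence`);
#'   day/group combinations with no qualifying OTU are simply absent.
#' @export
persistence_by_arrival_day <- function(arrivals, core_ids, window = 600,
                                       max_first_day = 430,
                                       min_samples = 1L) {
  stopifnot(window > 0, min_samples >= 1)
  ot <- arrivals$otus
  keep <- ot$first_day <= max_first_day &
    ot$n_samples_present >= min_samples
  ot <- ot[keep, , drop = FALSE]
  if (!nrow(ot))
    return(data.frame(first_day = integer(0), group = character(0),
                      n = integer(0), mean_persistence = numeric(0)))
  ot$persistence <- pmin(ot$delta, window)
  ot$group <- ifelse(ot$otu_id %in% core_ids, "core", "non-core")
  agg <- stats::aggregate(persistence ~ first_day + group, data = ot,
                          FUN = mean)
  n <- stats::aggregate(persistence ~ first_day + group, data = ot,
                        FUN = length)
  out <- data.frame(first_day = agg$first_day, group = agg$group,
                    n = n$persistence, mean_persistence = agg$persistence,
                    stringsAsFactors = FALSE)
  out[order(out$group, out$first_day), ]
}

#' Persistence ratio of core vs non-core OTUs
#'
#' For each OTU, the ratio of its real span `delta = last - first` to the
#' mean span under `n_perm` random reassignments of the sampling-day
#' labels across samples. A persistent OTU concentrated on a contiguous
#' stretch scores below 1 less severely than a transient one. A two-sided
#' Welch t-test compares core and non-core ratio distributions. OTUs
#' present in a single sample have no defined ratio and are excluded.
#'
#' @param table a [cohort_table()].
#' @param core_ids character vector of core OTU ids.
#' @param n_perm number of day-label shuffles (>= 100).
#' @param seed optional integer seed.
#' @param within_animal permute days within each animal instead of
#'   globally (sensitivity analysis; default `FALSE`).
#' @return a list with per-OTU data.frame `ratios`, group means
#'   `mean_core` / `mean_noncore`, `t` and `p`.
#' @export
persistence_ratio_test <- function(table, core_ids, n_perm = 100L,
                                   seed = NULL, within_animal = FALSE) {
  stopifnot(n_perm >= 100)
  pres <- presence_matrix(table)
  keep <- colSums(pres) >= 2
  pres <- pres[, keep, drop = FALSE]
  days <- table$metadata$day_of_life
  animal <- table$metadata$animal_id
  idx_by_otu <- apply(pres, 2, which, simplify = FALSE)
  real <- vapply(idx_by_otu, function(ix) diff(range(days[ix])), 1)
  if (!is.null(seed)) set.seed(seed)
  perm_sum <- numeric(length(idx_by_otu))
  for (b in seq_len(n_perm)) {
    pd <- if (within_animal)
      stats::ave(days, animal, FUN = sample) else sample(days)
    perm_sum <- perm_sum +
      vapply(idx_by_otu, function(ix) diff(range(pd[ix])), 1)
  }
  perm_mean <- perm_sum / n_perm
  ratio <- real / perm_mean
  grp <- ifelse(names(ratio) %in% core_ids, "core", "non-core")
  if (min(table(grp)) < 2)
    stop("need at least 2 OTUs in each of core and non-core")
  tt <- stats::t.test(ratio[grp == "core"], ratio[grp == "non-core"])
  list(ratios = data.frame(otu_id = names(ratio), ratio = unname(ratio),
                           group = grp, real_delta = unname(real),
                           perm_delta = unname(perm_mean),
                           stringsAsFactors = FALSE),
       mean_core = mean(ratio[grp == "core"]),
       mean_noncore = mean(ratio[grp == "non-core"]),
       t = unname(tt$statistic), p = tt$p.value)
}
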