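#' Identify core successional OTUs by animal-level prevalence
#'
#' Samples are first collapsed by animal (an OTU is present in an animal
#' if observed in at least one of its samples); OTUs present in at least
#' `threshold` of the animals form the core set. The core's share of total
#' reads is reported alongside.
#'
#' @param table a [cohort_table()].
#' @param threshold prevalence fraction, inclusive (default 0.8).
#' @return a `core_result`: list with `core_otu_ids`, named `prevalence`
#'   vector, `threshold` and `share` (fraction of all reads on core OTUs).
#' @export
identify_core <- function(table, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  animals <- unique(table$metadata$animal_id)
  if (length(animals) < 2) stop("need at least 2 animals")
  pres <- presence_matrix(table)
  by_animal <- rowsum(pres + 0L, table$metadata$animal_id) > 0L
  prevalence <- colMeans(by_animal)
  core <- names(prevalence)[prevalence >= threshold]
  share <- sum(table$counts[, core, drop = FALSE]) / sum(table$counts)
  structure(list(core_otu_ids = core, prevalence = prevalence,
                 threshold = threshold, share = share),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat("core_result:", length(x$core_otu_ids), "core OTUs of",
      length(x$prevalence), "at prevalence >=", x$threshold, "\n")
  cat("  core read share:", round(x$share, 3), "\n")
  invisible(x)
}

#' Diet breadth of core OTUs against a row-shuffle null
#'
#' For each core OTU, breadth is the number of distinct diets in which it
#' is present. The null shuffles each OTU's presence vector across samples
#' (`n_perm` times), randomising time and diet while preserving occupancy.
#' An OTU is flagged diet-specific when its breadth falls below the 5th
#' percentile of its own null. The summary is the fraction of core OTUs
#' present in "most" diets, i.e. a strict majority of the diet codes.
#'
#' @param table a [cohort_table()].
#' @param core a `core_result` from [identify_core()].
#' @param n_perm number of shuffles (>= 100).
#' @param seed optional integer seed.
#' @return a list with a per-OTU data.frame (`breadth`, `null_q05`,
#'   `diet_specific`), `n_diets` and `frac_most_diets`.
#' @export
diet_breadth_test <- function(table, core, n_perm = 100L, seed = NULL) {
  stopifnot(n_perm >= 100)
  diets <- table$metadata$diet_code
  u_diets <- unique(diets)
  if (length(u_diets) < 2) stop("table has a single diet")
  if (!is.null(seed)) set.seed(seed)
  pres <- presence_matrix(table)[, core$core_otu_ids, drop = FALSE]
  n_samp <- nrow(pres)
  breadth_of <- function(rows) length(unique(diets[rows]))
  occupancy <- colSums(pres)
  breadth <- vapply(seq_len(ncol(pres)),
                    function(j) breadth_of(which(pres[, j])), 1L)
  null_q <- vapply(occupancy, function(m) {
    if (m == 0) return(0)
    nulls <- vapply(seq_len(n_perm),
                    function(b) breadth_of(sample.int(n_samp, m)), 1L)
    stats::quantile(nulls, 0.05, names = FALSE)
  }, 1)
  majority <- ceiling((length(u_diets) + 1) / 2)
  per_otu <- data.frame(otu_id = colnames(pres), breadth = breadth,
                        null_q05 = null_q,
                        diet_specific = breadth < null_q,
                        stringsAsFactors = FALSE)
  list(per_otu = per_otu, n_diets = length(u_diets),
       frac_most_diets = mean(breadth >= majority))
}

#' Do core OTUs appear earlier than random non-core sets?
#'
#' The statistic is the mean pooled first-presence day over the core OTUs.
#' The null draws `|core|` OTUs from the non-core pool `n_perm` times and
#' averages their first-presence days; `p = (b + 1) / (B + 1)` with `b`
#' the number of draws whose mean is at most the observed (core arriving
#' early gives a small p).
#'
#' @param table a [cohort_table()].
#' @param core a `core_result`.
#' @param n_perm number of null draws (default 1000).
#' @param seed optional integer seed.
#' @return a list with `observed`, `null` (vector of null means) and `p`.
#' @export
first_appearance_test <- function(table, core, n_perm = 1000L,
                                  seed = NULL) {
  arrivals <- build_arrival_table(table)
  first <- stats::setNames(arrivals$otus$first_day, arrivals$otus$otu_id)
  core_ids <- intersect(core$core_otu_ids, names(first))
  noncore <- first[setdiff(names(first), core_ids)]
  if (length(noncore) < length(core_ids))
    stop("fewer non-core than core OTUs: cannot draw null sets")
  if (!is.null(seed)) set.seed(seed)
  observed <- mean(first[core_ids])
  null <- replicate(n_perm, mean(sample(noncore, length(core_ids))))
  p <- (sum(null <= observed) + 1) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}

#' Variance in community structure explained by the core set
#'
#' Sums the PERMANOVA R-squared of age, diet and their interaction on the
#' core-only subtable (age enters as the numeric time-bin index so that it
#' is not aliased with the diet factor), and compares the sum against
#' `n_iter` random non-core subsets of the same size.
#'
#' @param table a [cohort_table()] with time bins assigned.
#' @param core a `core_result`.
#' @param n_iter number of random non-core subsets (default 1000; 0 skips
#'   the null comparison).
#' @param seed optional integer seed.
#' @return a list with `r2_core`, `null` (vector of non-core sums),
#'   `null_mean` and empirical `p` = fraction of null sums at least the
#'   observed (plus-one corrected).
#' @export
core_variance_explained <- function(table, core, n_iter = 1000L,
                                    seed = NULL) {
  md <- table$metadata
  if (is.null(md$time_bin)) stop("assign time bins first")
  if (length(unique(md$diet_code)) < 2) stop("need >= 2 diets")
  factors <- data.frame(age = as.numeric(md$time_bin),
                        diet = factor(md$diet_code))
  fml <- ~ age + diet + age:diet
  core_ids <- core$core_otu_ids
  noncore_ids <- setdiff(colnames(table$counts), core_ids)
  if (n_iter > 0 && length(noncore_ids) < length(core_ids))
    stop("fewer non-core than core OTUs")
  r2_of <- function(ids) {
    sub <- table$counts[, ids, drop = FALSE]
    ok <- rowSums(sub) > 0
    r2_terms_sum(bray_curtis_matrix(sub[ok, , drop = FALSE]),
                 factors[ok, , drop = FALSE], fml)
  }
  r2_core <- r2_of(core_ids)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_iter),
                 function(i) r2_of(sample(noncore_ids, length(core_ids))),
                 1)
  list(r2_core = r2_core, null = null,
       null_mean = if (n_iter > 0) mean(null) else NA_real_,
       p = if (n_iter > 0) (sum(null >= r2_core) + 1) / (n_iter + 1)
           else NA_real_)
}
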