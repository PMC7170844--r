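#' Temporal centre of mass of an abundance series
#'
#' The COM summarises when, on the life axis, an OTU carries its
#' abundance. Two variants are computed:
#' \describe{
#'   \item{`weighted-mean`}{`sum(RA_t * Day_t) / sum(RA_t)` -- the
#'     abundance-weighted mean sampling day; always inside
#'     `[min(day), max(day)]` and the default for inference.}
#'   \item{`as-printed`}{`sum(RA_t * Day_t) / sum(Day_t)` -- a variant
#'     with the sampling days in the denominator, emitted for literal
#'     replication of the legacy formula; not a day and not range-bound.}
#' }
#'
#' @param days numeric vector of sampling days (>= 0).
#' @param ra matching vector of relative abundances.
#' @param variant `"weighted-mean"` (default) or `"as-printed"`.
#' @return the COM value; `NA` for the weighted-mean variant when all
#'   abundances are zero.
#' @export
compute_com <- function(days, ra, variant = c("weighted-mean",
                                              "as-printed")) {
  variant <- match.arg(variant)
  stopifnot(length(days) == length(ra), length(days) >= 1, all(days >= 0))
  if (variant == "as-printed") {
    if (sum(days) == 0) return(NA_real_)
    sum(ra * days) / sum(days)
  } else {
    if (sum(ra) == 0) return(NA_real_)
    sum(ra * days) / sum(ra)
  }
}

#' Per-OTU centre-of-mass table
#'
#' Computes both COM variants for every OTU over the sample series,
#' pooled or per animal.
#'
#' @param table a [cohort_table()].
#' @param by `"otu"` pools all samples; `"otu_animal"` computes one COM
#'   per OTU per animal.
#' @return a data.frame with `otu_id` (and `animal_id` if per animal),
#'   `com_weighted`, `com_printed` and `n_present` (samples with the OTU).
#' @export
com_table <- function(table, by = c("otu", "otu_animal")) {
  by <- match.arg(by)
  ra <- to_relative_abundance(table)
  days <- table$metadata$day_of_life
  one_block <- function(rows, label = NULL) {
    sub <- ra[rows, , drop = FALSE]
    d <- days[rows]
    num <- colSums(sub * d)
    wsum <- colSums(sub)
    data.frame(otu_id = colnames(sub),
               animal_id = if (is.null(label)) NA_character_ else label,
               com_weighted = ifelse(wsum > 0, num / wsum, NA_real_),
               com_printed = if (sum(d) > 0) num / sum(d) else NA_real_,
               n_present = colSums(sub > 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (by == "otu") {
    out <- one_block(seq_len(nrow(ra)))
    out$animal_id <- NULL
    return(out)
  }
  blocks <- split(seq_len(nrow(ra)), table$metadata$animal_id)
  do.call(rbind, mapply(one_block, blocks, names(blocks),
                        SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

#' K-means clustering and shift test on paired COM values
#'
#' Given each OTU's (or per-animal mean) COM under both delivery modes,
#' clusters the paired values with seeded multi-restart K-means and tests
#' the C-section vs vaginal shift with a two-sided Welch t-test.
#'
#' @param com_vaginal,com_csection paired numeric COM vectors.
#' @param k number of clusters (default 2).
#' @param nstart K-means restarts (best inertia kept).
#' @param seed optional integer seed.
#' @return a list with `cluster` (assignments), `centers`, `t` and `p`
#'   (`t = 0`, `p = 1` when the two vectors are identical).
#' @export
com_cluster_and_shift <- function(com_vaginal, com_csection, k = 2L,
                                  nstart = 10L, seed = NULL) {
  stopifnot(length(com_vaginal) == length(com_csection))
  m <- cbind(vaginal = com_vaginal, csection = com_csection)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < k) stop("fewer points than clusters")
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart)
  if (isTRUE(all.equal(m[, 1], m[, 2]))) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(m[, "csection"], m[, "vaginal"])
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(cluster = km$cluster, centers = km$centers,
       mean_vaginal = mean(m[, "vaginal"]),
       mean_csection = mean(m[, "csection"]), t = t_stat, p = p)
}

#' Spearman correlation of COM ordering between delivery modes
#'
#' Tests whether the temporal ordering of shared OTUs' COM values is
#' conserved between the two modes (tie-corrected, two-sided).
#'
#' @param com_vaginal,com_csection paired COM vectors over the shared
#'   OTUs (>= 5).
#' @return a list with `rho` and `p`.
#' @export
com_order_correlation <- function(com_vaginal, com_csection) {
  ok <- stats::complete.cases(com_vaginal, com_csection)
  x <- com_vaginal[ok]; y <- com_csection[ok]
  if (length(x) < 5) stop("need at least 5 shared OTUs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant COM vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
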