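#' Remove rare OTUs by table-wide total count
#'
#' With the default `min_total = 3`, singletons and doubletons (table-wide
#' total of 1 or 2 reads) are discarded, the usual screen applied to
#' clustered 16S OTU tables before analysis.
#'
#' @param table a [cohort_table()].
#' @param min_total smallest table-wide total an OTU must reach to be kept.
#' @return the filtered `cohort_table`; samples are unchanged.
#' @export
filter_rare <- function(table, min_total = 3L) {
  stopifnot(min_total >= 0)
  keep <- colSums(table$counts) >= min_total
  table[, keep]
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (vegan's `rrarefy`). Samples whose total is below `depth` cannot
#' be rarefied and are dropped with a warning.
#'
#' @param table a [cohort_table()].
#' @param depth target reads per sample (default 10,000).
#' @param seed optional integer seed for the subsampling.
#' @return the rarefied `cohort_table`; every remaining sample sums to
#'   exactly `depth`. OTUs absent everywhere after rarefaction are kept
#'   (zero columns) so OTU sets stay comparable across seeds.
#' @export
rarefy <- function(table, depth = 10000L, seed = NULL) {
  stopifnot(depth > 0)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples are below the rarefaction depth (", depth, ")")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(table$counts)[!keep], 5),
                  collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  if (!is.null(seed)) set.seed(seed)
  sub <- table[keep, ]
  rare <- vegan::rrarefy(sub$counts, depth)
  storage.mode(rare) <- "integer"
  sub$counts <- rare
  sub
}

#' Assign samples to time bins on day of life
#'
#' Bins are left-closed right-open intervals `[lo, hi)` on `day_of_life`,
#' indexed from 0. Either explicit `edges` are supplied, or `n_bins`
#' equal-frequency bins (default 58) are built greedily over the pooled
#' sampling days: distinct days are accumulated, in order, until a bin
#' holds at least its share of the remaining samples. Bin assignment is a
#' pure, monotone function of `day_of_life`.
#'
#' @param table a [cohort_table()].
#' @param edges strictly ascending day boundaries covering all observed
#'   days (`length(edges) - 1` bins), or `NULL` to use `n_bins`.
#' @param n_bins number of equal-frequency bins when `edges` is `NULL`.
#' @return the `cohort_table` with a `time_bin` metadata column and the
#'   edges stored in `attr(table$metadata, "bin_edges")`.
#' @export
assign_time_bins <- function(table, edges = NULL, n_bins = 58L) {
  days <- table$metadata$day_of_life
  if (is.null(edges)) {
    stopifnot(n_bins >= 1)
    edges <- equal_frequency_edges(days, n_bins)
  } else {
    if (any(diff(edges) <= 0)) stop("edges must be strictly ascending")
  }
  if (any(days < edges[1]) || any(days >= edges[length(edges)]))
    stop("day_of_life outside the binning range [", edges[1], ", ",
         edges[length(edges)], ")")
  bins <- findInterval(days, edges, rightmost.closed = FALSE) - 1L
  table$metadata$time_bin <- bins
  attr(table$metadata, "bin_edges") <- edges
  message("time bins: ", length(edges) - 1L, " bins, edges ",
          paste(edges, collapse = " "))
  table
}

# Equal-frequency edges over the pooled (tied) day values. Ties never
# straddle an edge, so bins are built from "atoms" (distinct days with
# their sample counts). The construction: (1) binary-search the largest
# minimum occupancy m any contiguous n_bins partition can guarantee;
# (2) place edges greedily at each bin's fair share of the remaining
# samples, never closing where the tail could no longer sustain m;
# (3) polish boundaries by hill climbing (maximise the minimum occupancy,
# then minimise the maximum).
equal_frequency_edges <- function(days, n_bins) {
  tab <- table(days)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  n_atom <- length(vals)
  n_bins <- min(n_bins, n_atom)
  if (n_bins == 1L) return(c(vals[1], vals[n_atom] + 1L))

  greedy_bins <- function(x, m) {
    b <- 0L; acc <- 0L
    for (v in x) {
      acc <- acc + v
      if (acc >= m) { b <- b + 1L; acc <- 0L }
    }
    b
  }
  lo <- 1L; hi <- max(1L, sum(cnt) %/% n_bins)
  while (lo < hi) {
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (greedy_bins(cnt, mid) >= n_bins) lo <- mid else hi <- mid - 1L
  }
  m <- lo
  # f[k]: max bins of >= m formable from atoms k..n_atom
  f <- integer(n_atom + 1L)
  for (k in n_atom:1) f[k] <- greedy_bins(cnt[k:n_atom], m)
  f[n_atom + 1L] <- 0L

  csum <- cumsum(cnt)
  sum_range <- function(i, k) csum[k] - if (i > 1) csum[i - 1] else 0L
  bounds <- integer(n_bins - 1L)
  i <- 1L
  remaining <- sum(cnt)
  for (b in seq_len(n_bins - 1L)) {
    bins_left <- n_bins - b + 1L
    target <- remaining / bins_left
    feasible <- NA_integer_
    chosen <- NA_integer_
    for (k in i:(n_atom - (bins_left - 1L))) {
      s <- sum_range(i, k)
      if (s >= m && f[k + 1L] >= bins_left - 1L) feasible <- k
      if (s >= target && !is.na(feasible)) { chosen <- feasible; break }
    }
    if (is.na(chosen)) chosen <- feasible
    bounds[b] <- chosen
    remaining <- remaining - sum_range(i, chosen)
    i <- chosen + 1L
  }

  # local polish: move single boundaries while it improves
  # (min occupancy up, then max occupancy down)
  bnd <- c(0L, bounds, n_atom)
  occ_of <- function(b) diff(c(0, csum[b[-1]]))
  score <- function(o) c(min(o), -max(o))
  for (it in seq_len(200L)) {
    o <- occ_of(bnd)
    improved <- FALSE
    for (j in 2:(length(bnd) - 1L)) {
      for (dlt in c(-1L, 1L)) {
        nb <- bnd
        nb[j] <- nb[j] + dlt
        if (nb[j] <= nb[j - 1L] || nb[j] >= nb[j + 1L]) next
        no <- occ_of(nb)
        s1 <- score(no); s0 <- score(o)
        if (s1[1] > s0[1] || (s1[1] == s0[1] && s1[2] > s0[2])) {
          bnd <- nb; o <- no; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  c(vals[1], vals[bnd[2:(length(bnd) - 1L)] + 1L], vals[n_atom] + 1L)
}

#' Convert counts to per-sample relative abundances
#'
#' @param table a [cohort_table()] or a numeric count matrix
#'   (samples x OTUs).
#' @return a numeric matrix of the same shape whose rows each sum to 1.
#' @export
to_relative_abundance <- function(table) {
  counts <- if (inherits(table, "cohort_table")) table$counts else
    as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(utils::head(rownames(counts)[totals <= 0], 5), collapse = ", "))
  counts / totals
}

# presence = count >= 1 (the convention every occupancy statistic uses)
presence_matrix <- function(table) {
  counts <- if (inherits(table, "cohort_table")) table$counts else
    as.matrix(table)
  counts >= 1L
}
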