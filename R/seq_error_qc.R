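#' Poisson probability that a read carries at least d errors
#'
#' Error counts per read are modelled as Poisson with
#' `lambda = rate * read_length`. Returns the per-sequence upper tail
#' `P(X >= d)` and the per-sample probability obtained by scaling with the
#' read length, clamped to 1.
#'
#' @param d mismatch count(s), >= 0 (vectorised).
#' @param read_length read length in nucleotides (default 250).
#' @param rate per-nucleotide error probability (default 0.0024).
#' @return a data.frame with columns `d`, `p_sequence` and `p_sample`.
#' @export
poisson_error_prob <- function(d, read_length = 250L, rate = 0.0024) {
  stopifnot(all(d >= 0), rate >= 0, rate < 1, read_length >= 1)
  lambda <- rate * read_length
  p_seq <- stats::ppois(d - 1, lambda, lower.tail = FALSE)
  data.frame(d = d, p_sequence = p_seq,
             p_sample = pmin(1, p_seq * read_length))
}

#' Probability that the same single-nucleotide error recurs in k samples
#'
#' Independent recurrence of one specific per-nucleotide error across `k`
#' samples has probability `rate^k`; strictly decreasing in `k` and
#' increasing in `rate`.
#'
#' @param k number of samples (>= 1, vectorised).
#' @param rate per-nucleotide error probability (default 0.0024).
#' @return `rate^k`.
#' @export
repeated_error_prob <- function(k, rate = 0.0024) {
  stopifnot(all(k >= 1), rate >= 0, rate < 1)
  rate^k
}

#' Flag OTUs consistent with a sequencing-error origin
#'
#' Each OTU is matched to its dominant co-occurring OTU (the most abundant
#' other OTU over the samples where it occurs) and classified `minor` when
#' its table-wide total is below `minor_frac` of that parent's total,
#' `major` otherwise -- a count-ratio proxy for the sequence-similarity
#' classification, which needs raw reads. Under the error null the OTU's
#' total count is Poisson with mean
#' `parent_total * (1 - (1 - rate)^read_length) / children`: the expected
#' reads diverted from the parent into any one of its `children` possible
#' error variants. The per-OTU p-value is the upper tail of that null;
#' after multiple-testing adjustment, OTUs that fail to reject (adjusted
#' p > `alpha`) are flagged spurious. Per-sequence and per-sample Poisson
#' probabilities at the cluster-escape distance
#' `ceiling(0.03 * read_length)` are reported alongside.
#'
#' @param table a [cohort_table()].
#' @param rate per-nucleotide error probability (default 0.0024).
#' @param read_length read length in nucleotides (default 250).
#' @param alpha significance level for rejecting the error null.
#' @param method multiple-testing adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @param children number of error variants a parent can spawn (matches
#'   [inject_sequencing_errors()]).
#' @param minor_frac minor/major count-ratio boundary (default 0.01).
#' @return a data.frame per OTU: `otu_id`, `class`, `parent`,
#'   `p_sequence`, `p_sample`, `p_value`, `q_value`, `flagged`.
#' @export
flag_spurious <- function(table, rate = 0.0024, read_length = 250L,
                          alpha = 0.05, method = c("BH", "bonferroni"),
                          children = 100L, minor_frac = 0.01) {
  method <- match.arg(method)
  if (!ncol(table$counts) || !nrow(table$counts)) stop("empty table")
  counts <- table$counts
  totals <- colSums(counts)
  pres <- counts >= 1L
  n_otu <- ncol(counts)
  parent <- character(n_otu)
  lambda <- numeric(n_otu)
  p_div <- per_read_error_prob(rate, read_length)
  for (j in seq_len(n_otu)) {
    rows <- pres[, j]
    cand <- colSums(counts[rows, -j, drop = FALSE])
    k <- which.max(cand)
    parent[j] <- names(cand)[k]
    # under the error null, the observed parent total is itself depleted by
    # diversion: true reads = observed / (1 - p_div)
    lambda[j] <- totals[parent[j]] * p_div / (1 - p_div) / children
  }
  cls <- ifelse(totals < minor_frac * totals[parent], "minor", "major")
  p_value <- stats::ppois(totals - 1, lambda, lower.tail = FALSE)
  d_escape <- ceiling(0.03 * read_length)
  pe <- poisson_error_prob(d_escape, read_length, rate)
  q_value <- stats::p.adjust(p_value,
                             if (method == "BH") "BH" else "bonferroni")
  data.frame(otu_id = colnames(counts), class = cls, parent = parent,
             total = as.numeric(totals),
             p_sequence = pe$p_sequence, p_sample = pe$p_sample,
             p_value = p_value, q_value = q_value,
             flagged = q_value > alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
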