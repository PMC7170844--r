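#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed
#' with [vegan::vegdist()].
#'
#' @param x a [cohort_table()] (counts are used) or a numeric matrix,
#'   samples x OTUs.
#' @return a `dist` object with sample labels; entries in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(x) {
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(utils::head(rownames(m)[totals <= 0], 5), collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower-centred double-centring of the squared dissimilarities; negative
#' eigenvalues are reported but their axes are never returned.
#'
#' @param dm a `dist` object, e.g. from [bray_curtis_matrix()].
#' @param k number of ordination axes to return.
#' @return a list with `points` (n x k coordinates), `eigenvalues` (all,
#'   non-increasing) and `negative` (the negative eigenvalues).
#' @export
pcoa <- function(dm, k = 2L) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  fit <- stats::cmdscale(dm, k = n - 1L, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos)
    stop("k = ", k, " exceeds the ", n_pos, " positive axes available")
  list(points = fit$points[, seq_len(k), drop = FALSE],
       eigenvalues = eig,
       negative = eig[eig < 0])
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Anderson-style permutational multivariate analysis of variance via
#' [vegan::adonis2()] with sequential (Type-I) sums of squares, so a
#' multi-factor design is partitioned term by term in the order given.
#' The permutation p-value is `(b + 1) / (B + 1)` where `b` counts
#' permutations with pseudo-F at least the observed.
#'
#' @param dm a `dist` object.
#' @param factors data.frame of per-sample design variables, rows aligned
#'   with `dm` labels.
#' @param formula right-hand-side formula over `factors` columns; default
#'   uses every column, in order.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed for the permutations.
#' @param blocks optional factor (e.g. animal id) defining exchangeable
#'   blocks: whole blocks are permuted and samples never move between
#'   blocks, the appropriate scheme for repeated measures.
#' @return a `permanova_result`: data.frame with one row per term plus
#'   `Residual` and `Total`, columns `term`, `df`, `ss`, `r2`, `f`, `p`,
#'   and attribute `n_perm`.
#' @export
permanova <- function(dm, factors, formula = NULL, n_perm = 999L,
                      seed = NULL, blocks = NULL) {
  stopifnot(n_perm >= 99)
  factors <- as.data.frame(factors)
  for (v in names(factors)) {
    col <- factors[[v]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      tab <- table(col)
      if (length(tab) < 2) stop("constant factor: ", v)
      if (any(tab < 2)) stop("factor ", v, " has a singleton level")
    }
  }
  if (is.null(formula))
    formula <- stats::reformulate(names(factors))
  lhs <- stats::as.dist(dm)
  full <- stats::as.formula(paste("lhs", paste(deparse(formula),
                                               collapse = "")))
  if (!is.null(seed)) set.seed(seed)
  perm <- if (is.null(blocks)) n_perm else
    permute::how(nperm = n_perm,
                 plots = permute::Plots(strata = as.factor(blocks),
                                        type = "free"),
                 within = permute::Within(type = "none"))
  fit <- vegan::adonis2(full, data = factors, permutations = perm,
                        by = "terms")
  res <- data.frame(term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
                    r2 = fit$R2, f = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_perm") <- n_perm
  class(res) <- c("permanova_result", class(res))
  res
}

# sum of the term R2 values (everything except Residual/Total); no
# permutations are run, so this is cheap inside null-resampling loops
r2_terms_sum <- function(dm, factors, formula = NULL) {
  factors <- as.data.frame(factors)
  if (is.null(formula))
    formula <- stats::reformulate(names(factors))
  lhs <- stats::as.dist(dm)
  full <- stats::as.formula(paste("lhs", paste(deparse(formula),
                                               collapse = "")))
  fit <- vegan::adonis2(full, data = factors, permutations = 0,
                        by = "terms")
  r2 <- fit$R2
  names(r2) <- rownames(fit)
  sum(r2[!names(r2) %in% c("Residual", "Total")], na.rm = TRUE)
}

#' Per-group alpha diversity and within-group dispersion
#'
#' Groups samples by `time_bin` x `delivery_mode` and reports pooled
#' richness (OTUs with count >= 1), Shannon diversity, Pielou evenness
#' `J = H / ln(richness)` and the mean pairwise within-group Bray-Curtis
#' dissimilarity (beta dispersion).
#'
#' @param table a [cohort_table()] with time bins assigned.
#' @return a data.frame with one row per group; `evenness` is `NA` where
#'   richness < 2 and `dispersion` is `NA` for groups of fewer than 2
#'   samples.
#' @export
alpha_and_dispersion <- function(table) {
  md <- table$metadata
  if (is.null(md$time_bin)) stop("assign time bins first")
  key <- interaction(md$time_bin, md$delivery_mode, drop = TRUE)
  groups <- split(seq_len(nrow(md)), key)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    pooled <- colSums(table$counts[idx, , drop = FALSE])
    rich <- sum(pooled >= 1)
    h <- vegan::diversity(pooled, index = "shannon")
    j <- if (rich >= 2) h / log(rich) else NA_real_
    disp <- if (length(idx) >= 2)
      mean(bray_curtis_matrix(table$counts[idx, , drop = FALSE])) else
      NA_real_
    data.frame(time_bin = md$time_bin[idx[1]],
               delivery_mode = md$delivery_mode[idx[1]],
               n_samples = length(idx), richness = rich, shannon = h,
               evenness = j, dispersion = disp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$delivery_mode, out$time_bin), ]
}
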