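#' Configuration for the temporal mixed model (MTV-LMM)
#'
#' The model predicts a focal taxon's relative abundance at time `t` from
#' its own `p` previous values (fixed effects) and the whole community's
#' state at the `q` previous time points (a random effect whose covariance
#' is the temporal kinship matrix). Candidate `(p, q)` pairs are fitted on
#' the training third of each animal's series and chosen on the validation
#' third by out-of-sample correlation; the winner is refit and scored on
#' the test third.
#'
#' @param p,q default autoregressive and community-history orders.
#' @param n_quantile_bins bins used to discretise community features
#'   (default 10, deciles).
#' @param candidates list of `c(p, q)` pairs to select among.
#' @param prevalence minimum fraction of samples in which a taxon must be
#'   present to be fitted (default 0.10).
#' @param split sequential train/validation/test fractions (sum to 1).
#' @return a classed list of settings.
#' @export
mtv_lmm_config <- function(p = 1L, q = 1L, n_quantile_bins = 10L,
                           candidates = list(c(1L, 1L), c(1L, 2L),
                                             c(2L, 1L), c(2L, 2L)),
                           prevalence = 0.10,
                           split = c(1, 1, 1) / 3) {
  stopifnot(p >= 0, q >= 0, p + q > 0, n_quantile_bins >= 2,
            abs(sum(split) - 1) < 1e-8, length(split) == 3)
  structure(list(p = p, q = q, n_quantile_bins = n_quantile_bins,
                 candidates = candidates, prevalence = prevalence,
                 split = split),
            class = "mtv_lmm_config")
}

#' Quantile-bin a relative-abundance matrix column by column
#'
#' Each taxon's nonzero values are mapped to quantile-bin indices
#' `0 .. n_bins - 1` over that taxon's own nonzero distribution; zeros map
#' to bin 0. The mapping is monotone within a column.
#'
#' @param ra numeric matrix, samples x taxa.
#' @param n_bins number of quantile bins (>= 2).
#' @return an integer matrix of the same shape.
#' @export
quantile_bin_features <- function(ra, n_bins = 10L) {
  stopifnot(n_bins >= 2)
  out <- matrix(0L, nrow(ra), ncol(ra), dimnames = dimnames(ra))
  for (j in seq_len(ncol(ra))) {
    v <- ra[, j]
    nz <- which(v > 0)
    if (length(nz)) {
      r <- rank(v[nz], ties.method = "average")
      out[nz, j] <- as.integer(ceiling(r / length(nz) * n_bins)) - 1L
    }
  }
  out
}

# per-sample index of the k-th previous sample within the same animal
# (NA where unavailable); days must be unique within animal
lag_index <- function(animal, day, k) {
  n <- length(animal)
  out <- rep(NA_integer_, n)
  for (a in unique(animal)) {
    ix <- which(animal == a)
    ix <- ix[order(day[ix])]
    if (length(ix) > k)
      out[ix[(k + 1):length(ix)]] <- ix[seq_len(length(ix) - k)]
  }
  out
}

#' Temporal kinship matrix from lagged community state
#'
#' A sample's feature vector is the column-standardised concatenation of
#' its animal's (quantile-binned) community states at the previous `q`
#' time points. `K = F F' / m` over the `m` retained features, rescaled so
#' the mean diagonal is 1. Samples without `q` predecessors in their
#' animal are excluded; `K` is positive semi-definite by construction.
#'
#' @param binned matrix from [quantile_bin_features()], samples x taxa.
#' @param animal per-sample animal ids.
#' @param day per-sample days of life.
#' @param q community-history order (>= 1).
#' @param rows optional sample indices to build the matrix over (each must
#'   still have `q` predecessors); defaults to all eligible samples.
#' @param exclude taxa (column names or indices) to drop from the
#'   community features, e.g. the focal taxon.
#' @return a list with `K` (rows x rows), `rows` (the sample indices) and
#'   `m` (number of features).
#' @export
temporal_kinship <- function(binned, animal, day, q = 1L, rows = NULL,
                             exclude = NULL) {
  stopifnot(q >= 1)
  if (!is.null(exclude)) {
    keep <- setdiff(seq_len(ncol(binned)),
                    if (is.character(exclude))
                      match(exclude, colnames(binned)) else exclude)
    binned <- binned[, keep, drop = FALSE]
  }
  lags <- lapply(seq_len(q), function(k) lag_index(animal, day, k))
  eligible <- which(Reduce(`&`, lapply(lags, function(l) !is.na(l))))
  if (!length(eligible))
    stop("no sample has ", q, " predecessors within its animal")
  if (is.null(rows)) rows <- eligible
  if (!all(rows %in% eligible))
    stop("some requested rows lack ", q, " predecessors")
  feats <- do.call(cbind, lapply(lags, function(l)
    binned[l[rows], , drop = FALSE]))
  sds <- apply(feats, 2, stats::sd)
  feats <- feats[, sds > 0, drop = FALSE]
  if (!ncol(feats))
    stop("no informative community features among the retained samples")
  feats <- scale(feats)
  K <- tcrossprod(feats) / ncol(feats)
  K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(binned)[rows], rownames(binned)[rows])
  list(K = K, rows = rows, m = ncol(feats))
}

# REML for y = X beta + g + e, g ~ N(0, s2g K), e ~ N(0, s2e I), via
# eigendecomposition of K and 1-D optimisation of delta = s2e / s2g
# (EMMA-style). Near-deterministic fits short-circuit to OLS.
lmm_reml <- function(y, X, K) {
  n <- length(y)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    X <- X[, keep, drop = FALSE]
    qrx <- qr(X)
  }
  cfx <- ncol(X)
  beta_ols <- qr.coef(qrx, y)
  res_ols <- y - X %*% beta_ols
  if (mean(res_ols^2) <= 1e-12 * max(stats::var(y), 1e-300))
    return(list(beta = beta_ols, sigma2_g = 0,
                sigma2_e = mean(res_ols^2), delta = Inf,
                X_cols = colnames(X)))
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  df <- n - cfx
  fit_at <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    beta <- tryCatch(solve(XX, crossprod(XtW, yt)),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    r <- yt - Xt %*% beta
    R <- sum(w * r^2)
    s2g <- R / df
    ll <- -0.5 * (df * log(2 * pi * s2g) + sum(log(d + delta)) +
                    determinant(XX, logarithm = TRUE)$modulus + df)
    list(ll = as.numeric(ll), beta = beta, s2g = s2g, delta = delta)
  }
  grid <- seq(-12, 12, length.out = 25)
  lls <- vapply(grid, function(g) fit_at(g)$ll, 1)
  best <- which.max(lls)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(function(g) fit_at(g)$ll, c(lo, hi),
                         maximum = TRUE)
  fit <- fit_at(opt$maximum)
  list(beta = fit$beta, sigma2_g = fit$s2g,
       sigma2_e = fit$delta * fit$s2g, delta = fit$delta,
       X_cols = colnames(X))
}

# BLUP of new rows conditioned on obs rows
lmm_predict <- function(fit, K, y, X, obs, new) {
  mu <- X[new, , drop = FALSE] %*% fit$beta
  if (!is.finite(fit$delta) || fit$sigma2_g <= 0) return(drop(mu))
  V <- K[obs, obs, drop = FALSE]
  diag(V) <- diag(V) + fit$delta
  resid <- y[obs] - X[obs, , drop = FALSE] %*% fit$beta
  drop(mu + K[new, obs, drop = FALSE] %*% solve(V, resid))
}

# sequential thirds within each animal's ordered model rows
sequential_split <- function(animal, day, rows, fracs) {
  part <- rep(NA_integer_, length(rows))
  for (a in unique(animal[rows])) {
    ix <- which(animal[rows] == a)
    ix <- ix[order(day[rows][ix])]
    n <- length(ix)
    n1 <- ceiling(fracs[1] * n)
    n2 <- ceiling((fracs[1] + fracs[2]) * n)
    part[ix] <- c(rep(1L, n1), rep(2L, max(0, n2 - n1)),
                  rep(3L, max(0, n - n2)))
  }
  part
}

# fit one (p, q) candidate for one response vector; returns validation and
# test correlations plus the refit used for the test predictions
mtv_eval_candidate <- function(y, binned_ex, animal, day, p, q, lag_max,
                               split) {
  lags <- lapply(seq_len(lag_max), function(k) lag_index(animal, day, k))
  rows <- which(Reduce(`&`, lapply(lags, function(l) !is.na(l))))
  if (length(rows) < 12)
    return(list(ok = FALSE, reason = "too few usable samples"))
  X <- cbind(intercept = 1)
  X <- matrix(1, length(rows), 1, dimnames = list(NULL, "intercept"))
  if (p > 0)
    X <- cbind(X, vapply(seq_len(p),
                         function(k) y[lags[[k]][rows]],
                         numeric(length(rows))))
  if (p > 0) colnames(X)[-1] <- paste0("lag", seq_len(p))
  kin <- temporal_kinship(binned_ex, animal, day, q = q, rows = rows)
  K <- kin$K
  yr <- y[rows]
  part <- sequential_split(animal, day, rows, split)
  train <- which(part == 1L)
  val <- which(part == 2L)
  test <- which(part == 3L)
  if (length(val) < 3 || length(test) < 3)
    return(list(ok = FALSE, reason = "series too short to split"))
  if (stats::sd(yr[train]) == 0)
    return(list(ok = FALSE, reason = "zero-variance taxon in training"))
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b)
  fit_tr <- lmm_reml(yr[train], X[train, , drop = FALSE],
                     K[train, train, drop = FALSE])
  Xf <- X[, fit_tr$X_cols, drop = FALSE]
  pred_val <- lmm_predict(fit_tr, K, yr, Xf, train, val)
  r_val <- safe_cor(pred_val, yr[val])
  obs <- sort(c(train, val))
  fit_tv <- lmm_reml(yr[obs], X[obs, , drop = FALSE],
                     K[obs, obs, drop = FALSE])
  Xf2 <- X[, fit_tv$X_cols, drop = FALSE]
  pred_test <- lmm_predict(fit_tv, K, yr, Xf2, obs, test)
  r_test <- safe_cor(pred_test, yr[test])
  list(ok = TRUE, r_val = r_val, r_test = r_test, fit = fit_tv,
       n_rows = length(rows), n_test = length(test),
       pred_test = pred_test, y_test = yr[test])
}

#' Fit the temporal mixed model to one focal taxon
#'
#' Fits every candidate `(p, q)` model, selects on the validation third by
#' out-of-sample correlation, refits on train + validation, and reports the
#' Pearson correlation of sequential best-linear-unbiased predictions on
#' the test third. The focal taxon is excluded from the community features
#' of its own kinship matrix.
#'
#' @param table a [cohort_table()].
#' @param taxon the focal OTU id.
#' @param config an [mtv_lmm_config()].
#' @param ra,binned optional precomputed relative-abundance and binned
#'   matrices (to amortise across taxa).
#' @return an `ar_fit`: list with `taxon`, selected `p`, `q`, `beta`,
#'   `sigma2_g`, `sigma2_e`, `r_val`, `r_test`, `n` (model rows) and
#'   `fitted` (`FALSE`, with a `reason`, when the taxon could not be
#'   fitted).
#' @export
fit_mtv_lmm <- function(table, taxon, config = mtv_lmm_config(),
                        ra = NULL, binned = NULL) {
  if (is.null(ra)) ra <- to_relative_abundance(table)
  if (!taxon %in% colnames(ra)) stop("unknown taxon: ", taxon)
  prev <- mean(ra[, taxon] > 0)
  if (prev < config$prevalence)
    stop("taxon below the prevalence filter (", signif(prev, 3), " < ",
         config$prevalence, ")")
  if (is.null(binned))
    binned <- quantile_bin_features(ra, config$n_quantile_bins)
  animal <- table$metadata$animal_id
  day <- table$metadata$day_of_life
  y <- ra[, taxon]
  binned_ex <- binned[, setdiff(colnames(binned), taxon), drop = FALSE]
  lag_max <- max(vapply(config$candidates, max, 1L))
  evals <- lapply(config$candidates, function(pq)
    mtv_eval_candidate(y, binned_ex, animal, day, pq[1], pq[2], lag_max,
                       config$split))
  ok <- vapply(evals, function(e) isTRUE(e$ok), TRUE)
  if (!any(ok)) {
    return(structure(list(taxon = taxon, fitted = FALSE,
                          reason = evals[[1]]$reason),
                     class = "ar_fit"))
  }
  r_vals <- vapply(evals, function(e)
    if (isTRUE(e$ok) && is.finite(e$r_val)) e$r_val else -Inf, 1)
  # ties (within float noise) go to the earliest, most parsimonious candidate
  best <- which(r_vals >= max(r_vals) - 1e-6)[1]
  e <- evals[[best]]
  structure(list(taxon = taxon, p = config$candidates[[best]][1],
                 q = config$candidates[[best]][2],
                 beta = drop(e$fit$beta),
                 sigma2_g = e$fit$sigma2_g, sigma2_e = e$fit$sigma2_e,
                 r_val = e$r_val, r_test = e$r_test, n = e$n_rows,
                 n_test = e$n_test, fitted = TRUE),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  if (!isTRUE(x$fitted)) {
    cat("ar_fit:", x$taxon, "not fitted (", x$reason, ")\n")
    return(invisible(x))
  }
  cat("ar_fit:", x$taxon, sprintf("(p=%d, q=%d)", x$p, x$q),
      "r_test =", round(x$r_test, 3), "\n")
  invisible(x)
}

#' Fit the temporal mixed model across taxa
#'
#' @param table a [cohort_table()].
#' @param config an [mtv_lmm_config()].
#' @param taxa OTU ids to fit; default every taxon passing the prevalence
#'   filter.
#' @return a data.frame with one row per attempted taxon: `taxon`, `p`,
#'   `q`, `sigma2_g`, `sigma2_e`, `r_val`, `r_test`, `fitted`.
#' @export
fit_mtv_lmm_all <- function(table, config = mtv_lmm_config(),
                            taxa = NULL) {
  ra <- to_relative_abundance(table)
  if (is.null(taxa))
    taxa <- colnames(ra)[colMeans(ra > 0) >= config$prevalence]
  binned <- quantile_bin_features(ra, config$n_quantile_bins)
  rows <- lapply(taxa, function(tx) {
    f <- tryCatch(fit_mtv_lmm(table, tx, config, ra = ra, binned = binned),
                  error = function(e)
                    structure(list(taxon = tx, fitted = FALSE,
                                   reason = conditionMessage(e)),
                              class = "ar_fit"))
    data.frame(taxon = tx,
               p = if (isTRUE(f$fitted)) f$p else NA_integer_,
               q = if (isTRUE(f$fitted)) f$q else NA_integer_,
               sigma2_g = if (isTRUE(f$fitted)) f$sigma2_g else NA_real_,
               sigma2_e = if (isTRUE(f$fitted)) f$sigma2_e else NA_real_,
               r_val = if (isTRUE(f$fitted)) f$r_val else NA_real_,
               r_test = if (isTRUE(f$fitted)) f$r_test else NA_real_,
               fitted = isTRUE(f$fitted), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call autoregressive taxa against a random-predictor-set null
#'
#' Builds a null distribution of test-set correlations: at each iteration
#' a random focal taxon is drawn, its series is permuted within each
#' animal (destroying temporal structure while keeping marginals), and the
#' default model is fitted with a kinship built from `set_size` randomly
#' chosen predictor taxa. A taxon is called autoregressive when its
#' observed test correlation exceeds the null's `threshold` quantile.
#'
#' @param table a [cohort_table()].
#' @param fits data.frame from [fit_mtv_lmm_all()].
#' @param config an [mtv_lmm_config()].
#' @param set_size predictor taxa per null iteration (default 495; must be
#'   below the number of eligible taxa).
#' @param n_iter null iterations (default 1000).
#' @param threshold null quantile above which a taxon is called (default
#'   0.95).
#' @param seed optional integer seed.
#' @return a list with `called` (OTU ids), `null_r` (the null correlation
#'   distribution), `cutoff` and the `threshold` used. An empty fit table
#'   yields an empty call set.
#' @export
call_autoregressive <- function(table, fits, config = mtv_lmm_config(),
                                set_size = 495L, n_iter = 1000L,
                                threshold = 0.95, seed = NULL) {
  fits_ok <- fits[fits$fitted & is.finite(fits$r_test), , drop = FALSE]
  if (!nrow(fits_ok))
    return(list(called = character(0), null_r = numeric(0),
                cutoff = NA_real_, threshold = threshold))
  ra <- to_relative_abundance(table)
  pool <- colnames(ra)[colMeans(ra > 0) >= config$prevalence]
  if (length(pool) <= set_size)
    stop("fewer eligible taxa (", length(pool), ") than set_size (",
         set_size, ")")
  binned <- quantile_bin_features(ra, config$n_quantile_bins)
  animal <- table$metadata$animal_id
  day <- table$metadata$day_of_life
  if (!is.null(seed)) set.seed(seed)
  lag_max <- max(config$p, config$q)
  null_r <- vapply(seq_len(n_iter), function(i) {
    focal <- sample(pool, 1)
    predictors <- sample(setdiff(pool, focal), set_size)
    y <- ra[, focal]
    y <- stats::ave(y, animal, FUN = sample)
    e <- mtv_eval_candidate(y, binned[, predictors, drop = FALSE],
                            animal, day, config$p, config$q, lag_max,
                            config$split)
    if (isTRUE(e$ok) && is.finite(e$r_test)) e$r_test else NA_real_
  }, 1)
  null_r <- null_r[is.finite(null_r)]
  if (!length(null_r)) stop("no null iteration produced a correlation")
  cutoff <- stats::quantile(null_r, threshold, names = FALSE)
  called <- fits_ok$taxon[fits_ok$r_test > cutoff]
  list(called = called, null_r = null_r, cutoff = cutoff,
       threshold = threshold)
}
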