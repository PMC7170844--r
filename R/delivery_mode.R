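#' Balance delivery-mode groups by animal selection
#'
#' Keeps every minority-group animal and greedily selects the same number
#' of majority-group animals, each pick minimising the per-time-bin
#' sample-count discrepancy (L1) to the minority group, so the two groups
#' end with matched sample totals and similar temporal coverage.
#'
#' @param table a [cohort_table()]; time bins are used when present,
#'   otherwise raw sampling days.
#' @param seed optional integer seed (breaks ties between equally good
#'   picks).
#' @return the `cohort_table` restricted to the selected animals; returned
#'   unchanged when the groups are already balanced.
#' @export
balance_cohorts <- function(table, seed = NULL) {
  md <- table$metadata
  modes <- table(unique(md[c("animal_id", "delivery_mode")])$delivery_mode)
  if (length(modes) < 2) stop("only one delivery mode present")
  minority <- names(modes)[which.min(modes)]
  majority <- names(modes)[which.max(modes)]
  if (modes[minority] == modes[majority] &&
      sum(md$delivery_mode == minority) == sum(md$delivery_mode == majority))
    return(table)
  strata <- if (!is.null(md$time_bin)) md$time_bin else md$day_of_life
  lev <- sort(unique(strata))
  profile_of <- function(animals) {
    rows <- md$animal_id %in% animals
    tabulate(match(strata[rows], lev), length(lev))
  }
  min_animals <- unique(md$animal_id[md$delivery_mode == minority])
  maj_animals <- unique(md$animal_id[md$delivery_mode == majority])
  target <- profile_of(min_animals)
  if (!is.null(seed)) set.seed(seed)
  selected <- character(0)
  current <- rep(0L, length(lev))
  pool <- maj_animals
  for (k in seq_len(length(min_animals))) {
    if (!length(pool)) break
    score <- vapply(pool, function(a)
      sum(abs(target - (current + profile_of(a)))), 1)
    best <- pool[score == min(score)]
    pick <- if (length(best) > 1) sample(best, 1) else best
    selected <- c(selected, pick)
    current <- current + profile_of(pick)
    pool <- setdiff(pool, pick)
  }
  table[md$animal_id %in% c(min_animals, selected), ]
}

# per-OTU max-over-groups indicator value for a given sample grouping;
# ra and pres are samples x OTUs, labels a vector over samples
indval_stat <- function(ra, pres, labels) {
  groups <- unique(labels)
  means <- vapply(groups, function(g)
    colMeans(ra[labels == g, , drop = FALSE]), numeric(ncol(ra)))
  fidelity <- vapply(groups, function(g)
    colMeans(pres[labels == g, , drop = FALSE]), numeric(ncol(ra)))
  denom <- rowSums(means)
  spec <- means / ifelse(denom > 0, denom, 1)
  iv <- spec * fidelity
  best <- max.col(iv, ties.method = "first")
  list(stat = iv[cbind(seq_len(nrow(iv)), best)],
       group = groups[best], indval = iv)
}

#' Dufrene-Legendre indicator species analysis (IndVal)
#'
#' For OTU `i` and group `g`, `IndVal = A x B` where the specificity
#' `A` is the group-mean relative abundance of `i` divided by the sum of
#' the group means, and the fidelity `B` is the fraction of group-`g`
#' samples where `i` is present. The per-OTU statistic is the maximum over
#' groups; significance comes from group-label permutation with
#' `p = (b + 1) / (B + 1)`, Benjamini-Hochberg adjusted across OTUs.
#'
#' @param table a [cohort_table()].
#' @param groups per-sample group labels; default `delivery_mode`.
#' @param n_perm number of permutations (>= 999 unless `exact`).
#' @param seed optional integer seed.
#' @param level `"animal"` (default) permutes delivery labels across
#'   animals, keeping each animal's samples together -- the exchangeable
#'   unit under repeated measures; `"sample"` permutes sample labels, the
#'   literal classic procedure.
#' @param exact enumerate every distinct label assignment instead of
#'   sampling (feasible for small designs); `p` is then the exact fraction
#'   of assignments with a statistic at least the observed.
#' @return an `indval_result` data.frame: `otu_id`, `group` (best group),
#'   `indval`, `p`, `q`; OTUs absent from every sample are dropped with a
#'   warning. Attribute `n_perm` records the permutations used.
#' @export
indval <- function(table, groups = NULL, n_perm = 1000L, seed = NULL,
                   level = c("animal", "sample"), exact = FALSE) {
  level <- match.arg(level)
  md <- table$metadata
  if (is.null(groups)) groups <- md$delivery_mode
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) != 2 || any(tab < 2))
    stop("need exactly 2 groups with >= 2 samples each")
  if (!exact && n_perm < 999) stop("n_perm must be >= 999")
  empty <- colSums(table$counts) == 0
  if (any(empty)) {
    warning(sum(empty), " OTU(s) absent from all samples excluded")
    table <- table[, !empty]
  }
  ra <- to_relative_abundance(table)
  pres <- presence_matrix(table)
  obs <- indval_stat(ra, pres, groups)

  if (level == "animal") {
    animals <- unique(md$animal_id)
    a_group <- md$delivery_mode[match(animals, md$animal_id)]
    if (is.null(groups) || identical(groups, md$delivery_mode)) {
      unit_labels <- a_group
    } else {
      unit_labels <- vapply(animals, function(a)
        groups[md$animal_id == a][1], "")
    }
    expand <- match(md$animal_id, animals)
    label_for <- function(perm_unit) perm_unit[expand]
    units <- unit_labels
  } else {
    label_for <- identity
    units <- groups
  }

  if (exact) {
    g1 <- unique(units)[1]
    pos <- which(units == g1)
    combos <- utils::combn(length(units), length(pos))
    ge <- rep(0L, length(obs$stat))
    for (k in seq_len(ncol(combos))) {
      lab <- rep(unique(units)[2], length(units))
      lab[combos[, k]] <- g1
      st <- indval_stat(ra, pres, label_for(lab))$stat
      ge <- ge + (st >= obs$stat - 1e-12)
    }
    p <- ge / ncol(combos)
    n_used <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- rep(0L, length(obs$stat))
    for (b in seq_len(n_perm)) {
      st <- indval_stat(ra, pres, label_for(sample(units)))$stat
      ge <- ge + (st >= obs$stat - 1e-12)
    }
    p <- (ge + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- data.frame(otu_id = colnames(ra), group = obs$group,
                    indval = obs$stat, p = p,
                    q = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_used
  class(out) <- c("indval_result", class(out))
  out
}

#' Label-shuffle validation of the IndVal-significant count
#'
#' Counts the OTUs significant for delivery mode and compares the count
#' with `n_shuffles` reruns in which the delivery-mode labels are shuffled
#' at the animal level.
#'
#' @param table a [cohort_table()].
#' @param n_shuffles number of label shuffles (>= 1; 100 in the classic
#'   procedure).
#' @param n_perm permutations inside each [indval()] call.
#' @param alpha per-OTU significance level on the raw permutation p.
#' @param seed optional integer seed.
#' @return a list with `observed` (significant-OTU count), `null` (counts
#'   under shuffled labels) and empirical `p`.
#' @export
indval_label_shuffle_validation <- function(table, n_shuffles = 100L,
                                            n_perm = 1000L, alpha = 0.05,
                                            seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  md <- table$metadata
  observed <- sum(indval(table, n_perm = n_perm)$p < alpha)
  animals <- unique(md$animal_id)
  a_group <- md$delivery_mode[match(animals, md$animal_id)]
  null <- vapply(seq_len(n_shuffles), function(s) {
    shuf <- sample(a_group)[match(md$animal_id, animals)]
    sum(indval(table, groups = shuf, n_perm = n_perm)$p < alpha)
  }, 1)
  list(observed = observed, null = null,
       p = (sum(null >= observed) + 1) / (n_shuffles + 1))
}

#' OTU sets present on each animal's first sampling day, per delivery mode
#'
#' @param table a [cohort_table()].
#' @return a named list of two character vectors of OTU ids, one per
#'   delivery mode.
#' @export
first_day_otu_sets <- function(table) {
  md <- table$metadata
  pres <- presence_matrix(table)
  first_rows <- unlist(lapply(split(seq_len(nrow(md)), md$animal_id),
                              function(ix) ix[which.min(md$day_of_life[ix])]))
  modes <- sort(unique(md$delivery_mode))
  stats::setNames(lapply(modes, function(m) {
    rows <- first_rows[md$delivery_mode[first_rows] == m]
    colnames(pres)[colSums(pres[rows, , drop = FALSE]) > 0]
  }), modes)
}

#' Chi-squared test on first-day unique and shared OTUs
#'
#' Builds the three-cell contingency (unique to group A, shared, unique to
#' group B) from two first-day OTU sets and runs a goodness-of-fit
#' chi-squared test against the configured expected proportions (uniform
#' by default, the minimal "no association" reference).
#'
#' @param set_a,set_b character vectors of OTU ids present at the first
#'   time point in each group.
#' @param expected expected proportions for (unique-A, shared, unique-B).
#' @return a list with `counts` (named length-3 vector), `total`,
#'   `statistic` and `p`.
#' @export
unique_species_chi2 <- function(set_a, set_b,
                                expected = rep(1 / 3, 3)) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(union(set_a, set_b))) stop("empty union of first-day sets")
  counts <- c(unique_a = length(setdiff(set_a, set_b)),
              shared = length(intersect(set_a, set_b)),
              unique_b = length(setdiff(set_b, set_a)))
  fit <- suppressWarnings(stats::chisq.test(counts, p = expected))
  list(counts = counts, total = sum(counts),
       statistic = unname(fit$statistic), p = fit$p.value)
}

#' Phylum-level temporal distributions by delivery mode
#'
#' Per delivery mode and phylum, counts the distinct OTUs of that phylum
#' present in each time bin, smooths the counts with a Gaussian kernel
#' density over time (Silverman's bandwidth), and compares the temporal
#' centre of mass (COM) of the count series between modes: `n_resample`
#' resamples of `resample_frac` of the per-bin count values are drawn
#' independently per mode and the two COM vectors compared by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param table a [cohort_table()] with time bins assigned.
#' @param taxonomy a taxonomy map covering the table's OTUs.
#' @param phyla phyla to analyse.
#' @param resample_frac fraction of per-bin values per resample.
#' @param n_resample number of resamples per mode.
#' @param seed optional integer seed.
#' @return a list with `counts` (long data.frame: mode, phylum, bin,
#'   midpoint day, OTU count), `density` (per mode x phylum, a
#'   [stats::density()] object over days) and `tests` (per-phylum COM
#'   means and Wilcoxon p).
#' @export
phylum_time_comparison <- function(table, taxonomy = table$taxonomy,
                                   phyla = c("Actinobacteria",
                                             "Bacteroidetes", "Firmicutes",
                                             "Proteobacteria"),
                                   resample_frac = 0.7,
                                   n_resample = 1000L, seed = NULL) {
  md <- table$metadata
  if (is.null(md$time_bin)) stop("assign time bins first")
  if (is.null(taxonomy)) stop("taxonomy required")
  missing <- setdiff(phyla, taxonomy$phylum)
  if (length(missing))
    stop("phylum absent from taxonomy: ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  pres <- presence_matrix(table)
  phy_of <- taxonomy$phylum[match(colnames(pres), taxonomy$otu_id)]
  bins <- sort(unique(md$time_bin))
  midday_by_bin <- tapply(md$day_of_life, md$time_bin, mean)
  midday <- as.numeric(midday_by_bin[as.character(bins)])
  modes <- sort(unique(md$delivery_mode))
  counts <- expand.grid(delivery_mode = modes, phylum = phyla,
                        time_bin = bins, stringsAsFactors = FALSE)
  counts$midday <- midday[match(counts$time_bin, bins)]
  counts$n_otus <- mapply(function(m, f, b) {
    rows <- md$delivery_mode == m & md$time_bin == b
    cols <- phy_of == f & !is.na(phy_of)
    sum(colSums(pres[rows, cols, drop = FALSE]) > 0)
  }, counts$delivery_mode, counts$phylum, counts$time_bin)

  dens <- list()
  tests <- data.frame(phylum = phyla, com_csection = NA_real_,
                      com_vaginal = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  com_of <- function(cnt, day) sum(cnt * day) / sum(cnt)
  for (f in phyla) {
    coms <- list()
    for (m in modes) {
      sel <- counts$delivery_mode == m & counts$phylum == f
      cnt <- counts$n_otus[sel]
      day <- counts$midday[sel]
      if (sum(cnt) > 0) {
        bw <- stats::bw.nrd0(rep(day, cnt))  # Silverman on the count mass
        de <- stats::density(day, weights = cnt / sum(cnt), bw = bw,
                             n = 2048, cut = 6)
        # renormalise exactly on the reported grid (FFT evaluation is only
        # ~1e-4 accurate)
        area <- sum((de$y[-1] + de$y[-length(de$y)]) / 2) * diff(de$x[1:2])
        de$y <- de$y / area
        dens[[paste(m, f, sep = ".")]] <- de
      }
      take <- max(2L, ceiling(resample_frac * length(cnt)))
      coms[[m]] <- vapply(seq_len(n_resample), function(r) {
        ix <- sample.int(length(cnt), take)
        com_of(cnt[ix], day[ix])
      }, 1)
    }
    wt <- suppressWarnings(stats::wilcox.test(coms[["c-section"]],
                                              coms[["vaginal"]]))
    tests[tests$phylum == f, c("com_csection", "com_vaginal", "p")] <-
      c(mean(coms[["c-section"]], na.rm = TRUE),
        mean(coms[["vaginal"]], na.rm = TRUE), wt$p.value)
  }
  list(counts = counts, density = dens, tests = tests)
}
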