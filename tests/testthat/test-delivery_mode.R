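# 4 + 4-sample two-animal-per-mode toy used by the IndVal tests
indval_toy <- function() {
  counts <- matrix(
    c(10L, 0L, 5L, 2L,
      8L,  0L, 4L, 0L,
      12L, 1L, 6L, 3L,
      9L,  0L, 2L, 1L,
      0L, 10L, 5L, 0L,
      0L,  7L, 4L, 2L,
      1L,  9L, 6L, 0L,
      0L, 11L, 3L, 1L),
    nrow = 8, byrow = TRUE,
    dimnames = list(paste0("s", 1:8), paste0("otu", 1:4)))
  md <- data.frame(sample_id = paste0("s", 1:8),
                   animal_id = paste0("cow", rep(1:4, each = 2)),
                   day_of_life = rep(c(0L, 10L), 4),
                   diet_code = "A",
                   delivery_mode = rep(c("vaginal", "c-section"), each = 4))
  cohort_table(counts, md)
}

test_that("IndVal hits its closed-form extremes", {
  tb <- indval_toy()
  # perfect indicator: present in all vaginal samples, absent in c-section
  counts <- tb$counts
  counts[, "otu1"] <- c(5L, 5L, 5L, 5L, 0L, 0L, 0L, 0L)
  tb2 <- cohort_table(counts, tb$metadata)
  res <- indval(tb2, n_perm = 999, seed = 1, level = "sample")
  perfect <- res[res$otu_id == "otu1", ]
  expect_equal(perfect$indval, 1)
  expect_equal(perfect$group, "vaginal")
  # equal mean relative abundance and full presence in equal-sized groups:
  # A = 0.5, B = 1 -> max IndVal exactly 0.5 (equal row totals make
  # relative abundances exact)
  csym <- matrix(c(2L, 8L, 0L,
                   2L, 0L, 8L,
                   2L, 8L, 0L,
                   2L, 0L, 8L), 4, 3, byrow = TRUE,
                 dimnames = list(paste0("t", 1:4), c("sym", "x", "y")))
  mdsym <- data.frame(sample_id = paste0("t", 1:4),
                      animal_id = paste0("k", 1:4),
                      day_of_life = 0L, diet_code = "A",
                      delivery_mode = rep(c("vaginal", "c-section"),
                                          each = 2))
  rsym <- indval(cohort_table(csym, mdsym), n_perm = 999, seed = 2,
                 level = "sample")
  expect_equal(rsym$indval[rsym$otu_id == "sym"], 0.5)
})

test_that("IndVal permutation p matches exhaustive enumeration", {
  tb <- indval_toy()
  res <- indval(tb, level = "sample", exact = TRUE)
  # independent brute force over all C(8,4) = 70 label assignments
  ra <- to_relative_abundance(tb)
  pres <- tb$counts >= 1
  stat_of <- function(labels) {
    vapply(colnames(ra), function(j) {
      a1 <- mean(ra[labels == 1, j]); a2 <- mean(ra[labels == 2, j])
      b1 <- mean(pres[labels == 1, j]); b2 <- mean(pres[labels == 2, j])
      if (a1 + a2 == 0) return(0)
      max(a1 / (a1 + a2) * b1, a2 / (a1 + a2) * b2)
    }, 1)
  }
  obs <- stat_of(rep(c(1, 2), each = 4))
  combos <- utils::combn(8, 4)
  ge <- rep(0, 4)
  for (k in seq_len(ncol(combos))) {
    lab <- rep(2, 8); lab[combos[, k]] <- 1
    ge <- ge + (stat_of(lab) >= obs - 1e-12)
  }
  expect_equal(attr(res, "n_perm"), 70)
  expect_equal(res$p, unname(ge / 70))
  # BH q-values are monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("IndVal is invariant to rescaling one sample's counts", {
  tb <- indval_toy()
  scaled <- tb$counts
  scaled[2, ] <- scaled[2, ] * 9L
  tb2 <- cohort_table(scaled, tb$metadata)
  r1 <- indval(tb, n_perm = 999, seed = 3)
  r2 <- indval(tb2, n_perm = 999, seed = 3)
  expect_equal(r1$indval, r2$indval)
  expect_equal(r1$p, r2$p)
})

test_that("IndVal contracts: empty OTU warning, bad groups error", {
  tb <- indval_toy()
  counts <- tb$counts
  counts[, "otu4"] <- 0L
  tb0 <- cohort_table(counts, tb$metadata)
  expect_warning(r <- indval(tb0, n_perm = 999, seed = 1), "absent")
  expect_false("otu4" %in% r$otu_id)
  expect_error(indval(tb, groups = rep("x", 8)), "2 groups")
  expect_error(indval(tb, n_perm = 99), "n_perm")
})

test_that("balancing selects matched animals and reduces discrepancy", {
  # 6 vaginal vs 3 c-section animals with identical schedules
  days <- c(0L, 30L, 120L)
  animals <- c(paste0("v", 1:6), paste0("c", 1:3))
  md <- do.call(rbind, lapply(animals, function(a)
    data.frame(sample_id = paste0(a, ".", days), animal_id = a,
               day_of_life = days, diet_code = "A",
               delivery_mode = if (startsWith(a, "v")) "vaginal"
                               else "c-section")))
  set.seed(1)
  counts <- matrix(rpois(nrow(md) * 5, 10), nrow(md), 5,
                   dimnames = list(md$sample_id, paste0("o", 1:5)))
  tb <- cohort_table(counts, md)
  bal <- balance_cohorts(tb, seed = 2)
  kept <- unique(bal$metadata$animal_id)
  expect_length(kept[startsWith(kept, "v")], 3)
  expect_length(kept[startsWith(kept, "c")], 3)
  expect_equal(sum(bal$metadata$delivery_mode == "vaginal"),
               sum(bal$metadata$delivery_mode == "c-section"))
  # already balanced input comes back unchanged
  expect_identical(balance_cohorts(bal, seed = 3)$counts, bal$counts)
  # per-bin discrepancy never increases on the simulated design
  sim <- simulate_cohort(small_sim_config(seed = 67))
  tb2 <- suppressMessages(assign_time_bins(sim$table, n_bins = 10))
  disc <- function(x) {
    tab <- table(x$metadata$time_bin, x$metadata$delivery_mode)
    sum(abs(tab[, 1] - tab[, 2]))
  }
  bal2 <- balance_cohorts(tb2, seed = 4)
  expect_lte(disc(bal2), disc(tb2))
})

test_that("label-shuffle validation is calibrated and detects planted effects", {
  sim <- simulate_cohort(small_sim_config(seed = 71))
  tb <- sim$table
  sub <- tb[, colSums(tb$counts > 0) >= 5]
  v <- indval_label_shuffle_validation(sub, n_shuffles = 20,
                                       n_perm = 999, seed = 5)
  # planted delivery-associated taxa push the observed count above the null
  expect_gt(v$observed, max(v$null))
  expect_equal(v$p, 1 / 21)
  expect_error(indval_label_shuffle_validation(sub, n_shuffles = 0),
               "n_shuffles")
})

test_that("first-day chi-squared counts cells and handles extremes", {
  sets <- first_day_otu_sets(make_tiny_table())
  expect_named(sets, c("c-section", "vaginal"))
  # hand case: 10 unique each, 10 shared, uniform expected -> chi2 = 0
  a <- c(paste0("u", 1:10), paste0("s", 1:10))
  b <- c(paste0("v", 1:10), paste0("s", 1:10))
  res <- unique_species_chi2(a, b)
  expect_equal(unname(res$counts), c(10, 10, 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$total, 30)
  expect_error(unique_species_chi2(character(0), character(0)), "empty")
})

test_that("phylum temporal comparison: densities normalise, shift detected", {
  # balanced design (equal group sizes and horizons) so the planted
  # 90-day acceleration is the only systematic mode difference
  sim <- simulate_cohort(small_sim_config(seed = 73, accel_csection = 90L,
                                          n_csection = 6L, frac_full = 1))
  tb <- suppressMessages(assign_time_bins(sim$table, n_bins = 12))
  ptc <- phylum_time_comparison(tb, n_resample = 200, seed = 6,
                                phyla = c("Firmicutes", "Bacteroidetes"))
  for (d in ptc$density) {
    dx <- diff(d$x[1:2])
    area <- sum((d$y[-1] + d$y[-length(d$y)]) / 2) * dx
    expect_lt(abs(area - 1), 1e-6)
  }
  # planted acceleration makes the c-section COM stochastically smaller
  expect_true(all(ptc$tests$com_csection < ptc$tests$com_vaginal))
  expect_true(all(ptc$tests$p < 0.001))
  expect_error(phylum_time_comparison(tb, phyla = "Cyanobacteria"),
               "absent")
})

test_that("phylum COM comparison is calibrated on identical count series", {
  # mirror the same animals into both modes: the per-bin series are
  # literally identical, so rejections only reflect resampling noise
  sim <- simulate_cohort(small_sim_config(seed = 79, n_delivery = 0L))
  tb <- sim$table
  md2 <- tb$metadata
  md2$sample_id <- paste0(md2$sample_id, ".mirror")
  md2$animal_id <- paste0(md2$animal_id, ".mirror")
  md2$delivery_mode <- ifelse(md2$delivery_mode == "vaginal",
                              "c-section", "vaginal")
  counts2 <- tb$counts
  rownames(counts2) <- md2$sample_id
  both <- cohort_table(rbind(tb$counts, counts2),
                       rbind(tb$metadata, md2), taxonomy = tb$taxonomy)
  both <- suppressMessages(assign_time_bins(both, n_bins = 12))
  ps <- vapply(1:10, function(s)
    phylum_time_comparison(both, n_resample = 100, seed = s,
                           phyla = "Firmicutes")$tests$p, 1)
  expect_gte(mean(ps > 0.05), 0.9)
})
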