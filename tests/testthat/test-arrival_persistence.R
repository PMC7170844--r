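test_that("arrival records pool first/last days consistently", {
  tb <- make_tiny_table()
  arr <- build_arrival_table(tb)
  ot <- arr$otus
  # otu4 seen only on days 30, 100 of a2... single-day case via otu2
  row3 <- ot[ot$otu_id == "otu3", ]
  expect_equal(row3$first_day, 0)
  expect_equal(row3$last_day, 305)
  expect_equal(row3$delta, 305)
  single <- ot[ot$otu_id == "otu4", ]
  expect_equal(single$delta, single$last_day - single$first_day)
  # pooled first = min over per-animal firsts
  fa <- arr$first_by_animal
  expect_equal(apply(fa, 2, min, na.rm = TRUE),
               stats::setNames(ot$first_day, ot$otu_id))
  # an OTU seen on a single day has delta 0
  counts <- tb$counts
  counts[, "otu4"] <- c(0L, 1L, 0L, 0L, 0L, 0L)  # only s2, day 12
  arr2 <- build_arrival_table(cohort_table(counts, tb$metadata))
  row4 <- arr2$otus[arr2$otus$otu_id == "otu4", ]
  expect_equal(c(row4$first_day, row4$last_day, row4$delta), c(12, 12, 0))
})

# cohort with exact planted per-bin first appearances
arrival_fixture <- function(new_per_bin) {
  n_bins <- length(new_per_bin)
  n_otu <- sum(new_per_bin)
  days <- seq(0L, by = 10L, length.out = n_bins)
  counts <- matrix(0L, n_bins, n_otu,
                   dimnames = list(paste0("s", seq_len(n_bins)),
                                   sprintf("o%03d", seq_len(n_otu))))
  j <- 1L
  for (b in seq_len(n_bins)) {
    take <- new_per_bin[b]
    if (take > 0) counts[b:n_bins, j:(j + take - 1L)] <- 1L
    j <- j + take
  }
  md <- data.frame(sample_id = rownames(counts), animal_id = "a1",
                   day_of_life = days, diet_code = "A",
                   delivery_mode = "vaginal",
                   time_bin = seq_len(n_bins) - 1L)
  cohort_table(counts, md)
}

test_that("arrival-rate slope is exact least squares on per-bin counts", {
  flat <- arrival_fixture(rep(10L, 5))
  r_flat <- arrival_rate_test(flat, n_perm = 100, seed = 1)
  expect_equal(r_flat$counts, rep(10, 5))
  expect_equal(r_flat$slope, 0)
  declining <- arrival_fixture(c(10L, 8L, 6L))
  r_dec <- arrival_rate_test(declining, n_perm = 100, seed = 1)
  expect_equal(r_dec$counts, c(10, 8, 6))
  expect_equal(r_dec$slope, -2)
  # conservation: per-bin counts sum to every OTU observed
  expect_equal(sum(r_dec$counts), ncol(declining$counts))
})

test_that("front-loaded arrivals give a slope shallower than the null", {
  sim <- simulate_cohort(small_sim_config(seed = 53))
  tb <- suppressMessages(assign_time_bins(sim$table, n_bins = 15))
  art <- arrival_rate_test(tb, n_perm = 199, seed = 2)
  # arrivals concentrate at birth, so the observed decline towards later
  # bins is less steep than under shuffled bin labels
  expect_gt(art$slope, art$null_mean)
  # every OTU observed at least once arrives in exactly one bin
  expect_equal(sum(art$counts), sum(colSums(tb$counts) > 0))
  expect_true(art$p >= 1 / 200 && art$p <= 1)
})

test_that("persistence curves cap at the window and drop late arrivals", {
  ot <- data.frame(otu_id = c("early_long", "early_short", "late"),
                   first_day = c(100, 100, 431),
                   last_day = c(800, 250, 600),
                   delta = c(700, 150, 169),
                   n_samples_present = c(10L, 5L, 3L))
  arr <- structure(list(otus = ot), class = "arrival_table")
  out <- persistence_by_arrival_day(arr, core_ids = "early_long")
  expect_false("late" %in% "" | 431 %in% out$first_day)  # excluded
  core_row <- out[out$group == "core", ]
  expect_equal(core_row$mean_persistence, 600)  # min(700, 600)
  non_row <- out[out$group == "non-core", ]
  expect_equal(non_row$mean_persistence, 150)
  expect_true(all(out$mean_persistence <= 600))
  # min_samples filtering is monotone
  n_at <- vapply(c(1, 5, 10), function(ms)
    sum(persistence_by_arrival_day(arr, "early_long",
                                   min_samples = ms)$n), 1)
  expect_true(all(diff(n_at) <= 0))
})

test_that("planted dwell contrast appears in the persistence curves", {
  sim <- simulate_cohort(small_sim_config(seed = 59))
  tb <- sim$table
  core_ids <- sim$truth$otus$otu_id[sim$truth$otus$is_core]
  arr <- build_arrival_table(tb)
  out <- persistence_by_arrival_day(arr, core_ids)
  early <- out[out$first_day <= 50, ]
  m_core <- stats::weighted.mean(
    early$mean_persistence[early$group == "core"],
    early$n[early$group == "core"])
  m_non <- stats::weighted.mean(
    early$mean_persistence[early$group == "non-core"],
    early$n[early$group == "non-core"])
  expect_gt(m_core, 2 * m_non)   # life-long core vs 200-day dwell
  # curves stay defined under the stringency sweep
  for (ms in c(5, 10, 20, 30)) {
    sw <- persistence_by_arrival_day(arr, core_ids, min_samples = ms)
    expect_gt(nrow(sw), 0)
    expect_true(all(sw$mean_persistence <= 600))
  }
})

test_that("persistence ratio saturates at 1 for ever-present OTUs", {
  sim <- simulate_cohort(small_sim_config(seed = 61))
  tb <- sim$table
  core_ids <- sim$truth$otus$otu_id[sim$truth$otus$is_core]
  prt <- persistence_ratio_test(tb, core_ids, n_perm = 100, seed = 5)
  everywhere <- names(which(colSums(tb$counts == 0) == 0))
  if (length(everywhere)) {
    sat <- prt$ratios$ratio[prt$ratios$otu_id %in% everywhere]
    expect_equal(sat, rep(1, length(sat)))
  }
  # OTUs seen twice on one day have delta 0; ratios stay finite, >= 0
  expect_true(all(is.finite(prt$ratios$ratio) & prt$ratios$ratio >= 0))
  expect_true(all(prt$ratios$perm_delta > 0))
  # planted persistent core scores higher than transient non-core
  expect_gt(prt$mean_core, prt$mean_noncore)
  expect_lt(prt$p, 0.01)
})
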