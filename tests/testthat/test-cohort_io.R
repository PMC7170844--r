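test_that("TSV write -> load round-trips counts, metadata and taxonomy", {
  sim <- simulate_cohort(small_sim_config(seed = 3))
  tb <- sim$table
  dir <- withr::local_tempdir()
  write_cohort(tb, dir, "rt")
  back <- load_cohort(file.path(dir, "rt_otu_table.tsv"),
                      file.path(dir, "rt_mapfile.tsv"),
                      file.path(dir, "rt_taxonomy.tsv"))
  expect_identical(back$counts[rownames(tb$counts), colnames(tb$counts)],
                   tb$counts)
  expect_identical(back$metadata$animal_id, tb$metadata$animal_id)
  expect_identical(back$metadata$day_of_life, tb$metadata$day_of_life)
  expect_identical(back$metadata$delivery_mode, tb$metadata$delivery_mode)
  tx <- back$taxonomy[match(tb$taxonomy$otu_id, back$taxonomy$otu_id), ]
  expect_equal(tx$phylum, tb$taxonomy$phylum)
  expect_equal(tx$species, tb$taxonomy$species)
})

test_that("BIOM and TSV loads of the same table agree", {
  tb <- make_tiny_table()
  dir <- withr::local_tempdir()
  write_cohort(tb, dir, "x", format = "tsv")
  write_cohort(tb, dir, "x", format = "biom")
  a <- load_cohort(file.path(dir, "x_otu_table.tsv"),
                   file.path(dir, "x_mapfile.tsv"))
  b <- load_cohort(file.path(dir, "x_otu_table.biom"),
                   file.path(dir, "x_mapfile.tsv"))
  expect_equal(b$counts[rownames(a$counts), colnames(a$counts)], a$counts)
})

test_that("metadata missing a sample errors naming it", {
  tb <- make_tiny_table()
  dir <- withr::local_tempdir()
  write_cohort(tb, dir, "m")
  md <- read.table(file.path(dir, "m_mapfile.tsv"), sep = "\t",
                   header = FALSE, skip = 1)
  hdr <- readLines(file.path(dir, "m_mapfile.tsv"), n = 1)
  writeLines(c(hdr, apply(md[-3, ], 1, paste, collapse = "\t")),
             file.path(dir, "m_mapfile.tsv"))
  expect_error(load_cohort(file.path(dir, "m_otu_table.tsv"),
                           file.path(dir, "m_mapfile.tsv")),
               "s3")
})

test_that("cohort_table validates ids, counts and metadata fields", {
  tb <- make_tiny_table()
  counts <- tb$counts
  md <- tb$metadata
  dup <- counts
  colnames(dup) <- rep("otu1", 4)
  expect_error(cohort_table(dup, md), "duplicate OTU")
  neg <- counts
  neg[1, 1] <- -1L
  expect_error(cohort_table(neg, md), "non-negative")
  frac <- matrix(0.5, 6, 4, dimnames = dimnames(counts))
  expect_error(cohort_table(frac, md), "whole numbers")
  md_bad <- md
  md_bad$delivery_mode[1] <- "unknown"
  expect_error(cohort_table(counts, md_bad), "delivery_mode")
  md_late <- md
  md_late$day_of_life[3] <- 9000L
  expect_error(cohort_table(counts, md_late), "horizon")
})

test_that("taxonomy rank-gap invariant is enforced", {
  bad <- data.frame(otu_id = "o1", domain = "Bacteria", phylum = "",
                    class = "X_cls1", order = "", family = "", genus = "",
                    species = "")
  expect_error(microsucc:::validate_taxonomy(bad), "gap")
})

test_that("filter_rare drops singletons/doubletons and honours boundaries", {
  tb <- make_tiny_table()
  totals <- colSums(tb$counts)   # otu1=11, otu2=7, otu3=11, otu4=4
  one <- tb
  one$counts[, "otu4"] <- c(1L, 0L, 0L, 0L, 0L, 0L)
  f <- filter_rare(one, 3)
  expect_false("otu4" %in% colnames(f$counts))
  three <- tb
  three$counts[, "otu4"] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  expect_true("otu4" %in% colnames(filter_rare(three, 3)$counts))
  expect_identical(filter_rare(tb, 0)$counts, tb$counts)
})

test_that("rarefy conserves depth, drops shallow samples, never inflates", {
  sim <- simulate_cohort(small_sim_config(seed = 5))
  tb <- sim$table
  expect_warning(r <- rarefy(tb, 10000, seed = 1), "below depth")
  expect_true(all(rowSums(r$counts) == 10000))
  expect_true(all(r$counts <=
                    tb$counts[rownames(r$counts), colnames(r$counts)]))
  deep <- tb[rowSums(tb$counts) >= 20000, ]
  r2 <- rarefy(deep, 10000, seed = 2)
  expect_equal(nrow(r2$counts), nrow(deep$counts))
  expect_error(rarefy(tb, 10^9), "below the rarefaction depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
  # one 100,000-read sample, OTU at proportion 0.3, depth 10,000
  counts <- matrix(c(30000L, 70000L, 30000L, 70000L), 2, 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a", "b")))
  md <- data.frame(sample_id = c("s1", "s2"), animal_id = c("x", "y"),
                   day_of_life = c(0L, 1L), diet_code = "A",
                   delivery_mode = "vaginal")
  tb <- cohort_table(counts, md)
  reps <- 200
  draws <- vapply(seq_len(reps), function(s)
    suppressWarnings(rarefy(tb, 10000, seed = s))$counts[1, "a"], 1)
  # hypergeometric: mean n*p, var n*p*q*(N-n)/(N-1)
  mu <- 10000 * 0.3
  sdv <- sqrt(10000 * 0.3 * 0.7 * (100000 - 10000) / (100000 - 1))
  expect_lt(abs(mean(draws) - mu), 3 * sdv / sqrt(reps))
})

test_that("time bins follow half-open boundaries and degenerate cases", {
  tb <- make_tiny_table()
  b <- suppressMessages(assign_time_bins(tb, edges = c(0, 30, 100, 832)))
  # days 0,12,305,0,30,100 -> bins 0,0,2,0,1,2 (day 30 opens bin 1)
  expect_identical(b$metadata$time_bin, c(0L, 0L, 2L, 0L, 1L, 2L))
  one <- suppressMessages(assign_time_bins(tb, n_bins = 1))
  expect_true(all(one$metadata$time_bin == 0L))
  expect_error(suppressMessages(assign_time_bins(tb, edges = c(0, 100))),
               "outside")
})

test_that("bin assignment is monotone in day of life", {
  sim <- simulate_cohort(small_sim_config(seed = 11))
  tb <- suppressMessages(assign_time_bins(sim$table, n_bins = 25))
  ord <- order(tb$metadata$day_of_life)
  expect_true(all(diff(tb$metadata$time_bin[ord]) >= 0))
})

test_that("58 equal-frequency bins balance occupancy on the default design", {
  sim <- simulate_cohort(cohort_sim_config(seed = 11))
  tb <- suppressMessages(assign_time_bins(sim$table, n_bins = 58))
  occ <- table(tb$metadata$time_bin)
  expect_length(occ, 58)
  expect_lte(max(occ) / min(occ), 2)
})

test_that("relative abundance normalises, is scale invariant, errors on 0", {
  tb <- make_tiny_table()
  ra <- to_relative_abundance(tb)
  expect_equal(rowSums(ra), rep(1, 6), ignore_attr = TRUE)
  expect_equal(unname(ra[1, ]), c(5, 0, 2, 0) / 7)
  scaled <- tb$counts
  scaled[2, ] <- scaled[2, ] * 7L
  expect_equal(to_relative_abundance(scaled)[2, ], ra[2, ])
  zero <- tb$counts
  zero[4, ] <- 0L
  expect_error(to_relative_abundance(zero), "zero-total")
})
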