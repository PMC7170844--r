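# deterministic hand-built cohort: 6 samples, 2 animals, 4 OTUs
make_tiny_table <- function() {
  counts <- matrix(
    c(5L, 0L, 2L, 0L,
      3L, 1L, 0L, 0L,
      0L, 4L, 1L, 0L,
      2L, 2L, 2L, 0L,
      0L, 0L, 6L, 1L,
      1L, 0L, 0L, 3L),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("s", 1:6), paste0("otu", 1:4)))
  md <- data.frame(
    sample_id = paste0("s", 1:6),
    animal_id = rep(c("a1", "a2"), each = 3),
    day_of_life = c(0L, 12L, 305L, 0L, 30L, 100L),
    diet_code = c("A", "A", "B", "A", "B", "B"),
    delivery_mode = rep(c("vaginal", "c-section"), each = 3),
    sex = rep(c("F", "M"), each = 3))
  cohort_table(counts, md)
}

# cohort_table from an exact relative-abundance matrix; last column absorbs
# rounding so every row sums to exactly `depth`
table_from_ra <- function(ra, animal, day, depth = 10000L,
                          delivery = NULL, diet = "A") {
  counts <- round(ra * depth)
  counts[, ncol(counts)] <- depth - rowSums(counts[, -ncol(counts),
                                                   drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("%s.%04d", animal, day)
  colnames(counts) <- sprintf("T%03d", seq_len(ncol(counts)))
  if (is.null(delivery)) delivery <- rep("vaginal", length(animal))
  md <- data.frame(sample_id = rownames(counts), animal_id = animal,
                   day_of_life = day, diet_code = diet,
                   delivery_mode = delivery)
  cohort_table(counts, md)
}

# scaled-down simulator settings shared across tests
small_sim_config <- function(seed = 7, ...) {
  defaults <- list(
    n_animals = 12L, n_csection = 5L, n_core = 40L, n_noncore = 160L,
    n_noise = 20L, n_ar = 10L, n_delivery = 15L,
    sampling_days = c(0:7, 10L, 13L, seq(20L, 220L, 14L),
                      seq(250L, 830L, 60L)),
    dropout = 0.1, seed = seed)
  do.call(cohort_sim_config, utils::modifyList(defaults, list(...)))
}

# panel of AR(1) taxa vs iid-noise taxa, realised as compositions: the
# clean world in which autoregressive calling has planted truth
ar_panel <- function(seed, n_animals = 20L, n_time = 18L, n_ar = 10L,
                     n_noise = 40L, alpha = 0.75, sd_innov = 0.4) {
  set.seed(seed)
  animal <- rep(sprintf("A%02d", seq_len(n_animals)), each = n_time)
  day <- rep(seq(0L, by = 14L, length.out = n_time), n_animals)
  n_tax <- n_ar + n_noise
  lat <- matrix(0, n_animals * n_time, n_tax)
  for (a in seq_len(n_animals)) {
    rows <- which(animal == sprintf("A%02d", a))
    z <- stats::rnorm(n_tax, 0, 0.5)
    for (t in seq_along(rows)) {
      z <- c(alpha * z[seq_len(n_ar)], numeric(n_noise)) +
        stats::rnorm(n_tax, 0, sd_innov)
      lat[rows[t], ] <- z
    }
  }
  ra <- exp(lat)
  ra <- ra / rowSums(ra)
  list(table = table_from_ra(ra, animal, day),
       ar_ids = sprintf("T%03d", seq_len(n_ar)),
       noise_ids = sprintf("T%03d", n_ar + seq_len(n_noise)))
}
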