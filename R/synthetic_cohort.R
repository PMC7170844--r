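#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults emulate a dense early-life rumen sampling design: 45 animals
#' (18 delivered by C-section), sampled daily over days 0-7, twice between
#' days 7 and 15, weekly to day 220 and monthly to day 830, with a third
#' of the cohort followed for the full period and the rest to day 240;
#' five sequential diet periods; ~200 core taxa arriving in the first days
#' of life with long persistence (mean dwell 600 days) against non-core
#' taxa arriving uniformly throughout life with short persistence (mean
#' dwell 200 days); delivery-mode-associated taxa with a group-restricted
#' colonisation pool; autoregressive taxa whose latent abundance depends
#' on its own lag and on the lagged community state; and overdispersed
#' per-sample read depths (mean 33,000).
#'
#' @param n_animals,n_csection cohort size and number of C-section births.
#' @param frac_full fraction of animals followed to `horizon_full` days;
#'   the rest stop at `horizon_short`.
#' @param horizon_full,horizon_short follow-up horizons in days.
#' @param sampling_days optional explicit vector of sampling days applied
#'   to every animal (truncated at its horizon); `NULL` uses the dense
#'   default schedule.
#' @param dropout probability that a scheduled sampling (other than day 0)
#'   is missed.
#' @param n_core,n_noncore,n_noise numbers of core, non-core and sporadic
#'   noise OTUs.
#' @param n_ar number of autoregressive taxa (drawn from the core set).
#' @param n_delivery number of delivery-mode-associated taxa per mode
#'   (drawn from the non-core set).
#' @param core_arrival_mean mean (days) of the exponential core arrival
#'   distribution; arrivals are capped at `core_arrival_max`.
#' @param core_arrival_max latest allowed core arrival day.
#' @param noncore_colonize_prob probability a non-core OTU ever colonises
#'   a given animal.
#' @param noncore_arrival_spread mean (days) of the per-animal exponential
#'   lag after a non-core OTU's cohort-level arrival epoch.
#' @param schedule_jitter jitter scheduled weekly/monthly sampling days by
#'   a few days per animal (real sampling is never grid-aligned).
#' @param delivery_colonize_own,delivery_colonize_other colonisation
#'   probabilities for delivery-associated OTUs in their own / the other
#'   delivery-mode group.
#' @param core_dwell_mean,noncore_dwell_mean mean occupancy dwell (days);
#'   `Inf` (the core default) means life-long residence, so core
#'   persistence saturates any observation window, as a persistent core
#'   should.
#' @param noise_presence_prob per-sample presence probability of noise OTUs.
#' @param baseline_core_mean,baseline_core_sd,baseline_noncore_mean,
#'   baseline_noncore_sd,baseline_noise log-scale baseline abundances.
#' @param diet_edges,diet_codes diet period boundaries (half-open) and codes.
#' @param diet_sd_core,diet_sd_noncore SD of per-OTU per-diet log offsets.
#' @param age_sd_core SD of the per-core-OTU age-trend coefficient.
#' @param delivery_effect log-abundance offset of a delivery-associated OTU
#'   in its own mode.
#' @param accel_csection days by which C-section animals' dynamics are
#'   advanced (earlier arrivals, earlier trends).
#' @param ar_alpha,ar_beta self-lag and community-lag coefficients of the
#'   autoregressive taxa (`|ar_alpha| < 1`).
#' @param sd_ar,sd_other log-scale innovation SDs for AR and other taxa.
#' @param depth_mean,depth_size negative-binomial read depth parameters.
#' @param error_rate,read_length per-nucleotide sequencing error rate and
#'   read length used by [inject_sequencing_errors()].
#' @param seed master seed; all randomness fans out from it.
#' @return a classed list of settings for [simulate_cohort()].
#' @export
cohort_sim_config <- function(n_animals = 45L, n_csection = 18L,
                              frac_full = 1 / 3,
                              horizon_full = 830L, horizon_short = 240L,
                              sampling_days = NULL, dropout = 0.2,
                              n_core = 200L, n_noncore = 1800L,
                              n_noise = 200L, n_ar = 100L,
                              n_delivery = 100L,
                              core_arrival_mean = 8, core_arrival_max = 140L,
                              noncore_colonize_prob = 0.3,
                              noncore_arrival_spread = 20,
                              schedule_jitter = TRUE,
                              delivery_colonize_own = 0.9,
                              delivery_colonize_other = 0.2,
                              core_dwell_mean = Inf, noncore_dwell_mean = 200,
                              noise_presence_prob = 0.02,
                              baseline_core_mean = 2, baseline_core_sd = 0.7,
                              baseline_noncore_mean = -1,
                              baseline_noncore_sd = 0.7,
                              baseline_noise = -3,
                              diet_edges = c(0L, 4L, 60L, 90L, 180L, 831L),
                              diet_codes = c("A", "B", "C", "D", "E"),
                              diet_sd_core = 0.8, diet_sd_noncore = 0.2,
                              age_sd_core = 1.2,
                              delivery_effect = 1.5, accel_csection = 30L,
                              ar_alpha = 0.6, ar_beta = 0.4,
                              sd_ar = 0.3, sd_other = 0.5,
                              depth_mean = 33000, depth_size = 3,
                              error_rate = 0.0024, read_length = 250L,
                              seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$n_csection > cfg$n_animals)
    stop("n_csection cannot exceed n_animals")
  if (abs(cfg$ar_alpha) >= 1) stop("ar_alpha must satisfy |alpha| < 1")
  if (cfg$n_ar > cfg$n_core) stop("n_ar cannot exceed n_core")
  if (2L * cfg$n_delivery > cfg$n_noncore)
    stop("2 * n_delivery cannot exceed n_noncore")
  stopifnot(cfg$dropout >= 0, cfg$dropout < 1,
            cfg$noncore_colonize_prob >= 0, cfg$noncore_colonize_prob <= 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            length(cfg$diet_edges) == length(cfg$diet_codes) + 1L)
  class(cfg) <- "cohort_sim_config"
  cfg
}

# daily 0-7, twice between days 7 and 15, weekly to 220, monthly onwards
default_sampling_days <- function(horizon) {
  d <- c(0:7, 10L, 13L, seq(20L, min(220L, horizon), by = 7L))
  if (horizon >= 250L) d <- c(d, seq(250L, horizon, by = 30L))
  d[d <= horizon]
}

diet_of_day <- function(day, edges, codes) {
  codes[findInterval(day, edges, rightmost.closed = FALSE)]
}

#' Simulate a longitudinal cohort with planted ground truth
#'
#' Latent log-abundances follow per-OTU baseline + diet offset + age trend
#' + delivery offset + a (possibly autoregressive) stochastic term, pushed
#' through a softmax over the OTUs present in a sample (presence governed
#' by planted arrival days and occupancy dwell times) and realised by a
#' multinomial draw at an overdispersed read depth. The generator is
#' deterministic given `config$seed`.
#'
#' @param config a [cohort_sim_config()].
#' @return a list with elements `table` (a [cohort_table()] including a
#'   generated taxonomy), `truth` (ground truth: per-OTU labels, the
#'   planted per-animal arrival-day matrix, and the config) and `taxonomy`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## ---- animals -------------------------------------------------------
  n_a <- cfg$n_animals
  animal_ids <- sprintf("A%02d", seq_len(n_a))
  mode <- rep("vaginal", n_a)
  mode[sample.int(n_a, cfg$n_csection)] <- "c-section"
  sex <- sample(c("F", "M"), n_a, replace = TRUE, prob = c(0.6, 0.4))
  n_full <- max(1L, round(cfg$frac_full * n_a))
  horizon <- rep(cfg$horizon_short, n_a)
  horizon[sample.int(n_a, n_full)] <- cfg$horizon_full

  ## ---- OTUs ----------------------------------------------------------
  n_otu <- cfg$n_core + cfg$n_noncore + cfg$n_noise
  otu_ids <- sprintf("OTU_%05d", seq_len(n_otu))
  cls <- rep(c("core", "noncore", "noise"),
             c(cfg$n_core, cfg$n_noncore, cfg$n_noise))
  is_core <- cls == "core"
  is_noise <- cls == "noise"
  core_idx <- which(is_core)
  noncore_idx <- which(cls == "noncore")

  is_ar <- rep(FALSE, n_otu)
  if (cfg$n_ar > 0) is_ar[sample(core_idx, cfg$n_ar)] <- TRUE
  # community score driving the AR taxa comes from the non-AR core taxa,
  # so the coupled latent system cannot feed back on itself and diverge
  com_idx <- which(is_core & !is_ar)
  if (!length(com_idx)) com_idx <- core_idx
  ar_alpha <- ifelse(is_ar, cfg$ar_alpha, 0)
  ar_beta <- ifelse(is_ar, cfg$ar_beta, 0)

  delivery_assoc <- rep("none", n_otu)
  if (cfg$n_delivery > 0) {
    picks <- sample(noncore_idx, 2L * cfg$n_delivery)
    delivery_assoc[picks[seq_len(cfg$n_delivery)]] <- "vaginal"
    delivery_assoc[picks[cfg$n_delivery + seq_len(cfg$n_delivery)]] <-
      "c-section"
  }

  baseline <- numeric(n_otu)
  baseline[is_core] <- stats::rnorm(cfg$n_core, cfg$baseline_core_mean,
                                    cfg$baseline_core_sd)
  baseline[cls == "noncore"] <- stats::rnorm(cfg$n_noncore,
                                             cfg$baseline_noncore_mean,
                                             cfg$baseline_noncore_sd)
  baseline[is_noise] <- cfg$baseline_noise

  n_diet <- length(cfg$diet_codes)
  diet_off <- matrix(stats::rnorm(n_otu * n_diet, 0, cfg$diet_sd_noncore),
                     n_otu, n_diet)
  diet_off[is_core, ] <- stats::rnorm(cfg$n_core * n_diet, 0,
                                      cfg$diet_sd_core)
  diet_off[is_noise, ] <- 0
  age_coef <- numeric(n_otu)
  age_coef[is_core] <- stats::rnorm(cfg$n_core, 0, cfg$age_sd_core)
  sd_innov <- ifelse(is_ar, cfg$sd_ar, cfg$sd_other)

  taxonomy <- simulate_taxonomy(otu_ids)

  ## ---- planted arrivals and dwell times ------------------------------
  # non-core OTUs invade the shared farm environment in a cohort-level
  # epoch; per-animal arrivals lag that epoch by an exponential delay, so
  # pooled first/last spans reflect the planted dwell rather than the
  # scatter of independent arrivals
  epoch <- round(stats::runif(n_otu, 0, cfg$horizon_full))
  # occupancy dwell is a species trait: one draw per OTU, shared across
  # animals, so pooled first-to-last spans reflect the planted dwell
  dwell_otu <- numeric(n_otu)
  dwell_otu[is_core] <- if (is.finite(cfg$core_dwell_mean))
    stats::rexp(cfg$n_core, 1 / cfg$core_dwell_mean) else Inf
  dwell_otu[cls == "noncore"] <- if (is.finite(cfg$noncore_dwell_mean))
    stats::rexp(cfg$n_noncore, 1 / cfg$noncore_dwell_mean) else Inf
  arrival <- matrix(Inf, n_a, n_otu, dimnames = list(animal_ids, otu_ids))
  dwell <- matrix(0, n_a, n_otu)
  for (a in seq_len(n_a)) {
    arr <- rep(Inf, n_otu)
    arr[is_core] <- pmin(round(stats::rexp(cfg$n_core,
                                           1 / cfg$core_arrival_mean)),
                         cfg$core_arrival_max)
    p_col <- rep(cfg$noncore_colonize_prob, n_otu)
    p_col[delivery_assoc == mode[a]] <- cfg$delivery_colonize_own
    p_col[delivery_assoc != "none" & delivery_assoc != mode[a]] <-
      cfg$delivery_colonize_other
    nc <- cls == "noncore"
    colonized <- nc & stats::runif(n_otu) < p_col
    arr[colonized] <- pmin(epoch[colonized] +
                             round(stats::rexp(sum(colonized),
                                               1 / cfg$noncore_arrival_spread)),
                           cfg$horizon_full)
    if (mode[a] == "c-section") arr <- pmax(0, arr - cfg$accel_csection)
    arrival[a, ] <- arr
    dwell[a, ] <- dwell_otu
  }

  ## ---- realise samples -----------------------------------------------
  counts_list <- vector("list", n_a)
  meta_list <- vector("list", n_a)
  for (a in seq_len(n_a)) {
    days <- if (is.null(cfg$sampling_days)) default_sampling_days(horizon[a])
            else cfg$sampling_days[cfg$sampling_days <= horizon[a]]
    if (cfg$dropout > 0 && length(days) > 1) {
      keep <- stats::runif(length(days)) >= cfg$dropout
      if (!any(keep)) keep[1] <- TRUE
      days <- days[keep]
    }
    if (isTRUE(cfg$schedule_jitter)) {
      # daily samples are exact; weekly slip by up to 2 days, monthly by 5
      jit <- ifelse(days <= 15, 0L,
                    ifelse(days <= 220,
                           sample(-2:2, length(days), replace = TRUE),
                           sample(-5:5, length(days), replace = TRUE)))
      days <- sort(unique(pmin(pmax(days + jit, 0L), horizon[a])))
    }
    accel <- if (mode[a] == "c-section") cfg$accel_csection else 0L
    z <- numeric(n_otu)
    com_score <- 0
    cm <- matrix(0L, length(days), n_otu)
    for (k in seq_along(days)) {
      d <- days[k]
      present <- arrival[a, ] <= d & d <= arrival[a, ] + dwell[a, ]
      present[is_noise] <- stats::runif(cfg$n_noise) < cfg$noise_presence_prob
      if (!any(present)) present[which.min(arrival[a, ])] <- TRUE
      d_eff <- min(d + accel, cfg$horizon_full)
      det <- baseline +
        diet_off[, match(diet_of_day(d, cfg$diet_edges, cfg$diet_codes),
                         cfg$diet_codes)] +
        age_coef * (log1p(d_eff) / log1p(cfg$horizon_full)) +
        cfg$delivery_effect * (delivery_assoc == mode[a])
      z <- ar_alpha * z + ar_beta * com_score +
        stats::rnorm(n_otu, 0, sd_innov)
      x <- det + z
      w <- ifelse(present, exp(x), 0)
      depth <- max(100L, stats::rnbinom(1, mu = cfg$depth_mean,
                                        size = cfg$depth_size))
      cm[k, ] <- stats::rmultinom(1, depth, w / sum(w))[, 1]
      com_score <- sum(z[com_idx]) / sqrt(length(com_idx))
    }
    rownames(cm) <- sprintf("%s.d%03d", animal_ids[a], days)
    counts_list[[a]] <- cm
    meta_list[[a]] <- data.frame(
      sample_id = rownames(cm), animal_id = animal_ids[a],
      day_of_life = days,
      diet_code = diet_of_day(days, cfg$diet_edges, cfg$diet_codes),
      delivery_mode = mode[a], sex = sex[a],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts_list)
  colnames(counts) <- otu_ids
  metadata <- do.call(rbind, meta_list)

  truth <- list(
    otus = data.frame(otu_id = otu_ids, class = cls, is_core = is_core,
                      is_noise = is_noise, is_ar = is_ar,
                      ar_alpha = ar_alpha, ar_beta = ar_beta,
                      delivery_association = delivery_assoc,
                      delivery_effect = ifelse(delivery_assoc == "none", 0,
                                               cfg$delivery_effect),
                      is_spurious = FALSE,
                      stringsAsFactors = FALSE),
    arrival_days = arrival,
    animals = data.frame(animal_id = animal_ids, delivery_mode = mode,
                         sex = sex, horizon = horizon,
                         stringsAsFactors = FALSE),
    config = cfg)

  table <- cohort_table(counts, metadata, taxonomy = taxonomy,
                        horizon = max(cfg$horizon_full, 831L))
  list(table = table, truth = truth, taxonomy = taxonomy)
}

# Greengenes-style lineages over a realistic phylum palette; genus and
# species are left empty for a share of OTUs (never with a gap).
simulate_taxonomy <- function(otu_ids) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia", "Euryarchaeota",
             "Spirochaetes")
  probs <- c(0.42, 0.30, 0.10, 0.06, 0.04, 0.04, 0.04)
  n <- length(otu_ids)
  phylum <- sample(phyla, n, replace = TRUE, prob = probs)
  domain <- ifelse(phylum == "Euryarchaeota", "Archaea", "Bacteria")
  cl <- paste0(phylum, "_cls", sample.int(3, n, replace = TRUE))
  ord <- paste0(phylum, "_ord", sample.int(4, n, replace = TRUE))
  fam <- paste0(phylum, "_fam", sample.int(8, n, replace = TRUE))
  gen <- ifelse(stats::runif(n) < 0.6,
                paste0(phylum, "_gen", sample.int(20, n, replace = TRUE)), "")
  sp <- ifelse(gen != "" & stats::runif(n) < 0.2,
               paste0("sp", sample.int(50, n, replace = TRUE)), "")
  validate_taxonomy(data.frame(otu_id = otu_ids, domain = domain,
                               phylum = phylum, class = cl, order = ord,
                               family = fam, genus = gen, species = sp,
                               stringsAsFactors = FALSE))
}

#' Inject sequencing errors into a cohort table
#'
#' Each read carries at least one nucleotide error with probability
#' `1 - (1 - rate)^read_length`; such reads are diverted from their parent
#' OTU into one of `children_per_parent` spurious error-variant OTUs of
#' that parent (uniformly). Per-sample read totals are conserved exactly.
#' Only realised children (>= 1 read somewhere) are materialised.
#'
#' @param table a [cohort_table()].
#' @param rate per-nucleotide error probability (default 0.0024).
#' @param read_length read length in nucleotides (default 250).
#' @param children_per_parent number of distinct error variants a parent
#'   OTU can spawn.
#' @param seed optional integer seed.
#' @param truth optional ground-truth list from [simulate_cohort()]; if
#'   given, returned updated with the spurious OTUs flagged.
#' @return a list with `table` (counts including spurious OTUs),
#'   `spurious_otus` (their ids), `parent_map` (child -> parent) and,
#'   when supplied, the updated `truth`.
#' @export
inject_sequencing_errors <- function(table, rate = 0.0024,
                                     read_length = 250L,
                                     children_per_parent = 100L,
                                     seed = NULL, truth = NULL) {
  stopifnot(rate >= 0, rate < 1, read_length >= 1)
  if (rate == 0)
    return(list(table = table, spurious_otus = character(0),
                parent_map = data.frame(child = character(0),
                                        parent = character(0)),
                truth = truth))
  if (!is.null(seed)) set.seed(seed)
  p_div <- per_read_error_prob(rate, read_length)
  counts <- table$counts
  nd <- matrix(stats::rbinom(length(counts), counts, p_div),
               nrow(counts), ncol(counts), dimnames = dimnames(counts))
  kept <- counts - nd
  child_of <- list()  # parent -> samples x children count matrix
  for (j in which(colSums(nd) > 0)) {
    cmat <- matrix(0L, nrow(counts), children_per_parent)
    for (i in which(nd[, j] > 0)) {
      cmat[i, ] <- tabulate(sample.int(children_per_parent, nd[i, j],
                                       replace = TRUE),
                            children_per_parent)
    }
    realized <- colSums(cmat) > 0
    cmat <- cmat[, realized, drop = FALSE]
    colnames(cmat) <- sprintf("%s.e%03d", colnames(counts)[j],
                              which(realized))
    child_of[[colnames(counts)[j]]] <- cmat
  }
  if (length(child_of)) {
    children <- do.call(cbind, unname(child_of))
    parent_map <- data.frame(
      child = unlist(lapply(child_of, colnames), use.names = FALSE),
      parent = rep(names(child_of), vapply(child_of, ncol, 1L)),
      stringsAsFactors = FALSE)
    new_counts <- cbind(kept, children)
  } else {
    parent_map <- data.frame(child = character(0), parent = character(0))
    new_counts <- kept
  }
  out <- table
  out$counts <- new_counts
  storage.mode(out$counts) <- "integer"
  if (!is.null(truth) && nrow(parent_map)) {
    add <- truth$otus[rep(NA_integer_, nrow(parent_map)), ]
    add$otu_id <- parent_map$child
    add$class <- "spurious"
    add$is_core <- FALSE; add$is_noise <- FALSE; add$is_ar <- FALSE
    add$ar_alpha <- 0; add$ar_beta <- 0
    add$delivery_association <- "none"; add$delivery_effect <- 0
    add$is_spurious <- TRUE
    rownames(add) <- NULL
    truth$otus <- rbind(truth$otus, add)
  }
  list(table = out, spurious_otus = parent_map$child,
       parent_map = parent_map, truth = truth)
}

#' Per-read probability of carrying at least one sequencing error
#'
#' @param rate per-nucleotide error probability.
#' @param read_length read length in nucleotides.
#' @return `1 - (1 - rate)^read_length`.
#' @export
per_read_error_prob <- function(rate, read_length) {
  stopifnot(rate >= 0, rate < 1, read_length >= 1)
  1 - (1 - rate)^read_length
}
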