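#' Configure the longitudinal microbiome simulator
#'
#' Builds and validates the parameter set for the capture-mark-recapture
#' microbiome simulator. The defaults describe a two-population woodland
#' rodent study: nightly trapping sessions every 2-4 weeks over a year,
#' a moderate per-session capture probability so that a typical animal is
#' caught about five times, strong per-individual compositional
#' signatures, a single-harmonic seasonal oscillation on a quarter of the
#' taxa peaking in mid-summer (communities contract onto the non-seasonal
#' pool, and converge across hosts, around the winter trough),
#' population-disjoint ASV pools drawn from
#' a shared pool of bacterial families, log-normal sequencing depths and
#' Dirichlet-multinomial count noise, plus a handful of planted
#' organelle-assigned contaminant ASVs.
#'
#' @param n_populations number of host populations (disjoint ASV pools).
#' @param asvs_per_population ASVs private to each population.
#' @param n_families taxonomic families shared across populations.
#' @param n_individuals_per_population hosts per population.
#' @param study_length_days study duration in days.
#' @param session_interval_days length-2 integer vector: min and max gap
#'   (days) between trapping sessions; gaps drawn uniformly.
#' @param capture_probability per-individual per-session capture probability.
#' @param sigma_individual s.d. of fixed per-individual per-ASV
#'   log-abundance offsets (the individuality signal).
#' @param sigma_drift daily s.d. of a Gaussian random walk added to the
#'   individual offsets over time (0 = static signatures).
#' @param seasonal_fraction fraction of each population's ASVs given
#'   seasonal forcing.
#' @param seasonal_amplitude log-scale cosine amplitude A.
#' @param seasonal_peak_day day-of-year (1-365) at which forced ASVs peak.
#' @param dirichlet_concentration Dirichlet-multinomial concentration
#'   theta > 0; larger = less overdispersion.
#' @param depth_log_mean,depth_log_sd log-normal sequencing depth parameters.
#' @param eta_sd s.d. of baseline log-abundances (rank-abundance spread).
#' @param contaminant_fraction expected relative abundance of each
#'   contaminant ASV.
#' @param n_contaminant_asvs planted organelle-assigned ASVs.
#' @param min_captures_target informational target for repeat captures.
#' @param seed integer master seed; all stochastic stages derive
#'   independent substreams from it.
#'
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(n_individuals_per_population = 5, seed = 1)
#' @export
simulationConfig <- function(n_populations = 2L,
                             asvs_per_population = 150L,
                             n_families = 12L,
                             n_individuals_per_population = 25L,
                             study_length_days = 365L,
                             session_interval_days = c(14L, 28L),
                             capture_probability = 0.3,
                             sigma_individual = 1.0,
                             sigma_drift = 0,
                             seasonal_fraction = 0.25,
                             seasonal_amplitude = 1.0,
                             seasonal_peak_day = 200,
                             dirichlet_concentration = 50,
                             depth_log_mean = log(15000),
                             depth_log_sd = 0.6,
                             eta_sd = 1.5,
                             contaminant_fraction = 0.001,
                             n_contaminant_asvs = 5L,
                             min_captures_target = 3L,
                             seed = 1L) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    asvs_per_population = as.integer(asvs_per_population),
    n_families = as.integer(n_families),
    n_individuals_per_population = as.integer(n_individuals_per_population),
    study_length_days = as.integer(study_length_days),
    session_interval_days = as.integer(session_interval_days),
    capture_probability = capture_probability,
    sigma_individual = sigma_individual,
    sigma_drift = sigma_drift,
    seasonal_fraction = seasonal_fraction,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_day = seasonal_peak_day,
    dirichlet_concentration = dirichlet_concentration,
    depth_log_mean = depth_log_mean,
    depth_log_sd = depth_log_sd,
    eta_sd = eta_sd,
    contaminant_fraction = contaminant_fraction,
    n_contaminant_asvs = as.integer(n_contaminant_asvs),
    min_captures_target = as.integer(min_captures_target),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_populations >= 1L,
    cfg$n_families >= 1L,
    cfg$asvs_per_population >= cfg$n_families,
    cfg$n_individuals_per_population >= 1L,
    length(cfg$session_interval_days) == 2L,
    cfg$session_interval_days[1] >= 1L,
    cfg$session_interval_days[2] >= cfg$session_interval_days[1],
    cfg$study_length_days >= cfg$session_interval_days[2],
    cfg$capture_probability >= 0, cfg$capture_probability <= 1,
    cfg$sigma_individual >= 0, cfg$sigma_drift >= 0,
    cfg$seasonal_fraction >= 0, cfg$seasonal_fraction <= 1,
    cfg$seasonal_peak_day >= 1, cfg$seasonal_peak_day <= 365,
    cfg$dirichlet_concentration > 0,
    cfg$depth_log_sd >= 0, cfg$eta_sd >= 0,
    cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1
  )
  if (cfg$n_contaminant_asvs < 0L)
    stop("n_contaminant_asvs must be non-negative")
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

## Deterministic per-stage substream: hash the stage tag into an offset so
## that e.g. the schedule is reproducible independently of the counts.
.subSeed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.withSubSeed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subSeed(seed, tag))
  expr
}

#' Simulate ASV taxonomy with population-disjoint pools
#'
#' Each population receives its own private set of ASV identifiers, but
#' family (and higher-rank) labels are drawn from a pool common to all
#' populations, so that populations share families, orders and phyla
#' while sharing no exact ASVs. Contaminant ASVs carry the literal
#' organelle labels used by 16S reference taxonomies: "Chloroplast" at
#' the Order rank and "Mitochondria" at the Family rank.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns `asv_id`, `population`,
#'   `Kingdom` ... `Genus`, `taxonomy` (semicolon-delimited string) and
#'   `is_organelle`.
#' @export
simulateTaxonomy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSubSeed(config$seed, "taxonomy", {
    nf <- config$n_families
    fams <- sprintf("Family_%02d", seq_len(nf))
    ## nest families into a coarser hierarchy shared by construction
    orders <- sprintf("Order_%02d", (seq_len(nf) - 1L) %/% 2L + 1L)
    classes <- sprintf("Class_%02d", (seq_len(nf) - 1L) %/% 4L + 1L)
    phyla  <- sprintf("Phylum_%02d", (seq_len(nf) - 1L) %/% 6L + 1L)
    rows <- list()
    for (p in seq_len(config$n_populations)) {
      fidx <- sample.int(nf, config$asvs_per_population, replace = TRUE)
      ## guarantee every family is represented in every population
      fidx[seq_len(nf)] <- seq_len(nf)
      ids <- sprintf("ASV_P%d_%04d", p, seq_len(config$asvs_per_population))
      rows[[p]] <- data.frame(
        asv_id = ids,
        population = sprintf("Pop%d", p),
        Kingdom = "Bacteria",
        Phylum = phyla[fidx],
        Class = classes[fidx],
        Order = orders[fidx],
        Family = fams[fidx],
        Genus = sprintf("Genus_P%d_%03d", p, fidx * 10L + (seq_along(fidx) %% 7L)),
        is_organelle = FALSE,
        stringsAsFactors = FALSE
      )
    }
    tax <- do.call(rbind, rows)
    if (config$n_contaminant_asvs > 0L) {
      k <- config$n_contaminant_asvs
      kind <- rep(c("Chloroplast", "Mitochondria"), length.out = k)
      cont <- data.frame(
        asv_id = sprintf("ASV_CONT_%03d", seq_len(k)),
        population = "shared",
        Kingdom = "Bacteria",
        Phylum = ifelse(kind == "Chloroplast", "Cyanobacteria", "Proteobacteria"),
        Class = ifelse(kind == "Chloroplast", "Chloroplast", "Alphaproteobacteria"),
        Order = ifelse(kind == "Chloroplast", "Chloroplast", "Rickettsiales"),
        Family = ifelse(kind == "Chloroplast", "Chloroplast", "Mitochondria"),
        Genus = NA_character_,
        is_organelle = TRUE,
        stringsAsFactors = FALSE
      )
      tax <- rbind(tax, cont)
    }
    ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")
    tax$taxonomy <- apply(tax[ranks], 1L, function(r)
      paste(ifelse(is.na(r), "unassigned", r), collapse = ";"))
    rownames(tax) <- tax$asv_id
    tax
  })
}

#' Simulate a capture-mark-recapture sampling schedule
#'
#' Trapping sessions are placed sequentially through the study with gaps
#' drawn uniformly from the configured interval (one night every 2-4
#' weeks by default). At each session every individual is captured
#' independently with `capture_probability`. Each capture record carries
#' the individual, population, day-of-study, calendar date and day-of-year
#' (365-day cycle), the session, and simulated host covariates (sex, age
#' class, reproductive status, body mass, body condition, sequencing
#' batch).
#'
#' @param config a [simulationConfig()].
#' @param start_date calendar date of study day 1.
#' @return data.frame of per-sample metadata keyed by `sample_id`.
#' @export
simulateSchedule <- function(config, start_date = as.Date("2015-01-01")) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSubSeed(config$seed, "schedule", {
    lo <- config$session_interval_days[1]
    hi <- config$session_interval_days[2]
    days <- integer()
    d <- sample(lo:hi, 1L)
    while (d <= config$study_length_days) {
      days <- c(days, d)
      d <- d + sample(lo:hi, 1L)
    }
    n_ind <- config$n_individuals_per_population
    inds <- unlist(lapply(seq_len(config$n_populations), function(p)
      sprintf("M_P%d_%02d", p, seq_len(n_ind))))
    pops <- rep(sprintf("Pop%d", seq_len(config$n_populations)), each = n_ind)
    sex <- sample(c("F", "M"), length(inds), replace = TRUE)
    mass0 <- stats::rnorm(length(inds), 20, 2.5)

    recs <- list()
    for (si in seq_along(days)) {
      caught <- stats::runif(length(inds)) < config$capture_probability
      if (!any(caught)) next
      idx <- which(caught)
      doy <- ((days[si] - 1L) %% 365L) + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        individual_id = inds[idx],
        population = pops[idx],
        session_id = sprintf("ses%03d", si),
        day_of_study = days[si],
        date = start_date + days[si] - 1L,
        day_of_year = doy,
        sex = sex[idx],
        age_class = sample(c("juvenile", "subadult", "adult"), length(idx),
                           replace = TRUE, prob = c(0.2, 0.3, 0.5)),
        reproductive_status = sample(c("active", "inactive"), length(idx),
                                     replace = TRUE),
        body_mass = round(mass0[idx] + stats::rnorm(length(idx), 0, 1), 1),
        body_condition = sample(0:4, length(idx), replace = TRUE),
        batch = sprintf("run%d", ((si - 1L) %/% 6L) + 1L),
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, recs)
    meta$sample_id <- sprintf("%s_%s", meta$individual_id, meta$session_id)
    rownames(meta) <- meta$sample_id
    meta[c("sample_id", setdiff(names(meta), "sample_id"))]
  })
}

#' Simulate Dirichlet-multinomial ASV counts with known structure
#'
#' For sample s of individual i on day-of-year t, the expected relative
#' abundance of ASV j is the softmax over the population's ASV pool of
#' `eta_j + b_ij(t) + A_j * cos(2*pi*(t - phi_j)/365)`, where `eta_j` is a
#' baseline log-abundance, `b_ij` is the individual's fixed signature
#' (Normal(0, sigma_individual^2), optionally drifting as a Gaussian
#' random walk with daily s.d. `sigma_drift`), and `A_j` is nonzero only
#' for the seasonally forced ASVs, all of which share peak day `phi`.
#' Contaminant ASVs are appended at a small constant expected fraction.
#' Counts are drawn Dirichlet-multinomial with concentration
#' `theta * p` at a log-normal depth (floored at 1 read).
#'
#' @param config a [simulationConfig()].
#' @param schedule metadata from [simulateSchedule()].
#' @param tax taxonomy from [simulateTaxonomy()].
#' @return list with `experiment` (counts-mode [AsvExperiment-class]) and
#'   `truth` (list: `individual_offsets`, `seasonal_asv_ids`,
#'   `amplitude_per_asv`, `peak_day_per_asv`, `population_asv_pools`,
#'   `eta`).
#' @export
simulateCounts <- function(config, schedule, tax) {
  stopifnot(inherits(config, "SimulationConfig"), nrow(schedule) > 0L)
  if (config$dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be > 0")
  .withSubSeed(config$seed, "counts", {
    pops <- sprintf("Pop%d", seq_len(config$n_populations))
    pool <- lapply(pops, function(p) tax$asv_id[tax$population == p])
    names(pool) <- pops
    asv_ids <- unlist(pool, use.names = FALSE)
    cont_ids <- tax$asv_id[tax$is_organelle]
    all_ids <- c(asv_ids, cont_ids)

    eta <- stats::rnorm(length(asv_ids), 0, config$eta_sd)
    names(eta) <- asv_ids

    ## seasonal forcing: a fixed fraction of each population's pool
    seasonal <- unlist(lapply(pool, function(ids) {
      k <- round(config$seasonal_fraction * length(ids))
      if (k > 0L) sample(ids, k) else character()
    }), use.names = FALSE)
    amp <- stats::setNames(rep(0, length(asv_ids)), asv_ids)
    amp[seasonal] <- config$seasonal_amplitude
    phi <- stats::setNames(rep(config$seasonal_peak_day, length(asv_ids)), asv_ids)

    inds <- unique(schedule$individual_id)
    ind_pop <- schedule$population[match(inds, schedule$individual_id)]
    b <- matrix(stats::rnorm(length(inds) * length(asv_ids),
                             0, config$sigma_individual),
                nrow = length(inds),
                dimnames = list(inds, asv_ids))

    theta <- config$dirichlet_concentration
    counts <- matrix(0L, nrow = nrow(schedule), ncol = length(all_ids),
                     dimnames = list(schedule$sample_id, all_ids))
    depths <- pmax(1, round(stats::rlnorm(nrow(schedule),
                                          config$depth_log_mean,
                                          config$depth_log_sd)))

    ## random-walk drift state per individual, advanced capture to capture
    ord <- order(schedule$individual_id, schedule$day_of_study)
    drift_state <- vector("list", length(inds))
    names(drift_state) <- inds
    last_day <- stats::setNames(rep(NA_real_, length(inds)), inds)

    cf <- config$contaminant_fraction
    tot_cont <- cf * length(cont_ids)
    for (r in ord) {
      ind <- schedule$individual_id[r]
      p <- schedule$population[r]
      ids <- pool[[p]]
      t_doy <- schedule$day_of_year[r]
      bvec <- b[ind, ids]
      if (config$sigma_drift > 0) {
        st <- drift_state[[ind]]
        if (is.null(st)) st <- stats::setNames(rep(0, length(ids)), ids)
        dt <- schedule$day_of_study[r] - last_day[ind]
        if (!is.na(dt) && dt > 0)
          st <- st + stats::rnorm(length(ids), 0, config$sigma_drift * sqrt(dt))
        drift_state[[ind]] <- st
        last_day[ind] <- schedule$day_of_study[r]
        bvec <- bvec + st
      }
      eta_s <- eta[ids] + bvec +
        amp[ids] * cos(2 * pi * (t_doy - phi[ids]) / 365)
      pvec <- exp(eta_s - max(eta_s))
      pvec <- pvec / sum(pvec)
      full <- c(pvec * (1 - tot_cont), rep(cf, length(cont_ids)))
      names(full) <- c(ids, cont_ids)
      ## Dirichlet-multinomial draw
      g <- stats::rgamma(length(full), shape = theta * full)
      if (sum(g) <= 0) g <- full
      cnt <- stats::rmultinom(1L, size = depths[r], prob = g / sum(g))[, 1L]
      counts[schedule$sample_id[r], names(full)] <- cnt
    }

    ae <- AsvExperiment(counts, sampleData = schedule,
                        taxonomy = tax[match(all_ids, tax$asv_id), ,
                                       drop = FALSE],
                        mode = "counts", samplesAsRows = TRUE)
    truth <- list(
      individual_offsets = b,
      seasonal_asv_ids = seasonal,
      amplitude_per_asv = amp,
      peak_day_per_asv = phi,
      population_asv_pools = pool,
      eta = eta
    )
    list(experiment = ae, truth = truth)
  })
}

#' Simulate a full longitudinal dataset
#'
#' Convenience wrapper running [simulateTaxonomy()], [simulateSchedule()]
#' and [simulateCounts()] from one configuration.
#'
#' @param config a [simulationConfig()]; or arguments passed on to it
#'   via `...`.
#' @param ... if `config` is missing, arguments for [simulationConfig()].
#' @return list with `experiment`, `truth`, `schedule`, `taxonomy`,
#'   `config`.
#' @examples
#' sim <- simulateDataset(simulationConfig(
#'   n_individuals_per_population = 4, asvs_per_population = 20,
#'   study_length_days = 120, seed = 7))
#' sim$experiment
#' @export
simulateDataset <- function(config, ...) {
  if (missing(config)) config <- simulationConfig(...)
  tax <- simulateTaxonomy(config)
  sched <- simulateSchedule(config)
  out <- simulateCounts(config, sched, tax)
  list(experiment = out$experiment, truth = out$truth,
       schedule = sched, taxonomy = tax, config = config)
}
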