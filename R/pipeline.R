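#' Run the full longitudinal analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> dissimilarities -> PCoA
#' -> core taxa -> sharing -> individuality -> time-decay -> monthly
#' convergence -> seasonal fit -> PERMANOVA -> dispersion, writing every
#' output as TSV under `out_dir` together with a JSON manifest listing
#' each file, its stage and the seed used, plus stage timings and record
#' counts. Re-running from the same configuration reproduces all outputs
#' because every stochastic stage draws from a named substream of the
#' master seed.
#'
#' @param config either a list (see Details) or the path to a YAML file.
#'   Recognised top-level keys: `simulation` (arguments for
#'   [simulationConfig()]) or `input` (paths `feature_table`, `metadata`,
#'   `taxonomy`); `filter` (`min_reads`, `min_copies`,
#'   `min_sample_fraction`); `analyses` (character vector, default all of
#'   `c("distances", "pcoa", "core", "sharing", "individuality",
#'   "timedecay", "convergence", "seasonal", "permanova", "dispersion")`);
#'   `n_perm`; `seed`.
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress to stderr?
#' @return the manifest data.frame (invisibly written to
#'   `manifest.json`): `file`, `stage`, `seed`.
#' @export
runPipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  n_perm <- if (!is.null(config$n_perm)) as.integer(config$n_perm) else 999L
  analyses <- config$analyses
  if (is.null(analyses))
    analyses <- c("distances", "pcoa", "core", "sharing", "individuality",
                  "timedecay", "convergence", "seasonal", "permanova",
                  "dispersion")
  manifest <- data.frame(file = character(), stage = character(),
                         seed = integer())
  note <- function(file, stage, s = seed) {
    manifest <<- rbind(manifest,
                       data.frame(file = file, stage = stage, seed = s))
  }
  logmsg <- function(...) if (verbose) message("[wildgut] ", ...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    on.exit(timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs"))
    logmsg("stage: ", name)
    tryCatch(expr, error = function(e) {
      .writeManifest(manifest, timings, out_dir, note)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ## --- input ---------------------------------------------------------
  if (!is.null(config$input)) {
    dat <- stage("load", {
      ae <- readFeatureTable(config$input$feature_table)
      meta <- readSampleMetadata(config$input$metadata)
      tax <- if (!is.null(config$input$taxonomy))
        readTaxonomyTable(config$input$taxonomy) else NULL
      list(experiment = attachMetadata(ae, meta, tax),
           schedule = meta, taxonomy = tax, truth = NULL)
    })
  } else {
    dat <- stage("simulate", {
      simargs <- config$simulation
      if (is.null(simargs)) simargs <- list()
      if (is.null(simargs$seed)) simargs$seed <- seed
      sim <- simulateDataset(do.call(simulationConfig, simargs))
      writeFeatureTable(sim$experiment, file.path(out_dir, "feature_table.tsv"))
      note("feature_table.tsv", "simulate", sim$config$seed)
      writeSampleMetadata(sim$schedule, file.path(out_dir, "metadata.tsv"))
      note("metadata.tsv", "simulate", sim$config$seed)
      writeTaxonomyTable(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
      note("taxonomy.tsv", "simulate", sim$config$seed)
      .writeTsv(data.frame(asv_id = names(sim$truth$amplitude_per_asv),
                           amplitude = sim$truth$amplitude_per_asv,
                           peak_day = sim$truth$peak_day_per_asv,
                           eta = sim$truth$eta[names(sim$truth$amplitude_per_asv)]),
                file.path(out_dir, "ground_truth_asvs.tsv"))
      note("ground_truth_asvs.tsv", "simulate", sim$config$seed)
      sim
    })
  }

  ## --- filtering -----------------------------------------------------
  fcfg <- config$filter
  if (is.null(fcfg)) fcfg <- list()
  filt <- stage("filter", {
    f <- standardFilter(dat$experiment,
      min_reads = fcfg$min_reads %||% 8000,
      min_copies = fcfg$min_copies %||% 2,
      min_sample_fraction = fcfg$min_sample_fraction %||% 0.01)
    .writeTsv(attr(f, "filter_log"), file.path(out_dir, "filter_log.tsv"))
    note("filter_log.tsv", "filter")
    f
  })
  rel <- stage("normalise", toRelative(filt))
  meta <- sampleData(filt)

  results <- list(filter_log = attr(filt, "filter_log"))
  bc <- pairs <- NULL
  if ("distances" %in% analyses) {
    bc <- stage("distances", {
      bc <- brayCurtis(rel)
      writeDistanceMatrix(bc, file.path(out_dir, "bray_curtis.tsv"))
      note("bray_curtis.tsv", "distances")
      jd <- jaccardDissimilarity(filt)
      writeDistanceMatrix(jd, file.path(out_dir, "jaccard.tsv"))
      note("jaccard.tsv", "distances")
      bc
    })
  }
  ordn <- NULL
  if ("pcoa" %in% analyses && !is.null(bc)) {
    ordn <- stage("pcoa", {
      o <- pcoa(bc)
      .writeTsv(data.frame(sample_id = o@sampleIds, scores(o)),
                file.path(out_dir, "pcoa_coordinates.tsv"))
      note("pcoa_coordinates.tsv", "pcoa")
      .writeTsv(data.frame(axis = seq_along(eigenvalues(o)),
                           eigenvalue = eigenvalues(o)),
                file.path(out_dir, "pcoa_eigenvalues.tsv"))
      note("pcoa_eigenvalues.tsv", "pcoa")
      o
    })
  }
  if ("core" %in% analyses) {
    stage("core", {
      rep <- coreTaxaReport(filt, rel, seed = seed)
      .writeTsv(rep, file.path(out_dir, "core_taxa.tsv"))
      note("core_taxa.tsv", "core")
      results$core <- rep
    })
  }
  if ("sharing" %in% analyses && length(unique(meta$population)) >= 2L) {
    stage("sharing", {
      rows <- list()
      for (rk in c("asv", "Family", "Order", "Phylum")) {
        ov <- taxonOverlap(filt, rank = rk)
        rows[[rk]] <- cbind(rank = rk, ov$pairs)
      }
      .writeTsv(do.call(rbind, rows), file.path(out_dir, "sharing.tsv"))
      note("sharing.tsv", "sharing")
      results$sharing <- do.call(rbind, rows)
    })
  }
  if (!is.null(bc) &&
      any(c("individuality", "timedecay", "convergence") %in% analyses)) {
    pairs <- stage("pairs", {
      p <- enumeratePairs(bc, meta)
      .writeTsv(p, file.path(out_dir, "pairs.tsv"))
      note("pairs.tsv", "pairs")
      p
    })
  }
  if ("individuality" %in% analyses && !is.null(pairs)) {
    stage("individuality", {
      tst <- individualityTest(pairs, n_perm = n_perm, seed = seed)
      .writeTsv(data.frame(U = tst$U, n_same_mouse = tst$n_a,
                           n_same_date = tst$n_b, p_value = tst$p_value,
                           mean_same_mouse = tst$mean_same_mouse,
                           mean_same_date = tst$mean_same_date),
                file.path(out_dir, "individuality.tsv"))
      note("individuality.tsv", "individuality")
      results$individuality <- tst
    })
  }
  if ("timedecay" %in% analyses && !is.null(pairs)) {
    stage("timedecay", {
      td <- timeDecay(pairs, meta = meta)
      .writeTsv(data.frame(slope = td$slope, slope_se = td$slope_se,
                           F = td$F, p_value = td$p_value,
                           adj_r_squared = td$adj_r_squared,
                           n_pairs = td$n_pairs),
                file.path(out_dir, "time_decay.tsv"))
      note("time_decay.tsv", "timedecay")
      .writeTsv(rateOfChange(pairs), file.path(out_dir, "rate_of_change.tsv"))
      note("rate_of_change.tsv", "timedecay")
      results$timedecay <- td
    })
  }
  if ("convergence" %in% analyses && !is.null(pairs)) {
    stage("convergence", {
      cv <- monthlyConvergence(pairs, n_perm = n_perm, seed = seed)
      .writeTsv(cv$summary, file.path(out_dir, "monthly_convergence.tsv"))
      note("monthly_convergence.tsv", "convergence")
      results$convergence <- cv
    })
  }
  if ("seasonal" %in% analyses && !is.null(ordn)) {
    stage("seasonal", {
      fit <- harmonicSeasonalFit(scores(ordn)[, 1L], meta,
                                 random_intercept_individual = TRUE)
      .writeTsv(data.frame(amplitude = fit$amplitude,
                           peak_day = fit$peak_day,
                           seasonal_r_squared = fit$seasonal_r_squared,
                           n = fit$n),
                file.path(out_dir, "seasonal_fit.tsv"))
      note("seasonal_fit.tsv", "seasonal")
      results$seasonal <- fit
    })
  }
  if ("permanova" %in% analyses && !is.null(bc)) {
    stage("permanova", {
      sub <- oneSamplePerIndividual(asDistanceMatrix(bc), meta, seed = seed)
      msub <- meta[match(rownames(sub), meta$sample_id), ]
      msub$month <- factor(format(as.Date(msub$date), "%m"))
      terms <- c("month", intersect(c("sex", "body_mass"), names(msub)))
      pt <- permanova(sub, stats::reformulate(terms), msub,
                      n_perm = n_perm, seed = seed)
      .writeTsv(as.data.frame(pt), file.path(out_dir, "permanova.tsv"))
      note("permanova.tsv", "permanova")
      results$permanova <- pt
    })
  }
  if ("dispersion" %in% analyses && !is.null(bc)) {
    stage("dispersion", {
      mo <- factor(format(as.Date(meta$date), "%m"))
      dt <- dispersionTest(bc, mo, n_perm = n_perm, seed = seed)
      .writeTsv(data.frame(factor = "month", F = dt$F, df1 = dt$df1,
                           df2 = dt$df2, p_value = dt$p_value),
                file.path(out_dir, "dispersion.tsv"))
      note("dispersion.tsv", "dispersion")
      results$dispersion <- dt
    })
  }

  .writeManifest(manifest, timings, out_dir, note)
  invisible(structure(manifest, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeManifest <- function(manifest, timings, out_dir, note) {
  jsonlite::write_json(
    list(files = manifest, timings = timings),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}
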