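#' Taxon overlap between populations at a chosen rank
#'
#' Collapses each population's detected ASVs (any nonzero count in any
#' sample of that population) to the chosen taxonomic rank and reports,
#' for every population pair, the shared taxon count and the shared
#' fraction relative to each population's set, plus per-population
#' exclusive counts and the full intersection. Unassigned labels at the
#' rank are excluded from the sets (absence of an assignment is not
#' evidence of sharing) and counted separately.
#'
#' @param x an [AsvExperiment-class] whose metadata has a `population`
#'   column and whose rowData carries taxonomy ranks.
#' @param rank one of `"asv"`, `"Genus"`, `"Family"`, `"Order"`,
#'   `"Class"`, `"Phylum"`.
#' @return list with `rank`, `sets` (per-population taxon sets), `pairs`
#'   (data.frame pop_a, pop_b, shared, frac_a, frac_b), `exclusive`
#'   (named counts), `shared_all` (taxa common to every population),
#'   `n_unassigned` (per population).
#' @export
taxonOverlap <- function(x, rank = "asv") {
  meta <- sampleData(x)
  stopifnot("population" %in% names(meta))
  pops <- unique(meta$population)
  if (length(pops) < 2L) stop("need >= 2 populations")
  present <- abundances(x) > 0
  tax <- taxonomy(x)
  if (!identical(rank, "asv") && !rank %in% names(tax))
    stop("rank '", rank, "' not found in taxonomy")
  sets <- list(); unass <- integer()
  for (p in pops) {
    detected <- rownames(x)[rowSums(present[, meta$population == p,
                                            drop = FALSE]) > 0]
    if (identical(rank, "asv")) {
      sets[[p]] <- detected
      unass[p] <- 0L
    } else {
      labs <- tax[[rank]][match(detected, tax$asv_id)]
      bad <- is.na(labs) | labs %in% c("", "unassigned", "Unassigned")
      unass[p] <- sum(bad)
      sets[[p]] <- unique(labs[!bad])
    }
  }
  pairs <- list()
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
    a <- sets[[pops[i]]]; b <- sets[[pops[j]]]
    sh <- length(intersect(a, b))
    pairs[[length(pairs) + 1L]] <- data.frame(
      pop_a = pops[i], pop_b = pops[j], shared = sh,
      frac_a = if (length(a)) sh / length(a) else NA_real_,
      frac_b = if (length(b)) sh / length(b) else NA_real_)
  }
  others <- function(p) unique(unlist(sets[setdiff(pops, p)]))
  exclusive <- vapply(pops, function(p)
    length(setdiff(sets[[p]], others(p))), 0L)
  list(rank = rank, sets = sets, pairs = do.call(rbind, pairs),
       exclusive = exclusive,
       shared_all = Reduce(intersect, sets), n_unassigned = unass)
}

#' Bootstrap shared fractions under subsampled, equalised sample sizes
#'
#' Repeatedly draws `subsample_n` samples without replacement from each
#' population, rebuilds presence sets at the chosen rank, and recomputes
#' pairwise shared fractions — a check that observed sharing is not an
#' artefact of unequal sampling effort.
#'
#' @inheritParams taxonOverlap
#' @param n_boot bootstrap replicates.
#' @param subsample_n samples drawn per population per replicate; must
#'   not exceed the smallest population's sample count.
#' @param seed integer seed.
#' @return data.frame per population pair and direction: `pop_a`,
#'   `pop_b`, `which_frac` ("a" or "b"), `mean`, `q2.5`, `q97.5`,
#'   `n_boot`.
#' @export
bootstrapSharedFraction <- function(x, rank = "asv", n_boot = 100,
                                    subsample_n, seed = 1) {
  meta <- sampleData(x)
  pops <- unique(meta$population)
  sizes <- table(meta$population)
  if (subsample_n > min(sizes))
    stop("subsample_n (", subsample_n, ") exceeds the smallest population (",
         min(sizes), " samples)")
  reps <- .withSubSeed(seed, "bootstrap_sharing", {
    lapply(seq_len(n_boot), function(b) {
      keep <- unlist(lapply(pops, function(p) {
        ix <- which(meta$population == p)
        ix[sample.int(length(ix), subsample_n)]
      }))
      taxonOverlap(x[, keep], rank = rank)$pairs
    })
  })
  all <- do.call(rbind, reps)
  out <- list()
  for (k in seq_len(nrow(reps[[1]]))) {
    sub <- all[seq(k, nrow(all), by = nrow(reps[[1]])), ]
    for (w in c("a", "b")) {
      v <- sub[[paste0("frac_", w)]]
      out[[length(out) + 1L]] <- data.frame(
        pop_a = sub$pop_a[1], pop_b = sub$pop_b[1], which_frac = w,
        mean = mean(v), q2.5 = stats::quantile(v, 0.025, names = FALSE),
        q97.5 = stats::quantile(v, 0.975, names = FALSE), n_boot = n_boot)
    }
  }
  do.call(rbind, out)
}
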