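analysis_trait_cols <- c("Topt", "Ttol", "Hopt", "Htol", "Pdisp", "Pglobal")

check_census_cols <- function(census, need) {
  missing <- setdiff(need, names(census))
  if (length(missing))
    stop("census is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(census)
}

#' Restrict a census to established lineages
#'
#' Keeps only individuals whose lineage reached a total landscape
#' population of at least `min_lineage_pop` individuals at the final
#' time step, within its own replicate (lineage ids are replicate-
#' scoped). This excludes transient lineages with maladaptive trait
#' combinations that arise from the random immigrant trait generation
#' and rarely persist beyond a few steps. Input row order is preserved.
#'
#' @param census A census table with `replicate` and `lineage_id`
#'   columns (and usually `scenario`).
#' @param min_lineage_pop Establishment threshold (default 50).
#' @return The retained subset of `census`.
#' @export
filter_established <- function(census, min_lineage_pop = 50) {
  stopifnot(min_lineage_pop >= 1)
  check_census_cols(census, c("replicate", "lineage_id"))
  if (nrow(census) == 0) return(census)
  scen <- if ("scenario" %in% names(census)) census$scenario else ""
  key <- paste(scen, census$replicate, census$lineage_id, sep = "\r")
  counts <- table(key)
  keep <- counts[key] >= min_lineage_pop
  out <- census[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample individuals per scenario
#'
#' Draws a simple random sample without replacement of up to
#' `sample_size` individuals from each scenario, pooling that
#' scenario's replicates before drawing. Scenarios with fewer
#' individuals than `sample_size` (population crashes at the final
#' step) contribute all of their individuals.
#'
#' @param census A (filtered) census table with a `scenario` column.
#' @param sample_size Target individuals per scenario (default 10000).
#' @param sample_seed Optional integer seed for the draw.
#' @return The sampled subset, in stable scenario order.
#' @export
sample_individuals <- function(census, sample_size = 10000,
                               sample_seed = NULL) {
  stopifnot(sample_size >= 1)
  check_census_cols(census, "scenario")
  if (!is.null(sample_seed)) set.seed(sample_seed)
  if (nrow(census) == 0) return(census)
  idx <- unlist(lapply(split(seq_len(nrow(census)), census$scenario), {
    function(rows)
      if (length(rows) <= sample_size) rows
      else sort(sample(rows, sample_size))
  }), use.names = FALSE)
  out <- census[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise R-squared correlations between traits
#'
#' Squared Pearson correlations between the six organism traits, with
#' the niche optima absolute-value transformed by default (the sign of
#' an optimum is arbitrary on a standardized, symmetric attribute
#' axis; its magnitude measures environmental extremeness). Pairs with
#' zero variance are reported as `NA`, not 0.
#'
#' @param census A sampled census table (single scenario or any subset
#'   with at least 3 rows).
#' @param abs_transform_optima Apply `abs()` to `Topt` and `Hopt`
#'   before correlating (default `TRUE`).
#' @return An object of class `"trait_correlations"`: the 6 x 6
#'   symmetric R-squared matrix with attribute `n` (rows used). Row
#'   and column names carry the transform (`|Topt|` vs `Topt`).
#' @export
trait_correlations <- function(census, abs_transform_optima = TRUE) {
  check_census_cols(census, analysis_trait_cols)
  if (nrow(census) < 3)
    stop("need at least 3 individuals to estimate trait correlations",
         call. = FALSE)
  vals <- census[, analysis_trait_cols]
  nms <- analysis_trait_cols
  if (abs_transform_optima) {
    vals$Topt <- abs(vals$Topt)
    vals$Hopt <- abs(vals$Hopt)
    nms[nms == "Topt"] <- "|Topt|"
    nms[nms == "Hopt"] <- "|Hopt|"
  }
  sds <- vapply(vals, stats::sd, 0)
  r <- suppressWarnings(stats::cor(as.matrix(vals)))
  r2 <- r^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  diag(r2) <- ifelse(sds == 0, NA_real_, 1)
  dimnames(r2) <- list(nms, nms)
  structure(r2, n = nrow(census), class = c("trait_correlations", "matrix",
                                            "array"))
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Trait R-squared matrix (n = %d individuals)\n", attr(x, "n")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Long-format trait correlations per scenario
#'
#' Convenience wrapper applying [trait_correlations()] within each
#' scenario of a sampled census and returning the 15 unique
#' off-diagonal pairs per scenario in long format, ready for export.
#'
#' @inheritParams trait_correlations
#' @return A data.frame with columns `scenario`, `trait_i`, `trait_j`,
#'   `r2`, `n`.
#' @export
correlations_by_scenario <- function(census, abs_transform_optima = TRUE) {
  check_census_cols(census, "scenario")
  parts <- lapply(split(census, census$scenario), function(d) {
    m <- trait_correlations(d, abs_transform_optima)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(scenario = d$scenario[[1]],
               trait_i = rownames(m)[ut[, 1]],
               trait_j = colnames(m)[ut[, 2]],
               r2 = m[ut], n = attr(m, "n"))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Niche-optimum mismatch with patch attributes
#'
#' One row per individual: the differences between niche optima and
#' the (time-invariant, G-scaled) patch attributes of the patch the
#' individual settled in, alongside the patch attributes and fitness
#' metrics. Mismatches near zero indicate local adaptation; plotting
#' mismatch against the patch attribute reveals the tendency of
#' organisms in extreme patches to be adapted to slightly more average
#' conditions.
#'
#' @param census A sampled census table.
#' @return A data.frame with `scenario`, `replicate` (if present),
#'   `Tpatch_base`, `Hpatch`, `T_mismatch` (`Topt - Tpatch_base`),
#'   `H_mismatch` (`Hopt - Hpatch`) and the fitness metric columns.
#' @export
adaptation_mismatch <- function(census) {
  check_census_cols(census, c("Topt", "Hopt", "Tpatch_base", "Hpatch",
                              "Efert_final", "prop_max_tradeoff",
                              "prop_max_R0"))
  keep <- intersect(c("scenario", "replicate"), names(census))
  data.frame(
    census[, keep, drop = FALSE],
    Tpatch_base = census$Tpatch_base,
    Hpatch = census$Hpatch,
    T_mismatch = census$Topt - census$Tpatch_base,
    H_mismatch = census$Hopt - census$Hpatch,
    Efert_final = census$Efert_final,
    prop_max_tradeoff = census$prop_max_tradeoff,
    prop_max_R0 = census$prop_max_R0,
    row.names = NULL
  )
}

#' Per-scenario distribution summaries
#'
#' Median, variance and quartiles of each trait and fitness metric per
#' scenario — the numbers behind box-plot style comparisons of trait
#' distributions across the `G` x `hurst` grid.
#'
#' @param census A sampled census table with a `scenario` column.
#' @return A data.frame with one row per (scenario, variable) and
#'   columns `n`, `median`, `variance`, `q25`, `q75`.
#' @export
scenario_summaries <- function(census) {
  check_census_cols(census, "scenario")
  vars <- intersect(c(analysis_trait_cols, "Efert_final",
                      "prop_max_tradeoff", "prop_max_R0"), names(census))
  parts <- lapply(split(census, census$scenario), function(d) {
    do.call(rbind, lapply(vars, function(v) {
      x <- d[[v]]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(scenario = d$scenario[[1]], variable = v, n = length(x),
                 median = q[2],
                 variance = if (length(x) > 1) stats::var(x) else 0,
                 q25 = q[1], q75 = q[3])
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Full census analysis pipeline
#'
#' Establishment filter, per-scenario sampling, trait correlations,
#' scenario summaries and adaptation/mismatch table in one call,
#' with the study defaults (threshold 50, sample 10,000).
#'
#' @param census A raw census table (all scenarios bound together).
#' @param min_lineage_pop Establishment threshold.
#' @param sample_size Individuals sampled per scenario.
#' @param sample_seed Seed for the sampling draw.
#' @param abs_transform_optima Absolute-value transform for the optima
#'   in the correlation analysis.
#' @return A list with `sampled` (the analysis data set),
#'   `correlations` (long format), `summaries`, `adaptation`.
#' @export
analyze_census <- function(census, min_lineage_pop = 50,
                           sample_size = 10000, sample_seed = NULL,
                           abs_transform_optima = TRUE) {
  est <- filter_established(census, min_lineage_pop)
  smp <- sample_individuals(est, sample_size, sample_seed)
  list(sampled = smp,
       correlations = correlations_by_scenario(smp, abs_transform_optima),
       summaries = scenario_summaries(smp),
       adaptation = adaptation_mismatch(smp))
}
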