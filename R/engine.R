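summary_cols <- function() {
  qty <- c("Topt", "Ttol", "Hopt", "Htol", "Pdisp", "Pglobal",
           "Efert", "prop_max_tradeoff", "prop_max_R0")
  c("t", "population",
    as.vector(rbind(paste0("mean_", qty), paste0("var_", qty))))
}

census_cols <- function()
  c("x", "y", "lineage_id", "Topt", "Ttol", "Hopt", "Htol",
    "Pdisp", "Pglobal", "Tpatch_base", "Tpatch_realized", "Hpatch",
    "Efert_final", "prop_max_tradeoff", "prop_max_R0")

#' Initialize a simulation state
#'
#' A state bundles the landscape, parameters, the pre-generated global
#' fluctuation series, the current population (initially empty — the
#' landscape is colonized by immigrants), a 0-based patch index per
#' individual, the time counter and the next fresh lineage id.
#'
#' @param landscape A [make_landscape()] object.
#' @param params A [sim_params()] object.
#' @param fluctuations Optional fluctuation series; drawn with
#'   [generate_fluctuations()] if omitted.
#' @return A list of class `"sim_state"`.
#' @export
new_sim_state <- function(landscape, params, fluctuations = NULL) {
  if (is.null(fluctuations)) fluctuations <- generate_fluctuations(params$tmax)
  stopifnot(length(fluctuations) >= 1)
  structure(
    list(landscape = landscape, params = params, eps = fluctuations,
         pop = draw_immigrant(params, 1L, n = 0), patch = integer(0),
         t = 0L, next_lineage_id = 1L),
    class = "sim_state"
  )
}

# Flatten a height x width attribute matrix to patch order p = y*width + x.
patch_vector <- function(m) as.vector(t(m))

#' Advance a simulation state by one annual cycle
#'
#' Executes one time step in the fixed phase order: (1) reproduction
#' using the patch attributes realized at this step; (2) density-
#' dependent competition within each patch's offspring pool;
#' (3) external immigration (immigrants join the new generation and may
#' disperse in their arrival step); (4) dispersal of the new
#' generation. Adults are removed (complete generational replacement)
#' and the time counter advances.
#'
#' This pure-R step is the reference implementation used for
#' fine-grained testing; [run_replicate()] defaults to a compiled
#' engine implementing the identical cycle.
#'
#' @param state A [new_sim_state()] object.
#' @return The updated state.
#' @export
step <- function(state) {
  p <- state$params; land <- state$landscape
  t_now <- state$t + 1L
  if (t_now > length(state$eps))
    stop("fluctuation series exhausted: cannot step past tmax", call. = FALSE)
  width <- land$width; height <- land$height
  npatch <- width * height
  tb <- p$G * patch_vector(land$t_base)
  hb <- p$G * patch_vector(land$h_base)
  eps_t <- state$eps[[t_now]]

  # (1) reproduction
  pop <- state$pop; patch <- state$patch
  if (nrow(pop) > 0) {
    ef <- fertility(pop, tb[patch + 1L] + eps_t, hb[patch + 1L], p)
    counts <- stats::rpois(nrow(pop), ef)
    idx <- rep.int(seq_len(nrow(pop)), counts)
    off <- pop[idx, , drop = FALSE]
    off_patch <- patch[idx]
  } else {
    off <- pop
    off_patch <- integer(0)
  }

  # (2) competition among each patch's offspring pool
  if (nrow(off) > 0) {
    L0 <- tabulate(off_patch + 1L, nbins = npatch)
    sa <- bh_survival_prob(L0, p)
    keep <- stats::runif(nrow(off)) <= sa[off_patch + 1L]
    off <- off[keep, , drop = FALSE]
    off_patch <- off_patch[keep]
  }

  # (3) immigration
  imm <- immigrate(land, p, state$next_lineage_id)
  pop <- rbind(off, imm$org)
  patch <- c(off_patch, imm$patch)

  # (4) dispersal
  if (nrow(pop) > 0) {
    mode <- decide_dispersal(pop)
    x <- patch %% width
    y <- patch %/% width
    nb <- mode == "neighbor"
    if (any(nb)) {
      tg <- neighbor_target(x[nb], y[nb], width, height)
      x[nb] <- tg$x; y[nb] <- tg$y
    }
    gl <- mode == "global"
    if (any(gl)) {
      tg <- global_target(x[gl], y[gl], width, height)
      x[gl] <- tg$x; y[gl] <- tg$y
    }
    patch <- as.integer(y * width + x)
  }

  state$pop <- pop
  state$patch <- patch
  state$t <- t_now
  state$next_lineage_id <- imm$next_lineage_id
  rownames(state$pop) <- NULL
  state
}

# Landscape-wide trait/fitness summary of the settled generation at the
# current step, fitness evaluated at this step's realized attributes.
summarize_state <- function(state) {
  p <- state$params; land <- state$landscape
  tb <- p$G * patch_vector(land$t_base)
  hb <- p$G * patch_vector(land$h_base)
  eps_t <- if (state$t >= 1) state$eps[[state$t]] else 0
  fm <- fitness_metrics(state$pop, tb[state$patch + 1L] + eps_t,
                        hb[state$patch + 1L], p)
  vals <- cbind(state$pop[, c("Topt", "Ttol", "Hopt", "Htol",
                              "Pdisp", "Pglobal")], fm)
  out <- c(state$t, nrow(state$pop),
           as.vector(rbind(vapply(vals, mean, 0),
                           vapply(vals, stats::var, 0))))
  stats::setNames(as.data.frame(as.list(out)), summary_cols())
}

# Final-census table for the R reference engine (base and realized T;
# fitness metrics from the base attribute).
census_state <- function(state) {
  p <- state$params; land <- state$landscape
  tb <- p$G * patch_vector(land$t_base)
  hb <- p$G * patch_vector(land$h_base)
  eps_final <- if (state$t >= 1) state$eps[[state$t]] else 0
  tpb <- tb[state$patch + 1L]
  hp <- hb[state$patch + 1L]
  fm <- fitness_metrics(state$pop, tpb, hp, p)
  data.frame(
    x = state$patch %% land$width,
    y = state$patch %/% land$width,
    lineage_id = state$pop$lineage_id,
    state$pop[, c("Topt", "Ttol", "Hopt", "Htol", "Pdisp", "Pglobal")],
    Tpatch_base = tpb, Tpatch_realized = tpb + eps_final, Hpatch = hp,
    Efert_final = fm$Efert,
    prop_max_tradeoff = fm$prop_max_tradeoff,
    prop_max_R0 = fm$prop_max_R0,
    row.names = NULL
  )
}

#' Deterministic replicate seed
#'
#' Derives the RNG seed of one replicate from the experiment base seed,
#' the scenario index and the replicate index by a fixed
#' multiply-and-add hash modulo `2^31 - 1`, so every replicate of every
#' scenario gets a unique, preset seed and any single replicate can be
#' re-run bit-identically in isolation.
#'
#' @param base_seed Experiment-level integer seed.
#' @param scenario_index,replicate_index 1-based indices.
#' @return A single integer seed.
#' @export
replicate_seed <- function(base_seed, scenario_index = 1, replicate_index = 1) {
  h <- as.double(base_seed) %% 2147483647
  h <- (h * 48271 + as.double(scenario_index) * 69621 +
          as.double(replicate_index) * 16807) %% 2147483647
  as.integer(h)
}

#' Run one simulation replicate
#'
#' Seeds the RNG, generates (or takes) the landscape, pre-generates the
#' global fluctuation series, and runs the annual cycle for
#' `params$tmax` steps starting from an empty landscape colonized by
#' immigrants. Returns per-step landscape-wide summaries and the final
#' individual census.
#'
#' @param params A [sim_params()] object.
#' @param base_seed Experiment base seed; the replicate's own seed is
#'   derived via [replicate_seed()].
#' @param scenario_index,replicate_index 1-based indices identifying
#'   the run within an experiment grid.
#' @param landscape Optional pre-built [make_landscape()] object (e.g.
#'   from [read_landscape_file()]); its `G` is overridden by
#'   `params$G`. If `NULL`, a landscape is generated from the
#'   replicate's RNG stream.
#' @param record_summaries Record per-step summaries (disable to save
#'   memory on long runs).
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; identical cycle, practical only at small scale).
#' @return A list of class `"sim_result"` with elements `census`
#'   (data.frame, one row per individual alive at `tmax`, including
#'   `scenario`, `replicate`, patch coordinates and attributes, traits
#'   and fitness metrics), `summaries` (data.frame, one row per step),
#'   `landscape`, `seed`, and `params`.
#' @examples
#' p <- sim_params(tmax = 50, width = 8, height = 8)
#' r <- run_replicate(p, base_seed = 1)
#' nrow(r$census) > 0
#' @export
run_replicate <- function(params, base_seed, scenario_index = 1,
                          replicate_index = 1, landscape = NULL,
                          record_summaries = TRUE,
                          engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  seed <- replicate_seed(base_seed, scenario_index, replicate_index)
  set.seed(seed)
  if (is.null(landscape)) {
    landscape <- make_landscape(params$width, params$height, params$hurst,
                                G = params$G)
  } else {
    stopifnot(inherits(landscape, "landscape"))
    landscape$G <- params$G
  }
  eps <- generate_fluctuations(params$tmax)

  if (engine == "cpp") {
    res <- .run_sim_cpp(unclass(landscape$t_base), unclass(landscape$h_base),
                        params$G, eps, params$tmax,
                        params$R0, params$alpha, params$K, params$Eimmi,
                        params$Ttrend, params$niche_denominator_factor,
                        record_summaries, 1L)
    census <- stats::setNames(as.data.frame(res$census), census_cols())
    census$lineage_id <- as.integer(census$lineage_id)
    census$x <- as.integer(census$x)
    census$y <- as.integer(census$y)
    summaries <- stats::setNames(as.data.frame(res$summaries), summary_cols())
  } else {
    state <- new_sim_state(landscape, params, eps)
    summaries <- vector("list", params$tmax)
    for (t in seq_len(params$tmax)) {
      state <- step(state)
      if (record_summaries) summaries[[t]] <- summarize_state(state)
    }
    summaries <- if (record_summaries) do.call(rbind, summaries)
                 else stats::setNames(as.data.frame(
                        matrix(numeric(0), 0, 20)), summary_cols())
    census <- census_state(state)
  }
  scen <- scenario_id(params$G, params$hurst)
  census <- cbind(scenario = scen, replicate = replicate_index, census)
  if (nrow(summaries)) summaries <- cbind(scenario = scen,
                                          replicate = replicate_index,
                                          summaries)
  structure(list(census = census, summaries = summaries,
                 landscape = landscape, seed = seed, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation replicate (%s, replicate %s): %d individuals at tmax = %d\n",
              x$census$scenario[1] %||% "?", x$census$replicate[1] %||% "?",
              nrow(x$census), x$params$tmax))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Scenario identifier string
#'
#' @param G,hurst Scenario parameters.
#' @return Character id like `"G1_H0"`.
#' @export
scenario_id <- function(G, hurst) sprintf("G%g_H%g", G, hurst)

#' Per-patch aggregation of a census
#'
#' Mean trait values and fitness per occupied patch, the patch-level
#' view of adaptation. Patch means weighted by patch population
#' reproduce the landscape-wide individual means exactly.
#'
#' @param census A census table from [run_replicate()] /
#'   [run_experiment()].
#' @return A data.frame with one row per (scenario, replicate, x, y)
#'   and columns `n` plus the per-patch means of traits and fitness.
#' @export
aggregate_patches <- function(census) {
  need <- c("scenario", "replicate", "x", "y")
  if (!all(need %in% names(census)))
    stop("census lacks columns: ",
         paste(setdiff(need, names(census)), collapse = ", "), call. = FALSE)
  num <- c("Topt", "Ttol", "Hopt", "Htol", "Pdisp", "Pglobal",
           "Tpatch_base", "Hpatch", "Efert_final",
           "prop_max_tradeoff", "prop_max_R0")
  num <- intersect(num, names(census))
  key <- interaction(census$scenario, census$replicate, census$x, census$y,
                     drop = TRUE)
  first <- !duplicated(key)
  out <- census[first, need, drop = FALSE]
  out$n <- as.vector(table(key)[as.character(key[first])])
  for (v in num)
    out[[paste0("mean_", v)]] <-
      tapply(census[[v]], key, mean)[as.character(key[first])]
  rownames(out) <- NULL
  out[order(out$scenario, out$replicate, out$y, out$x), , drop = FALSE]
}

#' Run a full scenario-grid experiment
#'
#' Runs every combination of the `G` and `hurst` grids for the given
#' number of replicates, with deterministic per-replicate seeds derived
#' from `base_seed`. Optionally writes one directory per scenario
#' containing `census.csv`, `summaries.csv` and `patches.csv`, plus a
#' top-level `manifest.json` echoing the configuration and seeds.
#'
#' @param config A list (see [read_run_config()]) with elements
#'   `G` (numeric vector), `hurst` (numeric vector), `replicates`,
#'   `base_seed`, optional parameter overrides (`R0`, `alpha`, `K`,
#'   `Eimmi`, `tmax`, `Ttrend`, `width`, `height`), optional `out_dir`
#'   and optional `landscape_files` (one path per replicate, reused
#'   across scenarios).
#' @param progress Print one line per completed replicate.
#' @return Invisibly, a list with `census` (all scenarios bound
#'   together), `summaries`, `patches`, `failures` (character vector of
#'   failed replicate labels) and `manifest`.
#' @export
run_experiment <- function(config, progress = interactive()) {
  config <- validate_run_config(config)
  grid <- expand.grid(G = config$G, hurst = config$hurst,
                      KEEP.OUT.ATTRS = FALSE)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  all_census <- list(); all_summ <- list(); all_patch <- list()
  failures <- character(0)
  seeds <- list()

  for (s in seq_len(nrow(grid))) {
    params <- sim_params(
      R0 = config$R0, alpha = config$alpha, K = config$K,
      Eimmi = config$Eimmi, G = grid$G[s], hurst = grid$hurst[s],
      tmax = config$tmax, Ttrend = config$Ttrend,
      width = config$width, height = config$height
    )
    scen <- scenario_id(params$G, params$hurst)
    scen_census <- list(); scen_summ <- list()
    for (r in seq_len(config$replicates)) {
      label <- sprintf("%s/replicate%d", scen, r)
      seeds[[label]] <- replicate_seed(config$base_seed, s, r)
      land <- NULL
      if (!is.null(config$landscape_files))
        land <- read_landscape_file(config$landscape_files[[r]])
      res <- tryCatch(
        run_replicate(params, config$base_seed, s, r, landscape = land),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warning(sprintf("replicate %s failed: %s", label,
                        conditionMessage(res)), call. = FALSE)
        failures <- c(failures, label)
        next
      }
      if (nrow(res$census) == 0)
        warning(sprintf("replicate %s: landscape-wide extinction at tmax",
                        label), call. = FALSE)
      scen_census[[r]] <- res$census
      scen_summ[[r]] <- res$summaries
      if (progress)
        message(sprintf("done %s (%d individuals)", label, nrow(res$census)))
    }
    census <- do.call(rbind, scen_census)
    summ <- do.call(rbind, scen_summ)
    patches <- if (!is.null(census) && nrow(census)) aggregate_patches(census)
               else NULL
    if (!is.null(out_dir) && !is.null(census)) {
      sd <- file.path(out_dir, scen)
      dir.create(sd, showWarnings = FALSE)
      utils::write.csv(census, file.path(sd, "census.csv"), row.names = FALSE)
      utils::write.csv(summ, file.path(sd, "summaries.csv"),
                       row.names = FALSE)
      if (!is.null(patches))
        utils::write.csv(patches, file.path(sd, "patches.csv"),
                         row.names = FALSE)
    }
    all_census[[scen]] <- census
    all_summ[[scen]] <- summ
    all_patch[[scen]] <- patches
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nichescape")),
    config = config[setdiff(names(config), "out_dir")],
    scenarios = nrow(grid), seeds = seeds, failures = failures,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(census = do.call(rbind, unname(all_census)),
                 summaries = do.call(rbind, unname(all_summ)),
                 patches = do.call(rbind, unname(all_patch)),
                 failures = failures, manifest = manifest))
}
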