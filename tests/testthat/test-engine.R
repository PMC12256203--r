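tiny_params <- function(...) sim_params(width = 4, height = 4, tmax = 20, ...)

test_that("an empty landscape with no immigration stays empty", {
  p <- tiny_params(Eimmi = 0)
  set.seed(1)
  st <- new_sim_state(make_landscape(4, 4, 0, 1), p)
  for (i in 1:10) st <- step(st)
  expect_identical(nrow(st$pop), 0L)
  expect_identical(st$t, 10L)
})

test_that("each individual occupies exactly one in-bounds patch after a step", {
  p <- tiny_params()
  set.seed(2)
  st <- new_sim_state(make_landscape(4, 4, 0, p$G), p)
  for (i in 1:8) {
    st <- step(st)
    expect_identical(length(st$patch), nrow(st$pop))
    expect_true(all(st$patch >= 0 & st$patch < 16))
  }
})

test_that("with sessile genotypes and no immigration, occupancy never grows", {
  p <- tiny_params(Eimmi = 0, G = 0)
  set.seed(3)
  land <- make_landscape(4, 4, 0, 0)
  st <- new_sim_state(land, p)
  st$pop <- perfect_organisms(60, Ttol = 5, Htol = 5)
  st$patch <- rep(c(0L, 5L), 30)
  occupied <- function(s) sort(unique(s$patch))
  prev <- occupied(st)
  for (i in 1:15) {
    st <- step(st)
    now <- occupied(st)
    expect_true(all(now %in% prev))
    prev <- now
  }
})

test_that("a closed, perfectly adapted population fluctuates around K", {
  p <- sim_params(width = 2, height = 2, G = 0, Eimmi = 0, tmax = 1000)
  set.seed(4)
  land <- make_landscape(2, 2, 0, G = 0)
  st <- new_sim_state(land, p, fluctuations = rep(0, 1000))
  st$pop <- perfect_organisms(150)
  st$patch <- rep(0L, 150)
  sizes <- numeric(1000)
  for (t in 1:1000) {
    st <- step(st)
    sizes[t] <- nrow(st$pop)
  }
  expect_lt(abs(mean(sizes) - 150) / 150, 0.10)
  expect_true(all(sizes > 0))
})

test_that("replicate runs are bit-identical under the same seed", {
  p <- sim_params(width = 8, height = 8, tmax = 60, G = 1)
  r1 <- run_replicate(p, base_seed = 7, engine = "cpp")
  r2 <- run_replicate(p, base_seed = 7, engine = "cpp")
  expect_identical(r1$census, r2$census)
  expect_identical(r1$summaries, r2$summaries)
  r3 <- run_replicate(p, base_seed = 7, engine = "R")
  r4 <- run_replicate(p, base_seed = 7, engine = "R")
  expect_identical(r3$census, r4$census)
  expect_false(identical(
    run_replicate(p, base_seed = 8, engine = "cpp")$census, r1$census))
})

test_that("replicate seeds are deterministic and distinct across the grid", {
  s <- outer(1:14, 1:30, function(a, b)
    mapply(replicate_seed, 123, a, b))
  expect_identical(anyDuplicated(as.vector(s)), 0L)
  expect_identical(replicate_seed(123, 3, 7), replicate_seed(123, 3, 7))
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("population respects the Beverton-Holt ceiling at study scale", {
  p <- sim_params(tmax = 500, G = 1, hurst = 0)
  r <- run_replicate(p, base_seed = 11)
  expect_gt(nrow(r$census), 0)
  expect_lte(nrow(r$census), 400 * 150 * 15 / 14)
  expect_identical(nrow(r$summaries), 500L)
  expect_identical(r$summaries$population[500], as.numeric(nrow(r$census)))
})

test_that("compiled and R engines agree demographically", {
  pops <- sapply(c("cpp", "R"), function(eng) {
    p <- sim_params(width = 6, height = 6, tmax = 120, G = 0.3)
    mean(vapply(1:3, function(r)
      nrow(run_replicate(p, base_seed = 5, replicate_index = r,
                         engine = eng)$census), 0))
  })
  expect_gt(pops[["cpp"]] / pops[["R"]], 0.8)
  expect_lt(pops[["cpp"]] / pops[["R"]], 1.25)
})

test_that("fitness metrics expose both proportion-of-maximum scales", {
  p <- sim_params()
  org <- organisms(1L, Topt = 1, Ttol = 2, Hopt = -1, Htol = 0.5,
                   Pdisp = 0, Pglobal = 0)
  fm <- fitness_metrics(org, 1, -1, p)          # zero mismatch
  expect_equal(fm$prop_max_tradeoff, 1)
  org2 <- organisms(1L, 0, 3, 0, 3, 0, 0)
  fm2 <- fitness_metrics(org2, 0, 0, p)
  expect_equal(fm2$prop_max_R0, exp(-1), tolerance = 1e-12)
  set.seed(6)
  n <- 100
  orgs <- organisms(1:n, rnorm(n), rlnorm(n), rnorm(n), rlnorm(n),
                    runif(n), runif(n))
  fmr <- fitness_metrics(orgs, rnorm(n), rnorm(n), p)
  expect_true(all(fmr$prop_max_tradeoff >= fmr$prop_max_R0 - 1e-12))
  expect_true(all(fmr$prop_max_tradeoff <= 1 + 1e-12))
})

test_that("patch aggregation reproduces landscape means when weighted", {
  p <- sim_params(width = 8, height = 8, tmax = 80, G = 1)
  r <- run_replicate(p, base_seed = 9)
  agg <- aggregate_patches(r$census)
  expect_equal(sum(agg$n), nrow(r$census))
  for (v in c("Topt", "Pdisp", "Efert_final"))
    expect_equal(sum(agg[[paste0("mean_", v)]] * agg$n) / sum(agg$n),
                 mean(r$census[[v]]), tolerance = 1e-9)
  expect_error(aggregate_patches(r$census[, -(1:2)]), "lacks columns")
})

test_that("the census records consistent patch attributes", {
  p <- sim_params(width = 8, height = 8, tmax = 50, G = 0.7, hurst = 1)
  r <- run_replicate(p, base_seed = 3)
  land <- r$landscape
  idx <- cbind(r$census$y + 1, r$census$x + 1)
  expect_equal(r$census$Tpatch_base, 0.7 * land$t_base[idx])
  expect_equal(r$census$Hpatch, 0.7 * land$h_base[idx])
  # realized - base is one global constant: the final fluctuation
  eps_gap <- r$census$Tpatch_realized - r$census$Tpatch_base
  expect_lt(diff(range(eps_gap)), 1e-12)
  fm <- fitness_metrics(r$census, r$census$Tpatch_base, r$census$Hpatch, p)
  expect_equal(r$census$Efert_final, fm$Efert, tolerance = 1e-12)
})

test_that("run_experiment writes a reproducible scenario grid", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(G = c(0.1, 1), hurst = c(0, 1), replicates = 2,
                 tmax = 40, width = 6, height = 6, base_seed = 42)
  r1 <- run_experiment(c(config, list(out_dir = out1)), progress = FALSE)
  r2 <- run_experiment(c(config, list(out_dir = out2)), progress = FALSE)
  expect_identical(r1$census, r2$census)
  expect_length(r1$failures, 0)
  dirs <- list.dirs(out1, recursive = FALSE, full.names = FALSE)
  expect_setequal(dirs, c("G0.1_H0", "G0.1_H1", "G1_H0", "G1_H1"))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  census <- utils::read.csv(file.path(out1, "G1_H0", "census.csv"))
  expect_identical(nrow(census),
                   sum(r1$census$scenario == "G1_H0"))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(length(manifest$seeds), 8L)
  expect_identical(manifest$config$base_seed, 42L)
})

test_that("configuration validation guards the scenario grid", {
  expect_error(validate_run_config(list(base_seed = 1, bogus = 2)),
               "unknown configuration keys: bogus")
  expect_error(validate_run_config(list(G = 1)), "base_seed")
  cfg <- validate_run_config(list(base_seed = 5))
  expect_identical(length(cfg$G) * length(cfg$hurst), 14L)
  expect_identical(cfg$replicates, 30L)
  expect_identical(cfg$tmax, 10000L)
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("base_seed: 9", "G: [0.05, 1]", "hurst: [0]",
               "replicates: 2", "tmax: 100"), tf)
  cfg2 <- read_run_config(tf)
  expect_identical(cfg2$G, c(0.05, 1))
  expect_identical(cfg2$replicates, 2L)
})

test_that("experiments can start from landscape files", {
  dir <- withr::local_tempdir()
  files <- vapply(1:2, function(r) {
    set.seed(100 + r)
    f <- file.path(dir, sprintf("land%d.txt", r))
    write_landscape_file(make_landscape(6, 6, 1, G = 1), f)
    f
  }, "")
  config <- list(G = 0.5, hurst = 1, replicates = 2, tmax = 30,
                 width = 6, height = 6, base_seed = 13,
                 landscape_files = files)
  res <- run_experiment(config, progress = FALSE)
  expect_length(res$failures, 0)
  # the same file serves a different G scenario: attributes rescale
  land <- read_landscape_file(files[1])
  cen1 <- res$census[res$census$replicate == 1, ]
  idx <- cbind(cen1$y + 1, cen1$x + 1)
  expect_equal(cen1$Hpatch, 0.5 * land$h_base[idx])
})
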