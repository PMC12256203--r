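p_default <- sim_params()

one_org <- function(Topt = 0, Ttol = 1, Hopt = 0, Htol = 1,
                    Pdisp = 0.5, Pglobal = 0.5)
  organisms(1L, Topt, Ttol, Hopt, Htol, Pdisp, Pglobal)

test_that("organism construction enforces trait domains", {
  expect_error(one_org(Ttol = 0), "strictly positive")
  expect_error(one_org(Htol = -1), "strictly positive")
  expect_error(one_org(Pdisp = 1.2), "\\[0, 1\\]")
  expect_error(validate_organisms(data.frame(lineage_id = 1)), "missing")
})

test_that("fertility reaches R0 in the zero-mismatch, vanishing-tolerance limit", {
  ef <- fertility(one_org(Ttol = 1e-6, Htol = 1e-6), 0, 0, p_default)
  expect_lt(abs(ef - 15) / 15, 1e-9)
})

test_that("fertility at tolerances equal to alpha gives R0/e (hand oracle)", {
  # mismatch terms = 1; each trade-off factor = exp(-9/18), product e^-1
  ef <- fertility(one_org(Ttol = 3, Htol = 3), 0, 0, p_default)
  expect_equal(ef, 15 * exp(-1), tolerance = 1e-12)
  expect_equal(ef, 5.5182, tolerance = 1e-4)
})

test_that("fertility decreases strictly with niche mismatch and is bounded", {
  mis <- seq(0, 5, length.out = 100)
  org <- one_org(Ttol = 2, Htol = 1.5)
  ef <- vapply(mis, function(m) fertility(org, m, 0, p_default), 0)
  expect_true(all(diff(ef) < 0))
  set.seed(4)
  for (i in 1:50) {
    o <- one_org(Topt = rnorm(1), Ttol = rlnorm(1),
                 Hopt = rnorm(1), Htol = rlnorm(1))
    bound <- 15 * exp(-(o$Ttol^2 + o$Htol^2) / 18)
    expect_lte(fertility(o, rnorm(1), rnorm(1), p_default), bound + 1e-12)
  }
  bad <- one_org(); bad$Ttol <- 0
  expect_error(fertility(bad, 0, 0, p_default), "strictly positive")
})

test_that("the mismatch-denominator switch widens the niche", {
  p2 <- sim_params(niche_denominator_factor = 2)
  o <- one_org(Ttol = 1, Htol = 1)
  expect_equal(fertility(o, 1, 0, p2),
               15 * exp(-1 / 2) * exp(-2 / 18), tolerance = 1e-12)
  expect_gt(fertility(o, 1, 0, p2), fertility(o, 1, 0, p_default))
})

test_that("compiled and R fertility agree on random inputs", {
  set.seed(17)
  n <- 200
  org <- organisms(seq_len(n), Topt = rnorm(n), Ttol = rlnorm(n),
                   Hopt = rnorm(n), Htol = rlnorm(n),
                   Pdisp = runif(n), Pglobal = runif(n))
  Tp <- rnorm(n); Hp <- rnorm(n)
  for (k in c(1, 2)) {
    p <- sim_params(niche_denominator_factor = k)
    expect_equal(
      fertility(org, Tp, Hp, p),
      nichescape:::.fertility_cpp(Tp, Hp, org$Topt, org$Ttol, org$Hopt,
                                  org$Htol, p$R0, p$alpha, k),
      tolerance = 1e-14)
  }
})

test_that("reproduction is clonal with Poisson offspring numbers", {
  expect_identical(nrow(reproduce(one_org()[0, ], 0, 0, p_default)), 0L)
  n <- 1e5
  parents <- organisms(seq_len(n), Topt = 0, Ttol = 3, Hopt = 0, Htol = 3,
                       Pdisp = 0.5, Pglobal = 0.5)
  set.seed(6)
  off <- reproduce(parents, 0, 0, p_default)  # Efert = 15/e ~ 5.5182
  expect_lt(abs(nrow(off) / n - 15 * exp(-1)), 0.03)
  expect_true(all(off$Ttol == 3 & off$Topt == 0))
  one <- one_org(Topt = 0.42, Ttol = 2)
  kids <- reproduce(one, 0.42, 0, p_default)
  expect_true(all(kids$Topt == 0.42 & kids$Ttol == 2 &
                    kids$lineage_id == one$lineage_id))
})

test_that("Beverton-Holt survival matches the closed form", {
  expect_equal(bh_survival_prob(0, p_default), 1)
  # a = (R0-1)/(K*R0) = 14/2250
  expect_equal(nichescape:::bh_a(p_default), 14 / 2250)
  expect_equal(nichescape:::bh_a(p_default), 0.0062222, tolerance = 1e-5)
  # expected survivors at L0 = R0*K is exactly K
  expect_equal(2250 * bh_survival_prob(2250, p_default), 150)
  expect_error(bh_survival_prob(-1, p_default), "non-negative")
  # L0*SA strictly increasing with asymptote K*R0/(R0-1)
  L0 <- c(10, 100, 1000, 10000, 1e6, 1e8)
  surv <- L0 * bh_survival_prob(L0, p_default)
  expect_true(all(diff(surv) > 0))
  expect_true(all(surv < 150 * 15 / 14))
})

test_that("competition survivor counts are binomial and trait-blind", {
  expect_identical(nrow(compete(one_org()[0, ], p_default)), 0L)
  pool <- organisms(rep(1L, 2250), Topt = 0, Ttol = 1, Hopt = 0, Htol = 1,
                    Pdisp = 0, Pglobal = 0)
  set.seed(9)
  survivors <- vapply(1:2000, function(i) nrow(compete(pool, p_default)), 0)
  expect_lt(abs(mean(survivors) - 150), 1)

  # two lineages at equal frequency survive at equal rates
  pool2 <- pool
  pool2$lineage_id <- rep(c(1L, 2L), 1125)
  pool2$Ttol <- ifelse(pool2$lineage_id == 1, 0.5, 5)  # traits must not matter
  set.seed(10)
  tallies <- colSums(vapply(1:400, function(i) {
    s <- compete(pool2, p_default)
    c(sum(s$lineage_id == 1), sum(s$lineage_id == 2))
  }, c(0, 0)))
  expect_gt(stats::chisq.test(tallies)$p.value, 1e-3)
})

test_that("dispersal decisions follow the two-draw probabilities", {
  stay <- decide_dispersal(organisms(1:100, 0, 1, 0, 1, Pdisp = 0,
                                     Pglobal = runif(100)))
  expect_true(all(stay == "stay"))
  glob <- decide_dispersal(organisms(1:100, 0, 1, 0, 1, Pdisp = 1,
                                     Pglobal = 1))
  expect_true(all(glob == "global"))
  n <- 1e5
  org <- organisms(seq_len(n), 0, 1, 0, 1, Pdisp = 0.6, Pglobal = 0.25)
  set.seed(12)
  mode <- decide_dispersal(org)
  freq <- table(factor(mode, c("stay", "neighbor", "global"))) / n
  expect_lt(abs(freq[["stay"]] - 0.40), 0.01)
  expect_lt(abs(freq[["neighbor"]] - 0.45), 0.01)
  expect_lt(abs(freq[["global"]] - 0.15), 0.01)
})

test_that("dispersal mode frequencies match closed form over a trait grid", {
  set.seed(14)
  n <- 2e4
  for (pd in c(0.2, 0.8)) for (pg in c(0.1, 0.9)) {
    mode <- decide_dispersal(organisms(seq_len(n), 0, 1, 0, 1, pd, pg))
    freq <- table(factor(mode, c("stay", "neighbor", "global"))) / n
    probs <- c(1 - pd, pd * (1 - pg), pd * pg)
    ci <- 2.58 * sqrt(probs * (1 - probs) / n)  # binomial 99% CI
    expect_true(all(abs(as.numeric(freq) - probs) <= ci + 1e-3))
  }
})

test_that("neighbour dispersal is uniform over the Moore ring with torus wrap", {
  set.seed(15)
  n <- 1e5
  tg <- neighbor_target(rep(0L, n), rep(0L, n), 20, 20)
  support <- sort(unique(paste(tg$x, tg$y)))
  exp_support <- expand.grid(x = c(19, 0, 1), y = c(19, 0, 1))
  exp_support <- exp_support[!(exp_support$x == 0 & exp_support$y == 0), ]
  expect_setequal(support, sort(paste(exp_support$x, exp_support$y)))
  freq <- table(paste(tg$x, tg$y)) / n
  expect_true(all(abs(freq - 0.125) < 0.01))

  tg2 <- neighbor_target(rep(19L, 500), rep(19L, 500), 20, 20)
  hits <- unique(paste(tg2$x, tg2$y))
  expect_true(all(c("0 0", "0 19", "19 0") %in% hits))
})

test_that("global dispersal is uniform over all non-natal patches", {
  set.seed(16)
  n <- 1e6
  tg <- global_target(rep(3L, n), rep(5L, n), 20, 20)
  idx <- tg$y * 20 + tg$x
  expect_false(any(idx == 5 * 20 + 3))
  counts <- tabulate(idx + 1, 400)
  expect_identical(sum(counts > 0), 399L)
  expect_gt(stats::chisq.test(counts[-(5 * 20 + 3 + 1)])$p.value, 1e-4)
  expect_error(global_target(0L, 0L, 1, 1), "1x1")
})

test_that("immigrant traits follow the prescribed distributions", {
  p0 <- sim_params(G = 0, Ttrend = 0.7)
  set.seed(18)
  imm0 <- draw_immigrant(p0, 1L, n = 100)
  expect_true(all(imm0$Topt == 0.7))
  expect_true(all(imm0$Hopt == 0))

  p1 <- sim_params(G = 1)
  set.seed(19)
  imm <- draw_immigrant(p1, 1L, n = 1e5)
  expect_lt(abs(median(imm$Ttol) - 1), 0.02)   # log-normal median e^0
  expect_lt(abs(mean(imm$Pdisp) - 0.5), 0.005)
  expect_identical(imm$lineage_id, 1L:100000L)
  expect_identical(anyDuplicated(imm$lineage_id), 0L)
})

test_that("immigration is patch-wise Poisson with fresh lineages", {
  land <- make_landscape(20, 20, 0, G = 1)
  p0 <- sim_params(Eimmi = 0)
  expect_identical(nrow(immigrate(land, p0, 1L)$org), 0L)

  p <- sim_params()
  set.seed(20)
  total <- 0; ids <- integer(0); next_id <- 1L
  for (t in 1:200) {
    im <- immigrate(land, p, next_id)
    total <- total + nrow(im$org)
    next_id <- im$next_lineage_id
    if (t <= 5) ids <- c(ids, im$org$lineage_id)
  }
  expect_lt(abs(total / (400 * 200) - 2.5), 0.02)
  expect_identical(anyDuplicated(ids), 0L)
})
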