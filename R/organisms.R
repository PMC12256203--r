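#' Construct a table of organisms
#'
#' Organisms are clonal: a lineage is founded by a single immigrant and
#' all descendants carry identical trait values. An organism table has
#' one row per individual with columns `lineage_id`, the four niche
#' traits (`Topt`, `Ttol`, `Hopt`, `Htol`) and the two dispersal traits
#' (`Pdisp`, `Pglobal`). Tolerances must be strictly positive
#' (log-normal support); dispersal traits lie in the unit interval.
#'
#' @param lineage_id Integer lineage identifiers.
#' @param Topt,Ttol,Hopt,Htol Niche optimum and tolerance for the
#'   temperature and habitat attribute.
#' @param Pdisp Probability of dispersing from the natal patch, in
#'   `[0, 1]`.
#' @param Pglobal Conditional preference, given dispersal, for random
#'   global over nearest-neighbour dispersal, in `[0, 1]`.
#' @return A data.frame with one row per organism.
#' @export
organisms <- function(lineage_id, Topt, Ttol, Hopt, Htol, Pdisp, Pglobal) {
  out <- data.frame(lineage_id = as.integer(lineage_id),
                    Topt = Topt, Ttol = Ttol, Hopt = Hopt, Htol = Htol,
                    Pdisp = Pdisp, Pglobal = Pglobal)
  validate_organisms(out)
  out
}

validate_organisms <- function(org) {
  stopifnot(is.data.frame(org))
  missing <- setdiff(organism_trait_cols(), names(org))
  if (length(missing))
    stop("organism table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(org$Ttol <= 0) || any(org$Htol <= 0))
    stop("tolerances must be strictly positive", call. = FALSE)
  if (any(org$Pdisp < 0 | org$Pdisp > 1) ||
      any(org$Pglobal < 0 | org$Pglobal > 1))
    stop("dispersal traits must lie in [0, 1]", call. = FALSE)
  invisible(org)
}

organism_trait_cols <- function()
  c("lineage_id", "Topt", "Ttol", "Hopt", "Htol", "Pdisp", "Pglobal")

#' Expected fecundity under the Gaussian niche with trade-off
#'
#' The expected number of offspring of an organism in a patch with
#' realized attributes `Tpatch`, `Hpatch` is
#' \deqn{E_{fert} = R_0 \,
#'   e^{-(T_{patch}-T_{opt})^2 / T_{tol}^2}\,
#'   e^{-(H_{patch}-H_{opt})^2 / H_{tol}^2}\,
#'   e^{-T_{tol}^2 / 2\alpha^2}\, e^{-H_{tol}^2 / 2\alpha^2}}
#' The two mismatch factors are Gaussian in the distance between patch
#' attribute and niche optimum, with width set by the tolerance traits;
#' the two trade-off factors penalise broad tolerances, so fecundity
#' under perfect conditions falls below `R0` as tolerances grow. The
#' mismatch denominator is `Ttol^2` (respectively `Htol^2`); setting
#' `niche_denominator_factor = 2` in [sim_params()] switches both
#' mismatch terms to `2 * tol^2`.
#'
#' @param org An organism table (vectorized over rows).
#' @param Tpatch,Hpatch Realized patch attribute values (scalar or one
#'   per organism).
#' @param params A [sim_params()] object.
#' @return Numeric vector of expected offspring, in `(0, R0]`.
#' @examples
#' p <- sim_params()
#' o <- organisms(1L, Topt = 0, Ttol = 3, Hopt = 0, Htol = 3,
#'                Pdisp = 0.5, Pglobal = 0.5)
#' fertility(o, Tpatch = 0, Hpatch = 0, p)  # 15 * exp(-1)
#' @export
fertility <- function(org, Tpatch, Hpatch, params) {
  if (any(org$Ttol <= 0) || any(org$Htol <= 0))
    stop("tolerances must be strictly positive", call. = FALSE)
  k <- params$niche_denominator_factor
  a2 <- 2 * params$alpha^2
  params$R0 *
    exp(-(Tpatch - org$Topt)^2 / (k * org$Ttol^2)) *
    exp(-(Hpatch - org$Hopt)^2 / (k * org$Htol^2)) *
    exp(-org$Ttol^2 / a2) *
    exp(-org$Htol^2 / a2)
}

#' Fitness metrics for recorded individuals
#'
#' Computes, per organism, the expected offspring `Efert` together with
#' two proportion-of-maximum measures: `prop_max_tradeoff`, the
#' proportion of the maximum achievable given the organism's own
#' tolerances (i.e. the mismatch factors alone, ignoring the fecundity
#' lost to the tolerance trade-off), and `prop_max_R0`, the proportion
#' of the absolute maximum `R0`.
#'
#' @inheritParams fertility
#' @return A data.frame with columns `Efert`, `prop_max_tradeoff`,
#'   `prop_max_R0`.
#' @export
fitness_metrics <- function(org, Tpatch, Hpatch, params) {
  ef <- fertility(org, Tpatch, Hpatch, params)
  tradeoff <- exp(-(org$Ttol^2 + org$Htol^2) / (2 * params$alpha^2))
  data.frame(Efert = ef,
             prop_max_tradeoff = ef / (params$R0 * tradeoff),
             prop_max_R0 = ef / params$R0)
}

#' Clonal reproduction within a patch
#'
#' Each parent contributes `Poisson(Efert)` offspring with traits
#' identical to its own; the parent generation is then discarded
#' (annual life cycle, complete replacement).
#'
#' @param patch_occupants Organism table of the patch's adults.
#' @param Tpatch,Hpatch Realized patch attributes at the current step.
#' @param params A [sim_params()] object.
#' @return Organism table of offspring (possibly zero rows).
#' @export
reproduce <- function(patch_occupants, Tpatch, Hpatch, params) {
  n <- nrow(patch_occupants)
  if (n == 0) return(patch_occupants)
  ef <- fertility(patch_occupants, Tpatch, Hpatch, params)
  counts <- stats::rpois(n, ef)
  patch_occupants[rep.int(seq_len(n), counts), , drop = FALSE]
}

#' Beverton-Holt survival probability
#'
#' Density-dependent survival through the maturation/competition phase:
#' with `a = (R0 - 1) / (K * R0)`, the per-offspring survival
#' probability in a patch holding `L0` offspring is
#' `SA = 1 / (1 + a * L0)`. At `L0 = R0 * K` the expected number of
#' survivors `L0 * SA` equals exactly `K`, the patch carrying capacity
#' under perfect fitness.
#'
#' @param L0 Total offspring in the patch (non-negative; vectorized).
#' @param params A [sim_params()] object.
#' @return Survival probability in `(0, 1]`.
#' @examples
#' p <- sim_params()
#' 2250 * bh_survival_prob(2250, p)  # = K = 150
#' @export
bh_survival_prob <- function(L0, params) {
  if (any(L0 < 0)) stop("'L0' must be non-negative", call. = FALSE)
  1 / (1 + bh_a(params) * L0)
}

#' Density-dependent competition among offspring
#'
#' Survival is trait-blind: every offspring in the patch survives
#' independently with probability `SA = bh_survival_prob(L0)`, so the
#' survivor count is `Binomial(L0, SA)` and survivor identities are an
#' unbiased draw from the pool.
#'
#' @param offspring Organism table of the patch's offspring pool.
#' @param params A [sim_params()] object.
#' @return Organism table of survivors.
#' @export
compete <- function(offspring, params) {
  L0 <- nrow(offspring)
  if (L0 == 0) return(offspring)
  sa <- bh_survival_prob(L0, params)
  keep <- stats::runif(L0) <= sa
  offspring[keep, , drop = FALSE]
}

#' Dispersal decision
#'
#' Each organism disperses at most once per life cycle. Two independent
#' uniform draws decide the outcome: the first is compared (with `<=`)
#' against `Pdisp` to decide whether to leave the natal patch; for
#' dispersers, the second is compared against `Pglobal` to choose
#' random global dispersal over nearest-neighbour dispersal. The
#' resulting mode probabilities are `1 - Pdisp` (stay),
#' `Pdisp * (1 - Pglobal)` (neighbour) and `Pdisp * Pglobal` (global).
#'
#' @param org Organism table (vectorized over rows).
#' @return Character vector with elements `"stay"`, `"neighbor"` or
#'   `"global"`.
#' @export
decide_dispersal <- function(org) {
  n <- nrow(org)
  disperse <- stats::runif(n) <= org$Pdisp
  mode <- rep("stay", n)
  if (any(disperse)) {
    glob <- stats::runif(sum(disperse)) <= org$Pglobal[disperse]
    mode[disperse] <- ifelse(glob, "global", "neighbor")
  }
  mode
}

#' Dispersal targets on the torus
#'
#' `neighbor_target()` draws a uniform patch from the 8-cell Moore
#' neighbourhood of the natal patch: offsets `p, q` are each uniform on
#' `{-1, 0, 1}` and the pair `(0, 0)` is rejected and redrawn, so a
#' disperser never stays home. Coordinates wrap modulo the landscape
#' dimensions (toroidal edges). `global_target()` draws a uniform patch
#' among all `width * height - 1` non-natal patches, redrawing on the
#' natal patch.
#'
#' Coordinates are 0-based: `x` in `0:(width-1)`, `y` in
#' `0:(height-1)`. Both functions are vectorized over natal
#' coordinates.
#'
#' @param x,y Natal patch coordinates (0-based).
#' @param width,height Landscape dimensions.
#' @return A list with integer vectors `x` and `y` of target
#'   coordinates.
#' @export
neighbor_target <- function(x, y, width, height) {
  n <- length(x)
  stopifnot(length(y) == n, all(x >= 0 & x < width), all(y >= 0 & y < height))
  # uniform over the 8 non-(0,0) offset pairs: no rejection needed
  idx <- sample.int(8L, n, replace = TRUE)
  off <- rbind(c(-1L, -1L), c(0L, -1L), c(1L, -1L),
               c(-1L,  0L),             c(1L,  0L),
               c(-1L,  1L), c(0L,  1L), c(1L,  1L))
  list(x = (x + off[idx, 1L]) %% width,
       y = (y + off[idx, 2L]) %% height)
}

#' @rdname neighbor_target
#' @export
global_target <- function(x, y, width, height) {
  npatch <- width * height
  if (npatch < 2)
    stop("global dispersal is impossible on a 1x1 landscape", call. = FALSE)
  n <- length(x)
  stopifnot(length(y) == n, all(x >= 0 & x < width), all(y >= 0 & y < height))
  natal <- y * width + x
  # draw among the npatch-1 non-natal patches, skipping over the natal one
  draw <- floor(stats::runif(n) * (npatch - 1))
  target <- ifelse(draw >= natal, draw + 1, draw)
  list(x = as.integer(target %% width), y = as.integer(target %/% width))
}

#' Draw external immigrants
#'
#' `draw_immigrant()` generates `n` immigrants, each founding a fresh
#' lineage, with traits drawn from the immigrant distributions:
#' `Topt ~ Normal(Ttrend, G)`, `Hopt ~ Normal(0, G)`,
#' `Ttol, Htol ~ LogNormal(meanlog = 0, sdlog = 1)` and
#' `Pdisp, Pglobal ~ Uniform(0, 1)`. Optima therefore scale with the
#' compositional heterogeneity of the landscape, and the median
#' tolerance is 1.
#'
#' @param params A [sim_params()] object.
#' @param next_lineage_id First lineage id to assign; ids
#'   `next_lineage_id, next_lineage_id + 1, ...` are used in order.
#' @param n Number of immigrants to draw.
#' @return An organism table with `n` rows.
#' @export
draw_immigrant <- function(params, next_lineage_id, n = 1) {
  n <- as.integer(n)
  if (n == 0)
    return(organisms(integer(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), numeric(0)))
  data.frame(
    lineage_id = next_lineage_id + seq_len(n) - 1L,
    Topt = stats::rnorm(n, params$Ttrend, params$G),
    Ttol = stats::rlnorm(n, meanlog = 0, sdlog = 1),
    Hopt = stats::rnorm(n, 0, params$G),
    Htol = stats::rlnorm(n, meanlog = 0, sdlog = 1),
    Pdisp = stats::runif(n),
    Pglobal = stats::runif(n)
  )
}

#' External immigration into every patch
#'
#' Each patch independently receives `Poisson(Eimmi)` immigrants per
#' time step, each a fresh lineage placed in its generating patch.
#'
#' @param landscape A [make_landscape()] object.
#' @param params A [sim_params()] object.
#' @param next_lineage_id First lineage id to assign.
#' @return A list with `org` (organism table), `patch` (0-based patch
#'   index `y * width + x` per immigrant) and `next_lineage_id` (the
#'   counter after assignment).
#' @export
immigrate <- function(landscape, params, next_lineage_id) {
  npatch <- landscape$width * landscape$height
  counts <- stats::rpois(npatch, params$Eimmi)
  total <- sum(counts)
  org <- draw_immigrant(params, next_lineage_id, n = total)
  list(org = org,
       patch = rep.int(seq_len(npatch) - 1L, counts),
       next_lineage_id = next_lineage_id + total)
}
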