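#' Simulation parameters
#'
#' Construct and validate the parameter set controlling demography,
#' the niche trade-off, immigration and landscape scaling. Defaults are
#' the study conditions used throughout: an intrinsic maximum fecundity
#' `R0 = 15`, trade-off strength `alpha = 3`, patch carrying capacity
#' `K = 150`, expected immigration `Eimmi = 2.5` per patch and step, and
#' `tmax = 10000` time steps.
#'
#' @param R0 Intrinsic maximum expected offspring of a perfectly adapted
#'   organism with vanishing tolerances. Must exceed 1.
#' @param alpha Tolerance/fecundity trade-off strength; smaller values
#'   penalise broad tolerances more. Must be positive.
#' @param K Patch carrying capacity when all occupants realise `R0`.
#' @param Eimmi Expected number of external immigrants per patch per
#'   time step (Poisson intensity).
#' @param G Compositional-heterogeneity multiplier applied to the
#'   standardized patch attribute fields; `G >= 0`.
#' @param hurst Hurst index of the landscape in `[0, 1]`; 1 gives smooth,
#'   fully autocorrelated fields, 0 a largely random arrangement.
#' @param tmax Number of time steps in a replicate.
#' @param Ttrend Mean of the immigrant temperature-optimum distribution.
#'   Zero means no directional environmental trend.
#' @param width,height Landscape dimensions in patches.
#' @param niche_denominator_factor Either 1 or 2: the factor applied to
#'   the squared tolerance in the denominator of the Gaussian mismatch
#'   terms of the fertility equation. The default 1 matches the printed
#'   form of the model equation, which writes the trade-off exponent
#'   with an explicit 2 but the mismatch terms without one.
#'
#' @return A list of class `"sim_params"`.
#' @examples
#' p <- sim_params()
#' p$R0
#' @export
sim_params <- function(R0 = 15, alpha = 3, K = 150, Eimmi = 2.5,
                       G = 1, hurst = 0, tmax = 10000, Ttrend = 0,
                       width = 20, height = 20,
                       niche_denominator_factor = 1) {
  stopifnot(
    is.numeric(R0), length(R0) == 1, is.finite(R0), R0 > 1,
    is.numeric(alpha), length(alpha) == 1, alpha > 0,
    is.numeric(K), length(K) == 1, K >= 1,
    is.numeric(Eimmi), length(Eimmi) == 1, Eimmi >= 0,
    is.numeric(G), length(G) == 1, G >= 0,
    is.numeric(hurst), length(hurst) == 1,
    is.numeric(tmax), length(tmax) == 1, tmax >= 1,
    is.numeric(Ttrend), length(Ttrend) == 1, is.finite(Ttrend),
    width >= 2, height >= 2,
    niche_denominator_factor %in% c(1, 2)
  )
  if (!is.finite(hurst) || hurst < 0 || hurst > 1)
    stop("'hurst' must be a finite value in [0, 1]", call. = FALSE)
  structure(
    list(R0 = R0, alpha = alpha, K = as.integer(K), Eimmi = Eimmi,
         G = G, hurst = hurst, tmax = as.integer(tmax), Ttrend = Ttrend,
         width = as.integer(width), height = as.integer(height),
         niche_denominator_factor = niche_denominator_factor),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Beverton-Holt competition coefficient a = (R0 - 1) / (K * R0).
bh_a <- function(params) (params$R0 - 1) / (params$K * params$R0)
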