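#' Generate a periodic fractal random field
#'
#' Draws a spatially autocorrelated random field by Fourier spectral
#' synthesis of fractional Brownian motion: white Gaussian noise is
#' filtered in the frequency domain with amplitude `f^-(hurst + 1)`,
#' i.e. power spectrum `S(f) ~ f^-(2 * hurst + 2)`, and transformed
#' back. Because the synthesis is performed on the discrete Fourier
#' basis the field is inherently periodic: opposite edges connect
#' seamlessly and the landscape is a torus without edge effects.
#'
#' A Hurst index of 1 yields a completely spatially autocorrelated
#' (smooth) field; a Hurst index of 0 yields a largely random
#' arrangement at the scale of a small grid. The DC (zero-frequency)
#' component is removed before the inverse transform, so the raw field
#' has mean ~0 but arbitrary variance; use [standardize_field()] to
#' bring it to mean 0, SD 1.
#'
#' @param width,height Grid dimensions in patches (both `>= 2`). Any
#'   sizes are supported; powers of two are not required.
#' @param hurst Hurst index in `[0, 1]`.
#' @return A `height` x `width` numeric matrix (rows indexed by `y`,
#'   columns by `x`) of class `"field"`, unstandardized.
#' @details Randomness is taken from R's global RNG stream; call
#'   [set.seed()] for reproducible fields.
#' @examples
#' set.seed(1)
#' f <- generate_fractal_field(20, 20, hurst = 1)
#' dim(f)
#' @seealso [make_landscape()], [standardize_field()], [moran_i()]
#' @export
generate_fractal_field <- function(width, height, hurst) {
  if (length(hurst) != 1 || !is.finite(hurst) || hurst < 0 || hurst > 1)
    stop("'hurst' must be a single finite value in [0, 1]", call. = FALSE)
  stopifnot(width >= 2, height >= 2)
  width <- as.integer(width); height <- as.integer(height)

  # Torus frequencies: index k on an n-grid has frequency min(k, n-k)/n.
  fx <- pmin(0:(width - 1), width - (0:(width - 1))) / width
  fy <- pmin(0:(height - 1), height - (0:(height - 1))) / height
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- ifelse(f > 0, f^(-(hurst + 1)), 0)  # zero the DC component

  noise <- matrix(stats::rnorm(width * height), nrow = height, ncol = width)
  spec <- stats::fft(noise) * amp
  field <- Re(stats::fft(spec, inverse = TRUE)) / (width * height)
  structure(field, class = c("field", class(field)))
}

#' Standardize a field to mean 0 and standard deviation 1
#'
#' Applies the affine transform `(x - mean) / sd` elementwise, using the
#' population standard deviation (divisor `n`). Standardization keeps
#' the frequency distribution of patch values constant across spatial
#' configurations, so the heterogeneity multiplier `G` alone controls
#' the magnitude of spatial variation.
#'
#' @param field A numeric matrix with non-zero variance.
#' @return The standardized matrix (class `"field"`).
#' @export
standardize_field <- function(field) {
  stopifnot(is.numeric(field), all(is.finite(field)))
  n <- length(field)
  if (n < 4) stop("field must contain at least 4 patches", call. = FALSE)
  mu <- mean(field)
  sdev <- sqrt(sum((field - mu)^2) / n)
  if (sdev == 0)
    stop("cannot standardize a constant field (zero variance)", call. = FALSE)
  out <- (field - mu) / sdev
  structure(out, class = c("field", "matrix", "array"))
}

#' Generate a two-attribute toroidal landscape
#'
#' Builds the simulation arena: two independently generated,
#' standardized fractal fields sharing the same Hurst index — a
#' temperature-like attribute `T` that will fluctuate globally over
#' time, and a static habitat attribute `H` — plus the
#' compositional-heterogeneity multiplier `G`. `G` is stored
#' unapplied; scaling happens at attribute lookup ([patch_T()],
#' [patch_H()]) so one landscape serves every `G` scenario.
#'
#' @inheritParams generate_fractal_field
#' @param G Compositional-heterogeneity multiplier (`>= 0`).
#' @return An object of class `"landscape"`: a list with elements
#'   `t_base`, `h_base` (standardized `height` x `width` matrices),
#'   `G`, `hurst`, `width`, `height`.
#' @examples
#' set.seed(42)
#' land <- make_landscape(20, 20, hurst = 1, G = 1)
#' land$width * land$height  # 400 patches
#' @export
make_landscape <- function(width, height, hurst, G = 1) {
  stopifnot(G >= 0)
  t_base <- standardize_field(generate_fractal_field(width, height, hurst))
  h_base <- standardize_field(generate_fractal_field(width, height, hurst))
  structure(
    list(t_base = t_base, h_base = h_base, G = G, hurst = hurst,
         width = as.integer(width), height = as.integer(height)),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Toroidal landscape: %d x %d patches, hurst = %g, G = %g\n",
              x$width, x$height, x$hurst, x$G))
  invisible(x)
}

#' Patch attribute lookup
#'
#' `patch_T()` returns the realized temperature attribute of a patch at
#' time step `t`: the standardized base value scaled by `G` plus the
#' global fluctuation of that step, `G * That(x, y) + eps(t)`.
#' `patch_H()` returns the static habitat attribute `G * Hhat(x, y)`.
#' Coordinates are 0-based (`x` column, `y` row), matching the torus
#' arithmetic used by the dispersal operations.
#'
#' @param landscape A [make_landscape()] object.
#' @param x,y 0-based patch coordinates (vectorized).
#' @param fluctuations A [generate_fluctuations()] vector.
#' @param t Time step, `1 <= t <= length(fluctuations)`.
#' @return Numeric vector of attribute values.
#' @export
patch_T <- function(landscape, x, y, fluctuations, t) {
  if (length(t) != 1 || t < 1 || t > length(fluctuations))
    stop("time step 't' out of range of the fluctuation series", call. = FALSE)
  check_coords(landscape, x, y)
  landscape$G * landscape$t_base[cbind(y + 1, x + 1)] + fluctuations[[t]]
}

#' @rdname patch_T
#' @export
patch_H <- function(landscape, x, y) {
  check_coords(landscape, x, y)
  landscape$G * landscape$h_base[cbind(y + 1, x + 1)]
}

check_coords <- function(landscape, x, y) {
  if (any(x < 0 | x >= landscape$width | y < 0 | y >= landscape$height))
    stop("patch coordinates out of bounds", call. = FALSE)
  invisible(TRUE)
}

#' Generate the global temperature fluctuation series
#'
#' Fluctuations in the temperature attribute are global — every patch
#' in a landscape is shifted by the same amount in a given step — and
#' are drawn i.i.d. standard normal. The whole series is generated at
#' initialization and fixed for the run.
#'
#' @param tmax Number of time steps (`>= 1`).
#' @return Numeric vector of length `tmax`.
#' @export
generate_fluctuations <- function(tmax) {
  if (length(tmax) != 1 || !is.finite(tmax) || tmax < 1)
    stop("'tmax' must be a single integer >= 1", call. = FALSE)
  stats::rnorm(as.integer(tmax))
}

#' Moran's I spatial autocorrelation on a torus
#'
#' Computes Moran's I for a gridded field under rook (4-neighbour)
#' adjacency, optionally with wrap-around (toroidal) edges. Used as a
#' diagnostic: the spectral-synthesis fields have Moran's I increasing
#' with the Hurst index, and wrap vs. no-wrap values agree closely
#' because the fields are periodic by construction.
#'
#' @param field Numeric matrix.
#' @param wrap Use toroidal adjacency (default) or clipped edges.
#' @return Moran's I (scalar).
#' @export
moran_i <- function(field, wrap = TRUE) {
  z <- field - mean(field)
  n <- length(z)
  if (wrap) {
    shift <- function(m, dr, dc) {
      nr <- nrow(m); nc <- ncol(m)
      m[(seq_len(nr) - 1 + dr) %% nr + 1, (seq_len(nc) - 1 + dc) %% nc + 1]
    }
    num <- sum(z * (shift(z, 1, 0) + shift(z, -1, 0) +
                    shift(z, 0, 1) + shift(z, 0, -1)))
    s0 <- 4 * n
  } else {
    num <- 2 * (sum(z[-1, ] * z[-nrow(z), ]) + sum(z[, -1] * z[, -ncol(z)]))
    s0 <- 2 * ((nrow(z) - 1) * ncol(z) + nrow(z) * (ncol(z) - 1))
  }
  (n / s0) * num / sum(z^2)
}
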