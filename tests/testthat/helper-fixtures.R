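# Shared helpers: small synthetic fixtures and independent oracles.

# Synthetic census with explicit lineage sizes. `sizes` is a named list
# scenario -> vector of lineage sizes; traits are filled with simple
# reproducible values.
make_census <- function(sizes, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (scen in names(sizes)) {
    lin_sizes <- sizes[[scen]]
    for (i in seq_along(lin_sizes)) {
      n <- lin_sizes[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scen, replicate = 1L, lineage_id = i,
        x = sample(0:19, n, TRUE), y = sample(0:19, n, TRUE),
        Topt = rnorm(n), Ttol = rlnorm(n), Hopt = rnorm(n),
        Htol = rlnorm(n), Pdisp = runif(n), Pglobal = runif(n),
        Tpatch_base = rnorm(n), Tpatch_realized = rnorm(n),
        Hpatch = rnorm(n), Efert_final = runif(n, 0, 15),
        prop_max_tradeoff = runif(n), prop_max_R0 = runif(n)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Independent oracle for the fractal-field spectral exponent: fit the
# log-log slope of the radially averaged periodogram. For a field
# synthesized with power ~ f^-beta the fitted slope estimates -beta.
periodogram_slope <- function(fields) {
  n <- nrow(fields[[1]])
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) / n
  f <- sqrt(outer(fr^2, fr^2, `+`))
  pow <- Reduce(`+`, lapply(fields, function(x) Mod(stats::fft(x))^2)) /
    length(fields)
  keep <- f > 0 & f <= 0.5  # drop DC and the aliased corner
  lf <- log(f[keep]); lp <- log(pow[keep])
  bins <- cut(lf, breaks = 16)
  mlf <- tapply(lf, bins, mean); mlp <- tapply(lp, bins, mean)
  ok <- is.finite(mlf) & is.finite(mlp)
  unname(stats::coef(stats::lm(mlp[ok] ~ mlf[ok]))[2])
}

# A single perfectly-adapted, sessile organism type for closed-
# population demography tests.
perfect_organisms <- function(n, Ttol = 1e-6, Htol = 1e-6) {
  organisms(rep(1L, n), Topt = 0, Ttol = Ttol, Hopt = 0, Htol = Htol,
            Pdisp = 0, Pglobal = 0)
}
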