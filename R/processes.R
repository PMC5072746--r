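#' Gaussian white noise
#'
#' Independent standard-normal draws: the maximal-entropy anchor of the
#' causal information planes (`H` near 1, `C` and `F` near 0).
#'
#' @param n Length.
#' @param seed Integer seed; the generator is fully reproducible per seed.
#' @param step,step_unit Passed to [itq_series()].
#' @return An [itq_series].
#' @export
white_noise <- function(n, seed = 1L, step = 1, step_unit = "steps") {
  stopifnot(n >= 1)
  x <- local_rng(seed, stats::rnorm(n))
  itq_series(x, step = step, step_unit = step_unit)
}

# Run expr under a private RNG state so generators do not disturb the
# caller's random stream.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Colored (1/f^k) noise by spectral synthesis
#'
#' Gaussian noise with power spectrum proportional to `1/f^k`: a unit
#' amplitude spectrum is scaled by `f^(-k/2)`, given iid uniform phases, and
#' inverse-Fourier transformed; the zero-frequency component is set to 0 and
#' the result standardized to zero mean, unit variance. `k = 0` is white
#' noise; increasing `k` (up to 3) gives progressively stronger long-range
#' correlation, lower permutation entropy and intermediate complexity.
#'
#' @param n Length.
#' @param k Spectral exponent in `[0, 3]`.
#' @inheritParams white_noise
#' @return An [itq_series].
#' @export
k_noise <- function(n, k, seed = 1L, step = 1, step_unit = "steps") {
  stopifnot(n >= 2)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 3)
    stop("k must lie in [0, 3]")
  x <- local_rng(seed, {
    nf <- n %/% 2L
    f <- seq_len(nf) / n
    amp <- f^(-k / 2)
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full <- complex(real = numeric(n))
    full[2:(nf + 1L)] <- spec
    # Hermitian symmetry for a real signal
    if (n %% 2L == 0L) {
      full[nf + 1L] <- complex(real = amp[nf] * cos(phase[nf]))
      if (nf > 1L) full[n:(nf + 2L)] <- Conj(spec[1:(nf - 1L)])
    } else {
      full[n:(nf + 2L)] <- Conj(spec[1:(nf - 1L)])
      full[nf + 2L] <- Conj(spec[nf])
    }
    Re(stats::fft(full, inverse = TRUE)) / n
  })
  x <- (x - mean(x)) / stats::sd(x)
  itq_series(x, step = step, step_unit = step_unit)
}

#' Logistic map orbit
#'
#' Iterates `x[t+1] = r * x[t] * (1 - x[t])`. At `r = 4` the orbit is fully
#' chaotic: intermediate entropy with complexity close to the upper limit
#' curve, the canonical deterministic-chaos reference. A transient of
#' `warmup` iterations is discarded before emitting samples. Note the orbit
#' from `x0 = 0.5` at `r = 4` hits 1 and then collapses to 0 forever; avoid
#' preimages of the fixed point when sampling chaos.
#'
#' @param n Number of samples returned (after warm-up).
#' @param r Map parameter in `(0, 4]`.
#' @param x0 Initial value in `(0, 1)`.
#' @param warmup Transient iterations discarded (default 1000; set 0 to keep
#'   the orbit from `x0` itself).
#' @inheritParams white_noise
#' @return An [itq_series].
#' @examples
#' logistic_map(5, r = 4, x0 = 0.3, warmup = 0)$values
#' @export
logistic_map <- function(n, r = 4, x0 = 0.1, warmup = 1000L,
                         step = 1, step_unit = "steps") {
  stopifnot(n >= 1)
  if (!is.numeric(r) || r <= 0 || r > 4) stop("r must lie in (0, 4]")
  if (!is.numeric(x0) || x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)")
  total <- n + as.integer(warmup)
  x <- numeric(total)
  x[1] <- x0
  for (t in seq_len(total - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  itq_series(x[(total - n + 1L):total], step = step, step_unit = step_unit)
}

#' Harmonic signal with additive noise
#'
#' `amplitude * sin(2 * pi * t / period) + N(0, noise_sd^2)`. Noise-free it
#' is the regular-process anchor: low entropy and complexity, Fisher
#' information near one.
#'
#' @param n Length.
#' @param period Period in samples, >= 2.
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @inheritParams white_noise
#' @return An [itq_series].
#' @export
harmonic <- function(n, period, amplitude = 1, noise_sd = 0, seed = 1L,
                     step = 1, step_unit = "steps") {
  stopifnot(n >= 1)
  if (period < 2) stop("period must be >= 2 samples")
  t <- seq_len(n)
  x <- amplitude * sin(2 * pi * t / period)
  if (noise_sd > 0) x <- x + local_rng(seed, stats::rnorm(n, sd = noise_sd))
  itq_series(x, step = step, step_unit = step_unit)
}

#' Pure diurnal productivity cycle
#'
#' A noise-free, strictly day-periodic daylight-bump profile: zero through
#' the night, an asymmetric sinusoidal bump during daylight hours. This is
#' the idealized "pure daily cycle" of a productivity series (no seasonal
#' modulation, no noise); under aggregation to 4 samples per day a length-4
#' embedding window spans exactly one day, which collapses the pattern
#' distribution onto the few phases of the cycle and produces the
#' characteristic entropy dip at 6-hour resolution.
#'
#' @param days Number of simulated days.
#' @param per_day Samples per day (default 48, half-hourly).
#' @param amplitude Peak value.
#' @return An [itq_series].
#' @export
diurnal_cycle <- function(days, per_day = 48L, amplitude = 1) {
  stopifnot(days >= 1, per_day >= 4)
  t <- seq_len(days * per_day)
  tod <- ((t - 1) %% per_day) / per_day
  x <- amplitude * pmax(0, sin(pi * (2 * tod - 0.25) / 0.75))
  itq_series(x, step = 1,
             step_unit = if (per_day == 48L) "half-hours" else "steps")
}

# resolution label -> samples per day / per year bookkeeping
resolution_info <- function(resolution) {
  switch(resolution,
    "halfhourly" = list(per_day = 48, step_unit = "half-hours"),
    "hourly"     = list(per_day = 24, step_unit = "hours"),
    "daily"      = list(per_day = 1, step_unit = "days"),
    "monthly"    = list(per_day = NA, step_unit = "months"),
    stop(sprintf("unsupported resolution '%s' (use halfhourly, hourly, daily, monthly)",
                 resolution))
  )
}

#' Synthetic productivity-like site series
#'
#' Emulates a gross-primary-productivity record: a seasonal sinusoid
#' (optionally with a mid-summer depression giving a two-peaked "bimodal"
#' season typical of water-limited sites), a diurnal cycle at sub-daily
#' resolutions, and AR(1) noise. Values are truncated at zero, as
#' productivity is nonnegative. Used as a stand-in for flux-tower series in
#' examples and tests; it does not emulate gap structure, weather-driven
#' synoptic variability or sensor artifacts of real data.
#'
#' @param years Number of simulated years, >= 1.
#' @param resolution One of `"halfhourly"`, `"hourly"`, `"daily"`,
#'   `"monthly"`.
#' @param regime `"unimodal"` (single summer peak) or `"bimodal"` (early
#'   summer + autumn peaks separated by a summer depression).
#' @param seed Integer seed.
#' @param amplitude Seasonal amplitude (arbitrary productivity units).
#' @param noise_sd AR(1) innovation standard deviation.
#' @param ar AR(1) coefficient of the noise, in `[0, 1)`.
#' @return An [itq_series].
#' @export
gpp_site <- function(years, resolution = "monthly",
                     regime = c("unimodal", "bimodal"), seed = 1L,
                     amplitude = 5, noise_sd = 0.3, ar = 0.5) {
  stopifnot(years >= 1)
  regime <- match.arg(regime)
  info <- resolution_info(resolution)
  if (resolution == "monthly") {
    n <- years * 12L
    doy <- (seq_len(n) - 0.5) / 12   # fractional year position
  } else {
    n <- as.integer(round(years * 365 * info$per_day))
    doy <- (seq_len(n) - 0.5) / (365 * info$per_day)
  }
  season <- sin(pi * ((doy %% 1)))^2          # one broad summer peak
  if (regime == "bimodal") {
    # mid-summer depression carves the peak into early + late maxima
    depress <- exp(-((doy %% 1) - 0.5)^2 / (2 * 0.06^2))
    season <- season - 0.7 * depress * season
  }
  x <- amplitude * season
  if (!is.na(info$per_day) && info$per_day > 1) {
    tod <- ((seq_len(n) - 0.5) %% info$per_day) / info$per_day
    diurnal <- pmax(0, sin(pi * (2 * tod - 0.25) / 0.75))  # daylight bump
    x <- x * diurnal
  }
  noise <- local_rng(seed, {
    as.numeric(stats::arima.sim(list(ar = ar), n = n, sd = noise_sd))
  })
  x <- pmax(0, x + noise)
  itq_series(x, step = 1, step_unit = info$step_unit)
}

#' Synthetic productivity-like space-time grid
#'
#' A monthly `time x lat x lon` field in which each latitude band is
#' assigned a dynamical regime, creating meridional gradients in the
#' information quantifiers: `"seasonal"` cells follow a strong annual cycle
#' (low entropy), `"noise"` cells are white noise (high entropy),
#' `"bimodal"` cells have a two-peaked season. Cell noise streams are
#' independent but derived deterministically from `seed`.
#'
#' @param nlat,nlon Grid dimensions.
#' @param months Number of monthly steps.
#' @param regimes Character vector of per-latitude-band regimes (recycled
#'   across `nlat` rows), entries among `"seasonal"`, `"noise"`,
#'   `"bimodal"`.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation added to seasonal cells.
#' @return A [gridded_field].
#' @export
gpp_grid <- function(nlat, nlon, months, regimes = c("seasonal", "noise"),
                     seed = 1L, noise_sd = 0.3) {
  stopifnot(nlat >= 1, nlon >= 1, months >= 12)
  regimes <- match.arg(regimes, c("seasonal", "noise", "bimodal"),
                       several.ok = TRUE)
  band <- rep(regimes, length.out = nlat)
  tt <- seq_len(months)
  season_uni <- sin(pi * (((tt - 0.5) / 12) %% 1))^2
  doy <- ((tt - 0.5) / 12) %% 1
  season_bi <- season_uni * (1 - 0.7 * exp(-(doy - 0.5)^2 / (2 * 0.06^2)))
  vals <- local_rng(seed, {
    arr <- array(NA_real_, dim = c(months, nlat, nlon))
    for (i in seq_len(nlat)) {
      for (j in seq_len(nlon)) {
        arr[, i, j] <- switch(band[i],
          seasonal = pmax(0, 5 * season_uni + stats::rnorm(months, sd = noise_sd)),
          bimodal  = pmax(0, 5 * season_bi + stats::rnorm(months, sd = noise_sd)),
          noise    = stats::rnorm(months)
        )
      }
    }
    arr
  })
  gridded_field(vals, time = tt, lat = seq(0.5, by = 1, length.out = nlat),
                lon = seq(0.5, by = 1, length.out = nlon))
}
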