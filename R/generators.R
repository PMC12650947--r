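# Generators of time series with known irreversibility: chaotic maps
# (strongly irreversible), linear Gaussian processes (reversible), stochastic
# processes with broken detailed balance, and symbolic chains.

#' Logistic map series
#'
#' Iterates `x[k+1] = r * x[k] * (1 - x[k])`; at `r = 4` the orbit is fully
#' chaotic and strongly time-irreversible.
#'
#' @param n series length (after burn-in).
#' @param r map parameter in (0, 4].
#' @param x0 initial condition in (0, 1); random when `NULL`. `x0 = 0.5` is
#'   rejected (it maps to the degenerate fixed orbit 1, 0, 0, ... at r = 4).
#' @param burn_in iterations discarded before recording.
#' @param seed RNG seed (used when `x0` is `NULL`).
#' @return numeric vector of length `n`.
#' @export
generate_logistic <- function(n, r = 4, x0 = NULL, burn_in = 1000,
                              seed = NULL) {
  if (r <= 0 || r > 4) stop("r must be in (0, 4]", call. = FALSE)
  if (is.null(x0)) x0 <- with_local_seed(seed, stats::runif(1, 0.01, 0.99))
  if (x0 <= 0 || x0 >= 1 || x0 == 0.5) {
    stop("x0 must be in (0, 1) and not 0.5", call. = FALSE)
  }
  total <- n + burn_in
  x <- numeric(total)
  x[1] <- x0
  for (k in seq_len(total - 1L)) x[k + 1L] <- r * x[k] * (1 - x[k])
  x[(burn_in + 1L):total]
}

#' Henon map series (first coordinate)
#'
#' `x[k+1] = 1 - a x[k]^2 + y[k]`, `y[k+1] = b x[k]`, standard parameters
#' a = 1.4, b = 0.3.
#'
#' @param n,burn_in,seed as in [generate_logistic()].
#' @param a,b map parameters.
#' @return numeric vector of length `n`.
#' @export
generate_henon <- function(n, a = 1.4, b = 0.3, burn_in = 1000, seed = NULL) {
  st <- with_local_seed(seed, stats::runif(2, -0.1, 0.1))
  x <- st[1]; y <- st[2]
  out <- numeric(n)
  total <- n + burn_in
  for (k in seq_len(total)) {
    xn <- 1 - a * x^2 + y
    y <- b * x
    x <- xn
    if (!is.finite(x)) stop("Henon orbit diverged", call. = FALSE)
    if (k > burn_in) out[k - burn_in] <- x
  }
  out
}

#' Linear congruential generator series
#'
#' The chaotic map `s[k+1] = (a s[k] + c) mod m`, returned normalised to
#' [0, 1). Park-Miller constants by default.
#'
#' @param n series length.
#' @param a,c,m LCG constants.
#' @param seed integer state seed.
#' @return numeric vector of length `n`.
#' @export
generate_lcg <- function(n, a = 16807, c = 0, m = 2^31 - 1, seed = 1) {
  s <- as.numeric(seed %% m)
  if (s == 0) s <- 1
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- (a * s + c) %% m
    out[k] <- s / m
  }
  out
}

#' Lorenz system series (first coordinate)
#'
#' Fixed-step fourth-order Runge-Kutta integration of the Lorenz equations
#' (sigma = 10, rho = 28, beta = 8/3), sampling the x coordinate.
#'
#' @param n number of samples.
#' @param sigma,rho,beta system parameters.
#' @param dt integration/sampling step.
#' @param burn_in discarded initial samples.
#' @param seed RNG seed for the random initial condition.
#' @return numeric vector of length `n`.
#' @export
generate_lorenz <- function(n, sigma = 10, rho = 28, beta = 8 / 3, dt = 0.02,
                            burn_in = 500, seed = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  st <- with_local_seed(seed, stats::rnorm(3, c(1, 1, 20), 0.5))
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  out <- numeric(n)
  total <- n + burn_in
  for (k in seq_len(total)) {
    k1 <- f(st); k2 <- f(st + dt / 2 * k1)
    k3 <- f(st + dt / 2 * k2); k4 <- f(st + dt * k3)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (k > burn_in) out[k - burn_in] <- st[1]
  }
  out
}

#' Ornstein-Uhlenbeck process
#'
#' Euler-Maruyama integration of `dx = -theta x dt + sigma dW`. A stationary
#' linear Gaussian process, hence time-reversible: the canonical negative
#' control for irreversibility tests.
#'
#' @param n series length.
#' @param theta mean-reversion rate (> 0).
#' @param sigma diffusion coefficient (> 0).
#' @param dt time step.
#' @param x0 initial value; stationary draw when `NULL`.
#' @param burn_in discarded initial samples.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
generate_ou <- function(n, theta = 1, sigma = 1, dt = 0.1, x0 = NULL,
                        burn_in = 100, seed = NULL) {
  if (theta <= 0 || sigma <= 0 || dt <= 0) {
    stop("theta, sigma, dt must be positive", call. = FALSE)
  }
  with_local_seed(seed, {
    x <- if (is.null(x0)) stats::rnorm(1, 0, sigma / sqrt(2 * theta)) else x0
    total <- n + burn_in
    out <- numeric(total)
    noise <- stats::rnorm(total, 0, sigma * sqrt(dt))
    for (k in seq_len(total)) {
      x <- x - theta * x * dt + noise[k]
      out[k] <- x
    }
    out[(burn_in + 1L):total]
  })
}

#' Geometric Brownian motion with stochastic resetting (srGBM)
#'
#' Log-Euler GBM with Poissonian resetting to `x0` at rate `r_reset`;
#' resetting breaks detailed balance, making the process canonically
#' irreversible.
#'
#' @param n series length.
#' @param mu,sigma GBM drift and volatility (per unit time).
#' @param r_reset resetting rate (per unit time, >= 0).
#' @param x0 reset/initial value (> 0).
#' @param dt time step.
#' @param seed RNG seed.
#' @return numeric vector of length `n` (positive values).
#' @export
generate_srgbm <- function(n, mu = 0.1, sigma = 0.2, r_reset = 0.05, x0 = 1,
                           dt = 0.1, seed = NULL) {
  if (x0 <= 0 || sigma <= 0 || dt <= 0 || r_reset < 0) {
    stop("invalid srGBM parameters", call. = FALSE)
  }
  with_local_seed(seed, {
    out <- numeric(n)
    x <- x0
    z <- stats::rnorm(n)
    u <- stats::runif(n)
    p_reset <- 1 - exp(-r_reset * dt)
    for (k in seq_len(n)) {
      if (u[k] < p_reset) {
        x <- x0
      } else {
        x <- x * exp((mu - sigma^2 / 2) * dt + sigma * sqrt(dt) * z[k])
      }
      out[k] <- x
    }
    out
  })
}

#' Asymmetric Weierstrass-type series
#'
#' A Weierstrass-style sum of self-similar harmonics in which the usual
#' cosine is replaced by an asymmetric piecewise-linear wave that rises over
#' a fraction `gamma` of its period and falls over the rest; `gamma != 0.5`
#' breaks time symmetry at every scale.
#'
#' @param n series length.
#' @param a amplitude ratio in (0, 1).
#' @param b frequency ratio (> 1, with `a * b > 1` for a rough signal).
#' @param gamma rise fraction of the waveform in (0, 1); 0.5 is symmetric.
#' @param nterms number of harmonics summed.
#' @param period base period in samples.
#' @return numeric vector of length `n`.
#' @export
generate_weierstrass_asym <- function(n, a = 0.6, b = 3, gamma = 0.25,
                                      nterms = 8, period = n / 4) {
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0,1)", call. = FALSE)
  saw <- function(ph) {  # asymmetric triangle wave on phase in [0,1)
    ph <- ph - floor(ph)
    ifelse(ph < gamma, ph / gamma, (1 - ph) / (1 - gamma))
  }
  t <- seq_len(n) / period
  x <- numeric(n)
  for (k in 0:(nterms - 1L)) x <- x + a^k * saw(b^k * t)
  x
}

#' Series irreversible at a specific time scale
#'
#' Superposes a strongly irreversible component held constant over blocks of
#' `tau_star` samples (a logistic-map orbit) and dominant iid Gaussian noise.
#' At the native resolution the reversible noise dominates; averaging-
#' downsampling at `tau = tau_star` suppresses the noise and exposes the
#' irreversible component; far coarser scales average over many chaotic
#' values and the asymmetry washes out again.
#'
#' @param n series length.
#' @param tau_star the scale (in samples) at which irreversibility lives.
#' @param snr amplitude of the irreversible component relative to the noise
#'   standard deviation.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
generate_multiscale_irrev <- function(n, tau_star = 5, snr = 1,
                                      seed = NULL) {
  tau_star <- as.integer(tau_star)
  if (tau_star < 1L) stop("tau_star must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    nb <- ceiling(n / tau_star)
    base <- generate_logistic(nb, x0 = stats::runif(1, 0.01, 0.99))
    base <- (base - mean(base)) / stats::sd(base)
    rep(base, each = tau_star)[seq_len(n)] * snr + stats::rnorm(n)
  })
}

#' Symbolic random walk
#'
#' A biased nearest-neighbour walk on a cyclic alphabet: from state i the
#' walk moves to i+1 with probability `p_up` and to i-1 otherwise (indices
#' mod alphabet size). Any `p_up != 0.5` breaks detailed balance on the
#' cycle, producing a known-irreversible symbol stream.
#'
#' @param n series length.
#' @param alphabet vector of symbols (>= 3 for the cycle to be asymmetric).
#' @param p_up probability of a forward step.
#' @param seed RNG seed.
#' @return vector of symbols drawn from `alphabet`.
#' @export
generate_symbolic_walk <- function(n, alphabet = 0:3, p_up = 0.7,
                                   seed = NULL) {
  K <- length(alphabet)
  if (K < 2L) stop("alphabet needs at least 2 symbols", call. = FALSE)
  if (p_up < 0 || p_up > 1) stop("p_up must be in [0,1]", call. = FALSE)
  with_local_seed(seed, {
    steps <- ifelse(stats::runif(n) < p_up, 1L, -1L)
    pos <- (cumsum(steps)) %% K
    alphabet[pos + 1L]
  })
}
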