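#' Exact Ornstein-Uhlenbeck update
#'
#' One step of the exactly discretised OU process:
#' `x' = mu + (x - mu) * exp(-dt/tau) + sigma * sqrt(1 - exp(-2 dt/tau)) * noise`.
#' With standard-normal `noise` the stationary distribution is
#' `Normal(mu, sigma^2)` for any `dt`.
#'
#' @param x current value (vectorised).
#' @param mu stationary mean.
#' @param tau_c relaxation time (> 0, same unit as `dt`).
#' @param sigma stationary standard deviation.
#' @param dt time step.
#' @param noise standard-normal draw(s), same length as `x`.
#' @return Updated value(s).
#' @export
ou_step <- function(x, mu, tau_c, sigma, dt, noise) {
  if (any(tau_c <= 0)) abort_config("ou_step: tau_c must be > 0")
  a <- exp(-dt / tau_c)
  mu + (x - mu) * a + sigma * sqrt(1 - a^2) * noise
}

#' Simulate an OU series with the exact discretisation
#'
#' @param n number of steps to return.
#' @param mu stationary mean: scalar or length-`n` vector (time-varying).
#' @param tau_c relaxation time.
#' @param sigma stationary sd.
#' @param dt time step.
#' @param x0 initial value (defaults to the first `mu`).
#' @param seed optional seed (`NULL` uses the current RNG stream).
#' @return Numeric vector of length `n` (the first element is `x0`).
#' @export
ou_series <- function(n, mu, tau_c, sigma, dt = 1, x0 = NULL, seed = NULL) {
  mu <- rep_len(mu, n)
  with_seed(seed, {
    x <- numeric(n)
    x[1] <- if (is.null(x0)) mu[1] else x0
    if (n > 1) {
      noise <- stats::rnorm(n - 1)
      for (t in 2:n) {
        x[t] <- ou_step(x[t - 1], mu[t], tau_c, sigma, dt, noise[t - 1])
      }
    }
    x
  })
}
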