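# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route their explicit `seed` argument through here so that no call perturbs
# global RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated-at-zero normal via inverse CDF; exact for sd = 0.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. Used by the scene simulator to draw step
#' directions biased toward the wound; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, >= 0.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0, seed = NULL) {
  stopifnot(kappa >= 0, n >= 0)
  with_local_seed(seed, {
    if (kappa == 0) {
      theta <- stats::runif(n, -pi, pi)
    } else {
      a <- 1 + sqrt(1 + 4 * kappa^2)
      b <- (a - sqrt(2 * a)) / (2 * kappa)
      r <- (1 + b^2) / (2 * b)
      theta <- numeric(n)
      i <- 1L
      while (i <= n) {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        c_ <- kappa * (r - f)
        if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
          theta[i] <- sign(u[3] - 0.5) * acos(f)
          i <- i + 1L
        }
      }
      theta <- theta + mu
    }
    wrap_angle(theta)
  })
}

# Wrap angles (radians) into (-pi, pi].
wrap_angle <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  out[out <= -pi] <- pi
  out
}
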