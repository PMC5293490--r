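#' The damped-sine oral-aboral angle distribution
#'
#' Density, distribution function and random generation for the damped-sine
#' family used to describe the polar angle \eqn{\theta \in [0, \pi]} of
#' piwi-1+ blastomeres measured from the oral (embryonic pharynx) pole:
#' \deqn{f(\theta; \theta') = (1 - e^{-\theta/\theta'}) \sin(\theta) / Z(\theta')}
#' The single parameter \eqn{\theta'} ("dampening term", radians) depletes
#' density near the oral pole; \eqn{\theta' = 0} recovers the
#' uniform-on-sphere polar density \eqn{\sin(\theta)/2}.
#'
#' The normalizing constant has the closed form
#' \deqn{Z(\theta') = 2 - \theta'^2 (1 + e^{-\pi/\theta'}) / (1 + \theta'^2)}
#' with \eqn{Z(0) = 2} as the limit. The distribution function is likewise
#' closed-form (see [pdsine()]); both are cross-checked against adaptive
#' quadrature in the package tests.
#'
#' @param theta numeric vector of angles in radians; must lie in
#'   \eqn{[0, \pi]}.
#' @param theta_prime dampening parameter \eqn{\theta' \ge 0} (radians);
#'   scalar.
#' @param log logical; if `TRUE`, return the log density.
#' @return `ddsine` the (log) density, `pdsine` the distribution function,
#'   `rdsine` a numeric vector of `n` angles, `dsine_normalizer` the
#'   normalizing constant \eqn{Z(\theta')}.
#' @examples
#' ddsine(pi / 2, theta_prime = 0)        # null density at the equator: 1/2
#' pdsine(pi / 2, theta_prime = 0)        # null CDF at the equator: 1/2
#' th <- rdsine(500, theta_prime = 0.45, seed = 1)
#' @name dsine
NULL

check_theta_prime <- function(theta_prime) {
  if (!is.numeric(theta_prime) || length(theta_prime) != 1L ||
      is.na(theta_prime) || theta_prime < 0) {
    stop("'theta_prime' must be a single non-negative number", call. = FALSE)
  }
  as.numeric(theta_prime)
}

check_theta_domain <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta)) {
    stop("'theta' must be numeric without NAs", call. = FALSE)
  }
  if (any(theta < 0 | theta > pi)) {
    stop("'theta' must lie in [0, pi]", call. = FALSE)
  }
  as.numeric(theta)
}

#' @rdname dsine
#' @export
dsine_normalizer <- function(theta_prime) {
  theta_prime <- check_theta_prime(theta_prime)
  if (theta_prime == 0) return(2)
  2 - theta_prime^2 * (1 + exp(-pi / theta_prime)) / (1 + theta_prime^2)
}

#' @rdname dsine
#' @export
ddsine <- function(theta, theta_prime, log = FALSE) {
  theta <- check_theta_domain(theta)
  theta_prime <- check_theta_prime(theta_prime)
  if (theta_prime == 0) {
    # exact null embedding: log(sin(theta)/2), -Inf at the poles
    ld <- suppressWarnings(log(sin(theta) / 2))
    ld[theta == 0 | theta == pi] <- -Inf
  } else {
    ld <- suppressWarnings(log(sin(theta)))
    ld[theta == 0 | theta == pi] <- -Inf    # sin() rounding at pi
    # log(1 - exp(-r)) via expm1 for accuracy at both small and large r
    r <- theta / theta_prime
    ld <- ld + log(-expm1(-r)) - log(dsine_normalizer(theta_prime))
  }
  if (log) ld else exp(ld)
}

#' @rdname dsine
#' @export
pdsine <- function(theta, theta_prime) {
  theta <- check_theta_domain(theta)
  theta_prime <- check_theta_prime(theta_prime)
  if (theta_prime == 0) {
    p <- (1 - cos(theta)) / 2
  } else {
    a <- 1 / theta_prime
    num <- (1 - cos(theta)) -
      (1 - exp(-a * theta) * (a * sin(theta) + cos(theta))) / (1 + a^2)
    p <- num / dsine_normalizer(theta_prime)
  }
  pmin(pmax(p, 0), 1)
}

#' @rdname dsine
#' @param n number of draws (non-negative integer).
#' @param seed optional integer seed; when supplied the draw is
#'   deterministic and the caller's RNG state is left untouched.
#' @details `rdsine` is an exact rejection sampler: proposals
#'   \eqn{\theta = \arccos(1 - 2u)} come from the null \eqn{\sin(\theta)/2}
#'   and are accepted with probability \eqn{1 - e^{-\theta/\theta'}}, so the
#'   overall acceptance rate is \eqn{Z(\theta')/2}.
#' @export
rdsine <- function(n, theta_prime, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  theta_prime <- check_theta_prime(theta_prime)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (theta_prime == 0) return(acos(1 - 2 * stats::runif(n)))
  accept_rate <- dsine_normalizer(theta_prime) / 2
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept_rate * 1.2) + 16L
    prop <- acos(1 - 2 * stats::runif(m))
    keep <- stats::runif(m) < -expm1(-prop / theta_prime)
    out <- c(out, prop[keep])
  }
  out[seq_len(n)]
}

# Save/restore .Random.seed so seeded helpers do not perturb the caller's
# RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Child seed for replicate b of a seeded procedure, so results for replicate
# b do not depend on how many replicates run. Kept below 2^31 - 1.
child_seed <- function(seed, b) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + b) %% 2147483647)
}
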