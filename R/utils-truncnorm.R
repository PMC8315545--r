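## Numerically stable univariate truncated-normal machinery.
##
## EP site updates routinely evaluate moments of a Gaussian truncated to a box
## lying ten or more standard deviations into a tail; naive pnorm/dnorm ratios
## underflow there. All tail work is routed through the scaled complementary
## error function erfcx(x) = exp(x^2) erfc(x), which stays O(1/x).

SQRT2 <- sqrt(2)
SQRT_2_PI <- sqrt(2 / pi)

#' Moments of a univariate truncated normal
#'
#' Mean and variance of `N(mean, sd^2)` truncated to `[a, b]`, computed
#' stably for truncation intervals arbitrarily far into either tail.
#' All arguments are recycled to a common length.
#'
#' @param mean,sd Mean and standard deviation of the parent Gaussian.
#'   `sd = Inf` (a flat parent) gives the uniform moments on `[a, b]`.
#' @param a,b Lower and upper truncation bounds (may be infinite; `a <= b`).
#' @return A list with numeric vectors `mean` and `var`.
#' @keywords internal
truncnorm_moments <- function(mean, sd, a, b) {
  n <- max(length(mean), length(sd), length(a), length(b))
  m <- rep_len(mean, n); s <- rep_len(sd, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  out_m <- numeric(n); out_v <- numeric(n)

  width <- b - a
  ## Degenerate interval: point mass.
  point <- width <= 0
  ## Flat parent (infinite or enormous sd relative to a finite box): uniform.
  flat <- !point & is.finite(width) & (!is.finite(s) | s > 1e8 * pmax(width, 1))

  out_m[point] <- a[point]
  out_v[point] <- 0
  out_m[flat] <- (a[flat] + b[flat]) / 2
  out_v[flat] <- width[flat]^2 / 12

  todo <- which(!point & !flat)
  for (i in todo) {
    mo <- .tn_moments1(m[i], s[i], a[i], b[i])
    out_m[i] <- mo[1]
    out_v[i] <- mo[2]
  }
  list(mean = out_m, var = out_v)
}

## Scalar worker: standardized bounds alpha, beta; reflect so that the
## interval sits in the upper tail or straddles the mode.
.tn_moments1 <- function(m, s, a, b) {
  al <- (a - m) / s
  be <- (b - m) / s
  if (!is.finite(al) && !is.finite(be)) return(c(m, s^2))
  if (be <= 0) { # reflect into the upper tail
    mo <- .tn_moments_std(-be, -al)
    return(c(m - s * mo[1], s^2 * mo[2]))
  }
  mo <- .tn_moments_std(al, be)
  c(m + s * mo[1], s^2 * mo[2])
}

## Standardized moments for N(0,1) truncated to [al, be] with be > 0.
## Returns c(mean, var) in standard units.
.tn_moments_std <- function(al, be) {
  if (al > 0) {
    ## Both bounds in the upper tail: work with erfcx to avoid underflow.
    z1 <- al / SQRT2
    z2 <- be / SQRT2
    if (is.finite(be)) {
      d <- exp(z1 * z1 - z2 * z2) # <= 1
      denom <- pracma::erfcx(z1) - d * pracma::erfcx(z2)
      r1 <- SQRT_2_PI / denom         # phi(al) / Z
      r2 <- SQRT_2_PI * d / denom     # phi(be) / Z
    } else {
      denom <- pracma::erfcx(z1)
      r1 <- SQRT_2_PI / denom
      r2 <- 0
      be <- 0 # so that be * r2 = 0 below
    }
    mu <- r1 - r2
    v <- 1 + al * r1 - be * r2 - mu * mu
  } else {
    ## Interval straddles the mode: plain formulas are stable.
    Z <- stats::pnorm(be) - stats::pnorm(al)
    p1 <- stats::dnorm(al)
    p2 <- stats::dnorm(be)
    mu <- (p1 - p2) / Z
    t1 <- if (is.finite(al)) al * p1 else 0
    t2 <- if (is.finite(be)) be * p2 else 0
    v <- 1 + (t1 - t2) / Z - mu * mu
  }
  ## Guard against cancellation at extreme truncation.
  if (!is.finite(v) || v <= 0) v <- .Machine$double.eps
  if (v > 1) v <- 1
  c(mu, v)
}

#' Draw from a univariate truncated normal
#'
#' Inverse-CDF sampler for `N(mean, sd^2)` truncated to `[a, b]`, carried out
#' in whichever tail the interval falls so far-tail draws stay accurate.
#' A non-finite or enormous `sd` yields a uniform draw on `[a, b]`.
#'
#' @param mean,sd Parent Gaussian parameters (scalars).
#' @param a,b Truncation bounds, `a <= b`.
#' @return A single draw. Consumes one `runif` variate.
#' @keywords internal
rtruncnorm1 <- function(mean, sd, a, b) {
  if (b <= a) return(a)
  if (!is.finite(sd) || sd > 1e8 * max(b - a, 1)) return(stats::runif(1, a, b))
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  u <- stats::runif(1)
  if (al >= 0) { # upper tail: interpolate log upper-tail probabilities
    la <- stats::pnorm(al, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(be, lower.tail = FALSE, log.p = TRUE)
    lp <- la + log1p(u * expm1(lb - la))
    z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  } else if (be <= 0) { # lower tail: reflect
    la <- stats::pnorm(-be, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(-al, lower.tail = FALSE, log.p = TRUE)
    lp <- la + log1p(u * expm1(lb - la))
    z <- -stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  } else {
    pa <- stats::pnorm(al)
    pb <- stats::pnorm(be)
    z <- stats::qnorm(pa + u * (pb - pa))
  }
  min(max(mean + sd * z, a), b)
}

## Evaluate expr with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
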