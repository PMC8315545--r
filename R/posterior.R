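## Expectation Propagation characterization of the feasible flux space.
##
## Target density over fluxes v:
##   p(v) ∝ exp(-beta/2 ||S v - mdot||^2) * prod_n 1[v_inf_n <= v_n <= v_sup_n]
##          * prod_{i in obs} N(v_i; v_i^obs, sigma_i^2)
## The stoichiometric constraint is handled exactly through the null-space
## parameterization v = v_p + K x (S K = 0), on which the Boltzmann energy is
## constant. Reactions whose kernel rows are proportional are *strictly
## coupled*: they share a single scalar degree of freedom t = w' x, and the
## intersection of their box constraints is one interval in t. EP places one
## univariate Gaussian site per coupled class on that interval; classes of
## size one recover the standard per-flux site. This choice makes the
## approximation exact on fully coupled models (a chain's single tilted
## moment is the uniform moment) and materially improves marginal variances
## elsewhere.

#' Fit the flux posterior by Expectation Propagation
#'
#' Approximates the steady-state flux distribution -- the Boltzmann-like
#' density `exp(-beta E(v))` with `E(v) = 1/2 ||S v - mdot||^2`, truncated
#' to the flux bounds -- by a multivariate Gaussian, using Expectation
#' Propagation in exact null-space coordinates. Each strictly coupled class
#' of reactions carries one univariate Gaussian site whose moments are
#' matched to the truncated-Gaussian tilted distribution on the class's
#' feasible interval; truncated moments are computed with scaled
#' complementary error function stabilization so sites survive far-tail
#' truncation.
#'
#' @param model A [metabolic_model()]. Bounds must close the polytope in
#'   every free direction.
#' @param mdot Length-`M` metabolite input/output rates; default the zero
#'   vector (steady state).
#' @param beta Energy stiffness (> 0), default `1e10`. Mass balance is
#'   enforced exactly through the null-space parameterization; `beta` only
#'   sets the (tiny) transverse variance of the reported covariance.
#' @param damping Fraction of the proposed site update applied per sweep, in
#'   (0, 1]; 1 is an undamped update.
#' @param tol Convergence threshold on the maximum relative change of site
#'   natural parameters between sweeps.
#' @param max_iter Maximum number of EP sweeps; non-convergence returns the
#'   current fit with `converged = FALSE` and a warning.
#' @param observations Optional named list `reaction_id = c(value, sigma)`:
#'   observed fluxes contributing Gaussian factors `N(value, sigma^2)` to
#'   the target (see [condition_on_observed_flux()]). Defaults to the
#'   `fixed_exchanges` recorded on the model by [apply_constraints()].
#' @param check_feasible Run the phase-I feasibility solve first (default
#'   TRUE) and fail fast on an empty polytope.
#' @return An object of class `flux_posterior`: `mu` and `marginal_var`
#'   (per-reaction posterior means and variances), `Sigma` (covariance of
#'   the EP Gaussian over fluxes), `mu_gaussian`, `bounds`, `mdot`, `beta`,
#'   `converged`, `iterations`, `particular_solution`, `kernel` (a
#'   [kernel_basis()]), the coupled-class structure, and the restriction of
#'   the EP Gaussian to the affine subspace (`A`, `m_x`) used by
#'   [log_density()] plus the Gaussian part of the exact target (`A_obs`,
#'   `b_obs`) used by [sample_posterior()].
#' @examples
#' m <- toy_models()$segment
#' post <- ep_fit(m)
#' post$mu           # both fluxes 0.5
#' post$marginal_var # both 1/12
#' @export
ep_fit <- function(model, mdot = NULL, beta = 1e10, damping = 0.7,
                   tol = 1e-6, max_iter = 2000, observations = NULL,
                   check_feasible = TRUE) {
  validate_model(model)
  stopifnot(beta > 0, damping > 0, damping <= 1, max_iter >= 1)
  N <- length(model$reaction_ids)
  M <- length(model$metabolite_ids)
  if (is.null(mdot)) mdot <- numeric(M)
  if (length(mdot) != M) stop("mdot must have one entry per metabolite")
  lo <- model$v_inf
  hi <- model$v_sup

  if (is.null(observations)) observations <- attr(model, "fixed_exchanges")
  obs_prec <- numeric(N)
  obs_h <- numeric(N)
  if (length(observations)) {
    for (rid in names(observations)) {
      j <- match(rid, model$reaction_ids)
      if (is.na(j)) stop("observed flux for unknown reaction: ", rid)
      val <- observations[[rid]][1]
      sig <- observations[[rid]][2]
      if (sig <= 0) stop("observation sigma must be > 0 for ", rid)
      if (val < lo[j] || val > hi[j])
        stop(sprintf(
          "observed flux %g for reaction %s lies outside its bounds [%g, %g]",
          val, rid, lo[j], hi[j]))
      obs_prec[j] <- obs_prec[j] + 1 / sig^2
      obs_h[j] <- obs_h[j] + val / sig^2
    }
  }

  geom <- polytope_geometry(model, mdot)
  kb <- geom$kb
  vp <- geom$vp
  if (check_feasible) {
    fp <- feasible_point(model, mdot, geom)
    if (!fp$feasible)
      stop("infeasible model: the flux polytope is empty (box violation ",
           format(fp$violation), ")")
  }
  K <- kb$K
  d <- kb$d

  cls <- coupled_classes(K)
  ## feasible interval of each class coordinate t = w' x:
  ## lo_n <= vp_n + c_n t <= hi_n for every member n
  nC <- length(cls$classes)
  t_lo <- numeric(nC); t_hi <- numeric(nC)
  for (ci in seq_len(nC)) {
    mem <- cls$classes[[ci]]
    co <- cls$coef[mem]
    l <- ifelse(co > 0, (lo[mem] - vp[mem]) / co, (hi[mem] - vp[mem]) / co)
    u <- ifelse(co > 0, (hi[mem] - vp[mem]) / co, (lo[mem] - vp[mem]) / co)
    t_lo[ci] <- max(l); t_hi[ci] <- min(u)
  }
  if (any(t_lo > t_hi + 1e-9))
    stop("infeasible model: a strictly coupled reaction class has an empty feasible interval")

  ## Gaussian factors of the exact target restricted to the subspace
  ## (only observation factors survive; the beta energy is constant there).
  A_obs <- crossprod(K * sqrt(obs_prec))
  b_obs <- as.numeric(crossprod(K, obs_h - obs_prec * vp))

  W <- cls$W # d x nC unit class directions
  ## site natural parameters per class (q = 1/variance, r = mean/variance)
  width <- t_hi - t_lo
  q_site <- ifelse(is.finite(width) & width > 0, 12 / width^2, 1e-6)
  q_site[width <= 0] <- 1e10
  r_site <- q_site * ifelse(is.finite(t_lo) & is.finite(t_hi),
                            (t_lo + t_hi) / 2,
                            ifelse(is.finite(t_lo), t_lo,
                                   ifelse(is.finite(t_hi), t_hi, 0)))
  q_min <- 1e-10; q_max <- 1e12

  tilt_m <- r_site / q_site
  tilt_v <- 1 / q_site
  converged <- FALSE
  it <- 0L
  delta <- Inf
  if (d > 0) {
    while (it < max_iter) {
      it <- it + 1L
      A <- A_obs + W %*% (q_site * t(W))
      Cx <- chol2inv(chol(A))
      m_x <- as.numeric(Cx %*% (b_obs + as.numeric(W %*% r_site)))
      ## class-coordinate marginals of the Gaussian
      s2_t <- colSums(W * (Cx %*% W))
      m_t <- as.numeric(crossprod(W, m_x))
      q_cav <- 1 / s2_t - q_site
      flat <- q_cav <= 1e-14
      s_cav <- ifelse(flat, Inf, sqrt(1 / q_cav))
      m_cav <- ifelse(flat, 0, (m_t / s2_t - r_site) / q_cav)
      mo <- truncnorm_moments(m_cav, s_cav, t_lo, t_hi)
      tilt_m <- mo$mean
      tilt_v <- pmax(mo$var, 1e-14)
      q_prop <- pmin(pmax(1 / tilt_v - q_cav, q_min), q_max)
      r_prop <- tilt_m / tilt_v - ifelse(flat, 0, m_cav * q_cav)
      q_next <- (1 - damping) * q_site + damping * q_prop
      r_next <- (1 - damping) * r_site + damping * r_prop
      delta <- max(abs(q_next - q_site) / (1 + abs(q_site)),
                   abs(r_next - r_site) / (1 + abs(r_site)))
      q_site <- q_next
      r_site <- r_next
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("EP did not converge in %d sweeps (last change %.3g)",
                      max_iter, delta))
    A <- A_obs + W %*% (q_site * t(W))
    Cx <- chol2inv(chol(A))
    m_x <- as.numeric(Cx %*% (b_obs + as.numeric(W %*% r_site)))
    s2_t <- colSums(W * (Cx %*% W))
    m_t <- as.numeric(crossprod(W, m_x))
    q_cav <- 1 / s2_t - q_site
    flat <- q_cav <= 1e-14
    s_cav <- ifelse(flat, Inf, sqrt(1 / q_cav))
    m_cav <- ifelse(flat, 0, (m_t / s2_t - r_site) / q_cav)
    mo <- truncnorm_moments(m_cav, s_cav, t_lo, t_hi)
    tilt_m <- mo$mean
    tilt_v <- mo$var
  } else {
    A <- matrix(0, 0, 0)
    Cx <- matrix(0, 0, 0)
    m_x <- numeric(0)
    converged <- TRUE
  }

  ## per-reaction posterior marginals
  mu <- vp
  marg_var <- numeric(N)
  for (ci in seq_len(nC)) {
    mem <- cls$classes[[ci]]
    co <- cls$coef[mem]
    mu[mem] <- vp[mem] + co * tilt_m[ci]
    marg_var[mem] <- co^2 * tilt_v[ci]
  }

  ## covariance of the EP Gaussian over fluxes: subspace part plus a
  ## transverse part of variance 1/(beta sigma_i^2) along each row-space
  ## direction of S
  Sigma <- if (d > 0) K %*% Cx %*% t(K) else matrix(0, N, N)
  if (kb$rank > 0) {
    sv <- svd(model$S, nu = 0, nv = N)
    pos <- seq_len(kb$rank)
    Vr <- sv$v[, pos, drop = FALSE]
    Sigma <- Sigma + Vr %*% (t(Vr) / (beta * sv$d[pos]^2))
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  mu_gaussian <- vp + if (d > 0) as.numeric(K %*% m_x) else 0

  structure(
    list(
      mu = mu,
      marginal_var = marg_var,
      Sigma = Sigma,
      mu_gaussian = mu_gaussian,
      bounds = list(v_inf = lo, v_sup = hi),
      mdot = mdot,
      beta = beta,
      converged = converged,
      iterations = it,
      particular_solution = vp,
      kernel = kb,
      classes = cls,
      class_bounds = cbind(t_lo = t_lo, t_hi = t_hi),
      site_q = q_site,
      site_r = r_site,
      A = A,
      m_x = m_x,
      A_obs = A_obs,
      b_obs = b_obs,
      obs_prec = obs_prec,
      obs_h = obs_h,
      reaction_ids = model$reaction_ids
    ),
    class = "flux_posterior"
  )
}

## Group kernel rows into strictly coupled classes (rows proportional up to
## sign). Returns member indices per class, the signed coefficient of each
## reaction on its class direction, the d x nC matrix W of unit class
## directions, and the indices of fully determined reactions (zero rows).
coupled_classes <- function(K, tol = 1e-8) {
  N <- nrow(K)
  norms <- sqrt(rowSums(K^2))
  determined <- which(norms < 1e-10)
  free <- setdiff(seq_len(N), determined)
  classes <- list()
  reps <- NULL # d x nC matrix of class directions
  coef <- numeric(N)
  cls_of <- integer(N)
  for (n in free) {
    u <- K[n, ] / norms[n]
    assigned <- FALSE
    if (length(classes)) {
      dots <- as.numeric(crossprod(reps, u))
      hit <- which(abs(dots) > 1 - tol)
      if (length(hit)) {
        ci <- hit[1]
        classes[[ci]] <- c(classes[[ci]], n)
        coef[n] <- sum(K[n, ] * reps[, ci])
        cls_of[n] <- ci
        assigned <- TRUE
      }
    }
    if (!assigned) {
      classes[[length(classes) + 1]] <- n
      reps <- cbind(reps, u)
      coef[n] <- norms[n]
      cls_of[n] <- length(classes)
    }
  }
  if (is.null(reps)) reps <- matrix(0, ncol(K), 0)
  list(classes = classes, W = reps, coef = coef, cls_of = cls_of,
       determined = determined)
}

#' @export
print.flux_posterior <- function(x, ...) {
  cat(sprintf("flux_posterior: %d reactions, kernel dimension %d (%d coupled classes)\n",
              length(x$mu), x$kernel$d, length(x$classes$classes)))
  cat(sprintf("  EP %s after %d sweeps (beta = %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$beta))
  invisible(x)
}

#' Condition the flux posterior on observed exchange fluxes
#'
#' Refits the posterior with each observed flux contributing a Gaussian
#' factor `N(v_obs, sigma^2)` to the target density -- the mechanism by
#' which, e.g., a measured CO2 release rate delimits the feasible space
#' before prediction. The marginal mean of an observed flux ends up within
#' about `2 sigma` of the observation (how close depends on how strongly
#' the polytope resists).
#'
#' @param model A [metabolic_model()].
#' @param spec A [constraint_spec()] with nonempty `fixed_exchanges`, or a
#'   named list `reaction_id = c(value, sigma)`.
#' @param ... Passed on to [ep_fit()].
#' @return A `flux_posterior`.
#' @export
condition_on_observed_flux <- function(model, spec, ...) {
  fe <- if (inherits(spec, "constraint_spec")) spec$fixed_exchanges else spec
  if (length(fe) == 0)
    stop("no observed fluxes supplied (fixed_exchanges is empty)")
  ep_fit(model, observations = fe, ...)
}

#' Unnormalized log posterior density of flux vectors
#'
#' Evaluates the EP Gaussian in null-space coordinates `x = K'(v - v_p)`:
#' the returned value is `-(x - m_x)' A (x - m_x) / 2`, comparable only
#' across points of the same posterior (the prediction objective only ever
#' uses ratios). Points violating the box bounds or falling off the affine
#' subspace get `-Inf`.
#'
#' @param posterior A `flux_posterior` from [ep_fit()].
#' @param v A length-`N` flux vector or an `n x N` matrix of flux vectors
#'   (rows are points).
#' @param tol Tolerance for the bound and mass-balance checks.
#' @return Numeric vector of unnormalized log densities.
#' @export
log_density <- function(posterior, v, tol = 1e-6) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != length(posterior$mu))
    stop("flux vectors must have one entry per reaction")
  K <- posterior$kernel$K
  vp <- posterior$particular_solution
  lo <- posterior$bounds$v_inf
  hi <- posterior$bounds$v_sup
  Vt <- t(V)
  X <- crossprod(K, Vt - vp) # d x n
  Vproj <- vp + K %*% X
  off <- apply(abs(Vt - Vproj), 2, max)
  inside <- colSums(Vt < lo - tol) == 0 & colSums(Vt > hi + tol) == 0 &
    off <= tol
  ld <- rep(-Inf, nrow(V))
  if (any(inside) && posterior$kernel$d > 0) {
    Dx <- X[, inside, drop = FALSE] - posterior$m_x
    ld[inside] <- -0.5 * colSums(Dx * (posterior$A %*% Dx))
  } else {
    ld[inside] <- 0
  }
  ld
}
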