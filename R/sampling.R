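## Samplers over the feasible flux polytope.
##
## Both samplers work in null-space coordinates x (v = v_p + K x), so mass
## balance holds to machine precision for every emitted point. On the affine
## subspace the Boltzmann energy is constant, so the exact target reduces to
## the box indicators times any observed-flux Gaussian factors: with no
## observations the Gibbs conditionals are uniform on the feasible chord and
## the sampler is an exact uniform polytope sampler; with observations they
## are truncated Gaussians.

#' Sample the flux posterior
#'
#' Coordinate-wise Gibbs sampler in null-space coordinates: each sweep
#' updates every coordinate of `x` from its exact conditional (uniform, or a
#' truncated Gaussian when observed-flux factors are present) on the
#' interval permitted by the flux bounds, and each sweep emits one sample
#' `v = v_p + K x`. Deterministic given `seed`; the global RNG state is
#' left untouched.
#'
#' @param posterior A `flux_posterior` from [ep_fit()].
#' @param N_s Number of samples to draw (>= 1).
#' @param seed Integer seed.
#' @param burn_in Sweeps discarded before recording (default 100).
#' @param thin Record every `thin`-th sweep (default 1).
#' @return A `sample_set`: list with `fluxes` (`N_s x N` matrix, columns
#'   named by reaction), `log_density` (unnormalized log `p_v` of each row
#'   under the EP posterior), `seed`, `source = "ep"`.
#' @export
sample_posterior <- function(posterior, N_s, seed = 1L, burn_in = 100L,
                             thin = 1L) {
  stopifnot(N_s >= 1, burn_in >= 0, thin >= 1)
  K <- posterior$kernel$K
  d <- posterior$kernel$d
  vp <- posterior$particular_solution
  lo <- posterior$bounds$v_inf
  hi <- posterior$bounds$v_sup
  N <- length(vp)

  if (d == 0) {
    fluxes <- matrix(rep(vp, each = N_s), N_s, N)
    colnames(fluxes) <- posterior$reaction_ids
    return(new_sample_set(fluxes, rep(0, N_s), seed, "ep"))
  }

  x <- gibbs_start(posterior)
  A <- posterior$A_obs
  b <- posterior$b_obs
  has_gauss <- any(A != 0)

  ## per-coordinate support of K for fast chord intersection
  supp <- lapply(seq_len(d), function(j) {
    nz <- which(abs(K[, j]) > 1e-13)
    list(idx = nz, k = K[nz, j])
  })

  fluxes <- matrix(0, N_s, N)
  v <- vp + as.numeric(K %*% x)
  with_seed(seed, {
    total <- burn_in + N_s * thin
    kept <- 0L
    for (sweep in seq_len(total)) {
      for (j in seq_len(d)) {
        sj <- supp[[j]]
        vj <- v[sj$idx]
        kj <- sj$k
        ## interval for delta = x_j' - x_j: lo <= v + kj * delta <= hi
        dl <- (lo[sj$idx] - vj) / kj
        du <- (hi[sj$idx] - vj) / kj
        t_lo <- max(pmin(dl, du))
        t_hi <- min(pmax(dl, du))
        if (t_lo > t_hi) { t_lo <- t_hi <- (t_lo + t_hi) / 2 }
        if (has_gauss) {
          prec <- A[j, j]
          if (prec > 1e-12) {
            cm <- (b[j] - sum(A[j, ] * x) + prec * x[j]) / prec
            delta <- rtruncnorm1(cm - x[j], 1 / sqrt(prec), t_lo, t_hi)
          } else {
            delta <- stats::runif(1, t_lo, t_hi)
          }
        } else {
          delta <- stats::runif(1, t_lo, t_hi)
        }
        if (delta != 0) {
          x[j] <- x[j] + delta
          v[sj$idx] <- vj + kj * delta
        }
      }
      if (sweep > burn_in && (sweep - burn_in) %% thin == 0) {
        kept <- kept + 1L
        fluxes[kept, ] <- pmin(pmax(v, lo), hi)
      }
    }
  })
  colnames(fluxes) <- posterior$reaction_ids
  new_sample_set(fluxes, log_density(posterior, fluxes), seed, "ep")
}

## feasible starting coordinates for the chains
gibbs_start <- function(posterior) {
  K <- posterior$kernel$K
  vp <- posterior$particular_solution
  lo <- posterior$bounds$v_inf
  hi <- posterior$bounds$v_sup
  ## the EP mode is already interior in well-behaved cases; fall back to the
  ## phase-I point when it is not
  x <- posterior$m_x
  v <- vp + as.numeric(K %*% x)
  if (all(v >= lo - 1e-9) && all(v <= hi + 1e-9)) return(x)
  span <- max(hi[is.finite(hi)] - lo[is.finite(lo)], 1)
  lo_f <- ifelse(is.finite(lo), lo, -10 * span)
  hi_f <- ifelse(is.finite(hi), hi, 10 * span)
  obj <- function(x) {
    v <- vp + as.numeric(K %*% x)
    dd <- pmax(lo - v, 0) + pmin(hi - v, 0)
    sum(dd * dd)
  }
  grad <- function(x) {
    v <- vp + as.numeric(K %*% x)
    r <- -2 * (pmax(lo - v, 0) + pmin(hi - v, 0))
    as.numeric(crossprod(K, r))
  }
  x0 <- as.numeric(crossprod(K, (lo_f + hi_f) / 2 - vp))
  fit <- stats::optim(x0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 10))
  if (sqrt(fit$value) > 1e-6)
    stop("could not locate a feasible starting point: polytope appears empty")
  fit$par
}

new_sample_set <- function(fluxes, log_density, seed, source) {
  structure(
    list(fluxes = fluxes, log_density = as.numeric(log_density),
         seed = seed, source = source),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d samples x %d reactions (source: %s, seed %s)\n",
              nrow(x$fluxes), ncol(x$fluxes), x$source, format(x$seed)))
  invisible(x)
}

#' Hit-and-Run sampling of the flux polytope
#'
#' Uniform samples over the feasible space `L` by the Hit-and-Run Markov
#' chain restricted to the affine subspace `v_p + range(K)`: at each step a
#' random direction is drawn in kernel coordinates, the feasible chord
#' through the current point is intersected with the flux bounds, and the
#' next point is drawn uniformly on the chord scaled by the `jump` parameter
#' (the fraction of the feasible chord used per step; the proposal is
#' symmetric, so the chain remains exactly uniform-invariant for any
#' `0 < jump <= 1`). Used as the moment oracle against [ep_fit()].
#'
#' @param model A [metabolic_model()].
#' @param mdot Metabolite input/output rates; default zero (steady state).
#' @param N Number of recorded states (>= 1).
#' @param burn_in States discarded before recording.
#' @param jump Fraction of the feasible chord used per step, in (0, 1].
#' @param seed Integer seed.
#' @return A `sample_set` with `source = "hit_and_run"` and `log_density`
#'   identically 0 (the chain targets the unnormalized uniform density).
#' @export
hit_and_run <- function(model, mdot = NULL, N = 1000L, burn_in = 1000L,
                        jump = 0.5, seed = 1L) {
  stopifnot(N >= 1, burn_in >= 0, jump > 0, jump <= 1)
  validate_model(model)
  geom <- polytope_geometry(model, mdot)
  fp <- feasible_point(model, mdot, geom)
  if (!fp$feasible)
    stop("infeasible model: the flux polytope is empty (box violation ",
         format(fp$violation), ")")
  K <- geom$kb$K
  d <- geom$kb$d
  vp <- geom$vp
  lo <- model$v_inf
  hi <- model$v_sup
  Nrx <- length(vp)
  fluxes <- matrix(0, N, Nrx)
  if (d == 0) {
    fluxes <- matrix(rep(fp$v0, each = N), N, Nrx)
    colnames(fluxes) <- model$reaction_ids
    return(new_sample_set(fluxes, rep(0, N), seed, "hit_and_run"))
  }
  x <- fp$x0
  v <- vp + as.numeric(K %*% x)
  with_seed(seed, {
    total <- burn_in + N
    kept <- 0L
    for (step in seq_len(total)) {
      retries <- 0L
      repeat {
        u <- stats::rnorm(d)
        u <- u / sqrt(sum(u * u))
        w <- as.numeric(K %*% u)
        nz <- abs(w) > 1e-13
        if (!any(nz)) { retries <- retries + 1L; next }
        tl <- (lo[nz] - v[nz]) / w[nz]
        tu <- (hi[nz] - v[nz]) / w[nz]
        t_lo <- max(pmin(tl, tu))
        t_hi <- min(pmax(tl, tu))
        if (t_hi - t_lo >= 1e-12) break
        retries <- retries + 1L
        if (retries > 100L)
          stop("hit_and_run: degenerate chord after 100 direction resamples")
      }
      ## symmetric proposal on a window of jump * chord length centered at
      ## the current point; off-chord proposals are rejected (Metropolis),
      ## which keeps the chain exactly uniform-invariant for any jump <= 1
      s_half <- jump * (t_hi - t_lo) / 2
      t <- stats::runif(1, -s_half, s_half)
      if (t >= t_lo && t <= t_hi) {
        x <- x + t * u
        v <- v + t * w
      }
      if (step > burn_in) {
        kept <- kept + 1L
        fluxes[kept, ] <- pmin(pmax(v, lo), hi)
      }
    }
  })
  colnames(fluxes) <- model$reaction_ids
  new_sample_set(fluxes, rep(0, N), seed, "hit_and_run")
}

#' Compare marginal moments between two characterizations of the polytope
#'
#' Pearson correlations, across the `N` reactions, between the marginal
#' means and between the marginal variances of two sources -- typically the
#' EP posterior against a Hit-and-Run sample (the moment oracle).
#'
#' @param A A `flux_posterior` (uses `mu` / `marginal_var`) or a
#'   `sample_set` (uses empirical moments).
#' @param B A `sample_set` (or `flux_posterior`).
#' @return A `moment_comparison`: list with `r_mean`, `r_var`,
#'   `max_abs_mean_gap` and the two moment matrices.
#' @export
moment_comparison <- function(A, B) {
  mom <- function(obj) {
    if (inherits(obj, "flux_posterior"))
      list(mean = obj$mu, var = obj$marginal_var)
    else if (inherits(obj, "sample_set"))
      list(mean = colMeans(obj$fluxes),
           var = apply(obj$fluxes, 2, stats::var))
    else stop("expected a flux_posterior or sample_set")
  }
  ma <- mom(A)
  mb <- mom(B)
  if (length(ma$mean) != length(mb$mean))
    stop("sources describe different numbers of reactions")
  if (length(ma$mean) < 3)
    stop("moment comparison needs at least 3 reactions")
  structure(
    list(
      r_mean = stats::cor(ma$mean, mb$mean),
      r_var = stats::cor(ma$var, mb$var),
      max_abs_mean_gap = max(abs(ma$mean - mb$mean)),
      moments_A = ma, moments_B = mb
    ),
    class = "moment_comparison"
  )
}

#' @export
print.moment_comparison <- function(x, ...) {
  cat(sprintf("moment_comparison: r_mean = %.4f, r_var = %.4f, max |mean gap| = %.4g\n",
              x$r_mean, x$r_var, x$max_abs_mean_gap))
  invisible(x)
}

#' Write a posterior to a directory of plain-text files
#'
#' Serializes the marginal moments (`mu.tsv`), the EP Gaussian covariance
#' (`sigma.tsv`) and fit metadata (`meta.json`).
#'
#' @param posterior A `flux_posterior`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(reaction = posterior$reaction_ids, mean = posterior$mu,
               var = posterior$marginal_var),
    file.path(dir, "mu.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(posterior$Sigma, file.path(dir, "sigma.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = posterior$reaction_ids)
  meta <- list(beta = posterior$beta, converged = posterior$converged,
               iterations = posterior$iterations,
               kernel_dimension = posterior$kernel$d,
               rank = posterior$kernel$rank)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Write a sample set to TSV
#'
#' Emits `fluxes.tsv` (rows = samples, columns = reactions) and
#' `logdensity.tsv` alongside it.
#'
#' @param samples A `sample_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sample_set <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(samples$fluxes, file.path(dir, "fluxes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(log_density = samples$log_density),
                     file.path(dir, "logdensity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
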