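# EP posterior: truncated moments, closed-form limits, density, conditioning.

test_that("truncated-normal moments match numerical integration", {
  cases <- list(
    c(m = 0, s = 1, a = -1, b = 1),
    c(m = 0.3, s = 0.5, a = 0, b = 1),
    c(m = -2, s = 2, a = 0, b = 5),
    c(m = 0, s = 1, a = 1.5, b = 4),
    c(m = 1, s = 0.2, a = 0, b = 0.5)
  )
  for (cs in cases) {
    Z <- integrate(function(x) dnorm(x, cs["m"], cs["s"]),
                   cs["a"], cs["b"])$value
    m1 <- integrate(function(x) x * dnorm(x, cs["m"], cs["s"]),
                    cs["a"], cs["b"])$value / Z
    m2 <- integrate(function(x) (x - m1)^2 * dnorm(x, cs["m"], cs["s"]),
                    cs["a"], cs["b"])$value / Z
    mo <- protoflux:::truncnorm_moments(cs["m"], cs["s"], cs["a"], cs["b"])
    expect_equal(mo$mean, m1, tolerance = 1e-7)
    expect_equal(mo$var, m2, tolerance = 1e-6)
  }
})

test_that("truncated-normal moments stay sane in far tails", {
  # 12-sigma truncation: one-sided closed-form tail expansion as reference
  mo <- protoflux:::truncnorm_moments(0, 1, 12, Inf)
  lambda <- exp(dnorm(12, log = TRUE) -
                  pnorm(12, lower.tail = FALSE, log.p = TRUE))
  expect_equal(mo$mean, lambda, tolerance = 1e-10)
  expect_equal(mo$var, 1 + 12 * lambda - lambda^2, tolerance = 1e-6)
  # interval far in the tail: mean inside, variance positive and below s^2
  mo2 <- protoflux:::truncnorm_moments(0, 1, 15, 16)
  expect_gt(mo2$mean, 15)
  expect_lt(mo2$mean, 16)
  expect_gt(mo2$var, 0)
  expect_lt(mo2$var, 1)
  # flat parent over a finite box gives uniform moments exactly
  mo3 <- protoflux:::truncnorm_moments(0, Inf, 2, 6)
  expect_equal(mo3$mean, 4)
  expect_equal(mo3$var, 16 / 12)
})

test_that("EP on the segment model recovers the uniform moments", {
  post <- ep_fit(toys$segment)
  expect_true(post$converged)
  expect_equal(post$mu, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(post$marginal_var, c(1, 1) / 12, tolerance = 0.01 * 12)
  expect_equal(max(abs(post$mu - 0.5)), 0, tolerance = 0.02)
})

test_that("with no stoichiometric constraints EP means are box midpoints", {
  box <- metabolic_model(character(0), c("r1", "r2"),
                         matrix(0, 0, 2), c(0, -2), c(1, 4))
  post <- ep_fit(box)
  expect_equal(post$mu, c(0.5, 1), tolerance = 1e-8)
  expect_equal(post$marginal_var, c(1 / 12, 36 / 12), tolerance = 1e-6)
})

test_that("posterior object satisfies its structural invariants", {
  for (m in list(toys$branch, toys$diamond, toys$toy_central_carbon)) {
    post <- ep_fit(m)
    # symmetric PSD covariance
    expect_equal(post$Sigma, t(post$Sigma))
    ev <- eigen(post$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(post$Sigma)))
    # particular solution solves S v_p = mdot
    expect_lte(max(abs(m$S %*% post$particular_solution - post$mdot)), 1e-8)
    # orthonormal kernel annihilated by S
    K <- post$kernel$K
    expect_lte(max(abs(m$S %*% K)), 1e-8)
    expect_equal(crossprod(K), diag(ncol(K)), tolerance = 1e-10)
  }
})

test_that("EP and Hit-and-Run agree on the branch model", {
  post <- ep_fit(toys$branch)
  hr <- hit_and_run(toys$branch, N = 4e4, burn_in = 4e3, seed = 9)
  se <- batch_se(hr$fluxes)
  # means within 3 chain MC standard errors (EP means are exact here by
  # symmetry: v1 = 2/3, v2 = v3 = 1/3)
  expect_true(all(abs(post$mu - colMeans(hr$fluxes)) <= 3 * se))
  # marginal variances within the EP approximation error (~2 %) plus noise
  hv <- apply(hr$fluxes, 2, var)
  expect_true(all(abs(post$marginal_var - hv) / hv < 0.05))
})

test_that("log_density peaks at the projected posterior mean", {
  post <- ep_fit(toys$branch)
  smp <- sample_posterior(post, 200, seed = 3)
  K <- post$kernel$K
  vp <- post$particular_solution
  v_mode <- vp + as.numeric(K %*% crossprod(K, post$mu - vp))
  lds <- log_density(post, rbind(v_mode, smp$fluxes))
  expect_equal(which.max(lds), 1L)
  # out of bounds is -Inf
  expect_equal(log_density(post, c(2, 1, 1)), -Inf)
  # off the affine subspace is -Inf
  expect_equal(log_density(post, c(0.5, 0.4, 0.4)), -Inf)
})

test_that("density ratios match a direct quadratic-form evaluation", {
  post <- ep_fit(toys$toy_central_carbon)
  smp <- sample_posterior(post, 5, seed = 11)
  v1 <- smp$fluxes[1, ]
  v2 <- smp$fluxes[2, ]
  # independent route: quadratic form assembled from site and observation
  # precisions in flux space, restricted by hand to the subspace
  K <- post$kernel$K
  vp <- post$particular_solution
  W <- post$classes$W
  q <- post$site_q
  quad <- function(v) {
    x <- as.numeric(crossprod(K, v - vp))
    tt <- as.numeric(crossprod(W, x))
    mt <- post$site_r / post$site_q
    -0.5 * sum(q * (tt - mt)^2)
  }
  d_direct <- quad(v1) - quad(v2)
  d_pkg <- log_density(post, v1) - log_density(post, v2)
  expect_equal(d_pkg, d_direct, tolerance = 1e-8)
})

test_that("conditioning on an observed flux moves the posterior onto it", {
  post <- condition_on_observed_flux(toys$segment, list(r2 = c(0.7, 0.01)))
  expect_equal(post$mu[1], 0.7, tolerance = 0.02)
  expect_equal(post$mu[2], 0.7, tolerance = 0.02)

  postb <- condition_on_observed_flux(toys$branch, list(v1 = c(1.0, 0.01)))
  expect_equal(postb$mu[2] + postb$mu[3], 1.0, tolerance = 0.03)
  # the Gibbs sampler honors the observation factors
  smp <- sample_posterior(postb, 4000, seed = 2)
  expect_equal(mean(smp$fluxes[, 1]), 1.0, tolerance = 0.02)

  expect_error(
    condition_on_observed_flux(toys$segment, list(r2 = c(1.5, 0.01))),
    "outside its bounds")
  expect_error(condition_on_observed_flux(toys$segment, list()),
               "empty")
})

test_that("infeasible polytopes fail fast", {
  m <- metabolic_model("A", c("r1", "r2"), matrix(c(1, -1), 1, 2),
                       c(0, 0.8), c(0.5, 1))
  expect_error(ep_fit(m), "infeasible")
  expect_error(hit_and_run(m, N = 10), "infeasible")
})
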