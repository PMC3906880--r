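# Small helper: params object for hand-built tests.
toy_params <- function(K, beta, D, sigma2, pi = rep(1 / K, K)) {
  cormclust:::new_clmm_params(K, pi, beta, D, sigma2)
}

test_that("marginal log-likelihood matches closed forms and a dense oracle", {
  # single observation at the mean, no random effects
  des <- list(X = matrix(1, 1, 1), Z = matrix(0, 1, 0))
  par <- toy_params(1, matrix(2, 1, 1), list(matrix(0, 0, 0)), sigma2 = 0.5)
  expect_equal(marginal_loglik_gene(2, des, 1, par),
               -0.5 * log(2 * pi * 0.5))

  # doubling sigma2 with y at the mean lowers it by (n/2) log 2
  des3 <- list(X = matrix(1, 3, 1), Z = matrix(0, 3, 0))
  par1 <- toy_params(1, matrix(0, 1, 1), list(matrix(0, 0, 0)), sigma2 = 1)
  par2 <- toy_params(1, matrix(0, 1, 1), list(matrix(0, 0, 0)), sigma2 = 2)
  y0 <- c(0, 0, 0)
  expect_equal(marginal_loglik_gene(y0, des3, 1, par1) -
                 marginal_loglik_gene(y0, des3, 1, par2),
               1.5 * log(2))

  # n = 3, q = 1: dense-covariance oracle computed with explicit inversion
  X <- cbind(1, c(0, 1, 2)); Z <- matrix(c(1, 1, 1), 3, 1)
  beta <- c(0.5, -0.2); Dm <- matrix(0.3, 1, 1); s2 <- 0.7
  y <- c(0.4, -0.1, 0.9)
  V <- Z %*% Dm %*% t(Z) + s2 * diag(3)
  r <- y - drop(X %*% beta)
  oracle <- -0.5 * (3 * log(2 * pi) + log(det(V)) +
                      drop(t(r) %*% solve(V) %*% r))
  par <- toy_params(1, matrix(beta, 1, 2), list(Dm), s2)
  expect_equal(marginal_loglik_gene(y, list(X = X, Z = Z), 1, par), oracle)

  expect_error(marginal_loglik_gene(c(1, 2), des3, 1, par1), "rows")
})

test_that("E step posteriors match brute-force Gaussian densities", {
  # two genes, two clusters, q = 0, two observations each
  P <- rbind(g1 = c(0.1, 0.2), g2 = c(2.0, 1.9))
  ds <- matrix_dataset(P)
  spec <- design_spec(degree = 0L, n_interior_knots = 0L,
                      time_range = c(0, 3), random_design = "none")
  beta <- matrix(c(0, 2), 2, 1)
  par <- toy_params(2, beta, rep(list(matrix(0, 0, 0)), 2),
                    sigma2 = c(0.5, 0.5), pi = c(0.3, 0.7))
  es <- clmm_e_step(ds, spec, par)
  dens <- function(y, mu, s2) prod(stats::dnorm(y, mu, sqrt(s2)))
  for (g in 1:2) {
    f <- c(dens(P[g, ], 0, 0.5), dens(P[g, ], 2, 0.5))
    post <- (c(0.3, 0.7) * f) / sum(c(0.3, 0.7) * f)
    expect_equal(unname(es$posterior[g, ]), post)
  }
  expect_equal(es$loglik,
               sum(log(c(0.3 * dens(P[1, ], 0, 0.5) + 0.7 * dens(P[1, ], 2, 0.5),
                         0.3 * dens(P[2, ], 0, 0.5) + 0.7 * dens(P[2, ], 2, 0.5)))))
})

test_that("E step degenerate cases: single component and symmetric ties", {
  P <- rbind(g1 = c(0, 1), g2 = c(1, 0))
  ds <- matrix_dataset(P)
  spec <- design_spec(degree = 0L, n_interior_knots = 0L,
                      time_range = c(0, 3), random_design = "none")
  par1 <- toy_params(1, matrix(0.5, 1, 1), list(matrix(0, 0, 0)), 1)
  expect_equal(clmm_e_step(ds, spec, par1)$posterior,
               matrix(1, 2, 1), ignore_attr = TRUE)

  # gene equidistant from both components: posterior (1/2, 1/2)
  par2 <- toy_params(2, matrix(c(0, 1), 2, 1),
                     rep(list(matrix(0, 0, 0)), 2), c(1, 1))
  es <- clmm_e_step(ds, spec, par2)
  expect_equal(unname(es$posterior), matrix(0.5, 2, 2))
})

test_that("E step random-effect moments agree with the dense BLUP formula", {
  set.seed(4)
  P <- matrix(rnorm(8), 2, 4)
  n <- 4
  obs <- data.frame(condition = rep(c("A", "B"), each = 2),
                    replicate = "r1", time = c(1, 2, 1, 2))
  ds <- expression_dataset(P, obs, c("g1", "g2"))
  spec <- design_spec(degree = 1L, n_interior_knots = 0L, time_range = c(0, 3),
                      random_design = "per-condition-intercept")
  beta <- matrix(c(0.2, 0.1), 1, 2)
  Dm <- matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2)
  s2 <- 0.3
  par <- toy_params(1, beta, list(Dm), s2)
  es <- clmm_e_step(ds, spec, par)
  fd <- cormclust:::full_design(ds, spec)
  V <- fd$Z %*% Dm %*% t(fd$Z) + s2 * diag(n)
  for (g in 1:2) {
    r <- P[g, ] - drop(fd$X %*% t(beta))
    bh <- drop(Dm %*% t(fd$Z) %*% solve(V, r))
    Cg <- Dm - Dm %*% t(fd$Z) %*% solve(V) %*% fd$Z %*% Dm
    expect_equal(unname(es$bhat[[1]][g, ]), bh)
    expect_equal(matrix(es$C[[1]][g, ], 2, 2), Cg)
  }
})

test_that("M step reduces to weighted least squares oracles", {
  # q = 0, K = 1, saturated design: beta = column means, sigma2 = mean sq resid
  set.seed(2)
  P <- matrix(rnorm(15), 3, 5)
  ds <- matrix_dataset(P)
  spec <- design_spec(random_design = "none", basis = "identity",
                      time_range = c(0, 6))
  par0 <- toy_params(1, matrix(0, 1, 5), list(matrix(0, 0, 0)), 1)
  es <- clmm_e_step(ds, spec, par0)
  par1 <- clmm_m_step(ds, spec, es, par0)
  expect_equal(drop(par1$beta), colMeans(P))
  expect_equal(par1$sigma2,
               sum(sweep(P, 2, colMeans(P))^2) / 15)

  # hard posteriors, q = 0, spline design: per-cluster pooled OLS via lm
  set.seed(3)
  P2 <- matrix(rnorm(4 * 6), 4, 6)
  ds2 <- matrix_dataset(P2)
  spec2 <- design_spec(degree = 1L, n_interior_knots = 0L,
                       time_range = c(1, 6), random_design = "none")
  X <- bspline_basis(1:6, spec2)
  es2 <- list(posterior = matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2),
              bhat = rep(list(matrix(0, 4, 0)), 2),
              C = rep(list(matrix(0, 4, 0)), 2))
  par0 <- toy_params(2, matrix(0, 2, 2), rep(list(matrix(0, 0, 0)), 2),
                     c(1, 1))
  par1 <- clmm_m_step(ds2, spec2, es2, par0)
  for (k in 1:2) {
    genes <- if (k == 1) 1:2 else 3:4
    yy <- as.vector(t(P2[genes, ]))
    XX <- rbind(X, X)
    ols <- stats::lm.fit(XX, yy)
    expect_equal(unname(par1$beta[k, ]), unname(ols$coefficients))
    expect_equal(par1$sigma2[k], sum(ols$residuals^2) / 12)
  }
  expect_equal(par1$pi, c(0.5, 0.5))

  # equal soft posteriors across clusters give identical parameters
  es3 <- list(posterior = matrix(0.5, 4, 2),
              bhat = rep(list(matrix(0, 4, 0)), 2),
              C = rep(list(matrix(0, 4, 0)), 2))
  par3 <- clmm_m_step(ds2, spec2, es3, par0)
  expect_equal(par3$beta[1, ], par3$beta[2, ])
  expect_equal(par3$sigma2[1], par3$sigma2[2])
})

test_that("EM fit recovers the two-cluster linear benchmark partition", {
  sim <- simulate_clm_benchmark(seed = 99)
  expect_equal(dim(sim$dataset), c(8L, 100L))
  fit <- fit_clmm(sim$dataset, clm_benchmark_design(), K = 2, n_restarts = 3,
                  seed = 1)
  expect_equal(ari(fit$map_labels, sim$labels), 1)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("K = 1 is the single mixed model: posterior one, lme4 agreement", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 40, K = 1, miss_frac = 0),
                                 seed = 5)
  spec <- design_spec(condition_blocking = TRUE,
                      random_design = "per-condition-intercept")
  fit <- fit_clmm(sim$dataset, spec, K = 1, n_restarts = 1, seed = 1,
                  max_iter = 2000, tol = 1e-12)
  expect_true(all(fit$posterior == 1))

  # independent oracle: lme4 ML fit of the same model
  ds <- sim$dataset
  fd <- cormclust:::full_design(ds, spec)
  long <- data.frame(y = as.vector(t(ds$values)),
                     gene = rep(ds$genes, each = ncol(ds$values)),
                     cond = rep(ds$observations$condition,
                                length(ds$genes)))
  Xrep <- fd$X[rep(seq_len(nrow(fd$X)), length(ds$genes)), ]
  lfit <- lme4::lmer(y ~ 0 + Xrep + (0 + cond | gene), data = long,
                     REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)), tolerance = 1e-5)
})

test_that("BLUPs shrink to zero and match the dense formula", {
  # toy n = 4, q = 1 oracle
  set.seed(6)
  spec <- design_spec(degree = 1L, n_interior_knots = 0L, time_range = c(1, 4),
                      random_design = "per-condition-intercept")
  X <- bspline_basis(1:4, spec); Z <- matrix(1, 4, 1)
  beta <- c(0.3, 0.2); Dm <- matrix(0.6, 1, 1); s2 <- 0.4
  y <- drop(X %*% beta) + c(0.5, -0.2, 0.1, 0.3)
  obs <- data.frame(condition = "A", replicate = "r1", time = 1:4)
  ds <- expression_dataset(matrix(y, 1, 4), obs, "g1")
  par <- toy_params(1, matrix(beta, 1, 2), list(Dm), s2)
  es <- clmm_e_step(ds, spec, par)
  V <- Z %*% Dm %*% t(Z) + s2 * diag(4)
  oracle <- drop(Dm %*% t(Z) %*% solve(V, y - drop(X %*% beta)))
  expect_equal(unname(es$bhat[[1]][1, ]), oracle)

  # y exactly at the cluster mean: BLUP is zero
  ds0 <- expression_dataset(matrix(drop(X %*% beta), 1, 4), obs, "g1")
  es0 <- clmm_e_step(ds0, spec, par)
  expect_equal(unname(es0$bhat[[1]][1, ]), 0)

  # D -> 0 shrinks the BLUP to zero
  parD <- toy_params(1, matrix(beta, 1, 2), list(matrix(1e-12, 1, 1)), s2)
  esD <- clmm_e_step(ds, spec, parD)
  expect_lt(abs(esD$bhat[[1]][1, ]), 1e-10)

  # blup() returns the MAP-cluster prediction from a real fit
  sim <- simulate_lwr_timecourse(sim_spec(G = 30, K = 2), seed = 8)
  spec2 <- design_spec(condition_blocking = TRUE)
  fit <- fit_clmm(sim$dataset, spec2, K = 2, n_restarts = 2, seed = 3)
  esf <- clmm_e_step(sim$dataset, spec2, fit$params)
  g <- 7L
  expect_equal(blup(fit, g), fit$blups$bhat[g, ])
  expect_equal(unname(blup(fit, g)),
               unname(esf$bhat[[fit$map_labels[g]]][g, ]))
  expect_error(blup(fit, "nonexistent"), "unknown gene")
})

test_that("prediction for new genes reuses the frozen parameters", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 40, K = 2, miss_frac = 0),
                                 seed = 10)
  spec <- design_spec(condition_blocking = TRUE)
  fit <- fit_clmm(sim$dataset, spec, K = 2, n_restarts = 2, seed = 2)
  designs <- build_designs(sim$dataset, spec)

  # a training gene predicts to its own posterior row
  g <- 5L
  y <- sim$dataset$values[g, sim$dataset$mask[g, ]]
  pr <- predict_new_gene(fit$params, y, designs[[g]])
  expect_equal(pr$posterior, unname(fit$posterior[g, ]), tolerance = 1e-8)
  expect_equal(pr$map, unname(fit$map_labels[g]))

  # a profile lying exactly on a cluster mean goes to that cluster
  full <- cormclust:::full_design(sim$dataset, spec)
  mu1 <- drop(full$X %*% fit$params$beta[1, ])
  pr1 <- predict_new_gene(fit$params, mu1, list(X = full$X, Z = full$Z))
  expect_equal(pr1$map, 1L)

  # a half-masked profile equals the computation on the subsetted design
  keep <- seq(1, length(mu1), by = 2)
  ysub <- sim$dataset$values[g, keep]
  prsub <- predict_new_gene(fit$params, ysub,
                            list(X = full$X[keep, ], Z = full$Z[keep, ]))
  ds_masked <- mask_entries(sim$dataset,
                            cbind(g, setdiff(seq_along(mu1), keep)))
  es <- clmm_e_step(ds_masked, spec, fit$params)
  expect_equal(prsub$posterior, unname(es$posterior[g, ]))

  expect_error(predict_new_gene(fit$params, y, list(X = designs[[g]]$X[, 1:3],
                                                    Z = designs[[g]]$Z)),
               "dimension|width")
})

test_that("fitted cluster profiles follow the design", {
  # constant coefficients on a partition-of-unity basis give a flat profile
  spec <- design_spec(time_range = c(0, 120))
  par <- toy_params(1, matrix(0.8, 1, 11), list(matrix(0, 0, 0)), 1)
  par$spec <- spec; par$conditions <- "WT"
  prof <- fitted_cluster_profile(par, times = seq(0, 120, 10))
  expect_equal(drop(prof), rep(0.8, 13), ignore_attr = TRUE)

  # blocked fit with a zeroed block yields an identically zero profile
  spec2 <- design_spec(condition_blocking = TRUE)
  beta2 <- matrix(c(stats::rnorm(11), rep(0, 11)), 1, 22)
  par2 <- toy_params(1, beta2, list(matrix(0, 0, 0)), 1)
  par2$spec <- spec2; par2$conditions <- c("SM", "WT")
  expect_equal(drop(fitted_cluster_profile(par2, "WT", seq(0, 120, 15))),
               rep(0, 9), ignore_attr = TRUE)

  # profile at the observed times equals the design rows times beta
  ds <- toy_dataset(conditions = "WT", times = seq(0, 120, 10))
  spec3 <- design_spec()
  X <- build_designs(ds, spec3)[[1]]$X
  beta3 <- matrix(stats::rnorm(11), 1, 11)
  par3 <- toy_params(1, beta3, list(matrix(0, 0, 0)), 1)
  par3$spec <- spec3; par3$conditions <- "WT"
  prof3 <- fitted_cluster_profile(par3, "WT", ds$observations$time[1:12])
  expect_equal(drop(prof3), drop(X[1:12, ] %*% t(beta3)))

  expect_error(fitted_cluster_profile(par3, "WT", c(0, 130)), "outside")
})

test_that("CLM is the q = 0 special case: D = 0 matches the q = 0 loglik", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 10, K = 2, miss_frac = 0),
                                 seed = 3)
  spec_q <- design_spec(condition_blocking = TRUE,
                        random_design = "per-condition-intercept")
  spec_0 <- design_spec(condition_blocking = TRUE, random_design = "none")
  beta <- matrix(stats::rnorm(2 * 22), 2, 22)
  par_q <- toy_params(2, beta, rep(list(matrix(0, 2, 2)), 2), c(0.5, 0.8))
  par_0 <- toy_params(2, beta, rep(list(matrix(0, 0, 0)), 2), c(0.5, 0.8))
  ll_q <- clmm_e_step(sim$dataset, spec_q, par_q)$loglik
  ll_0 <- clmm_e_step(sim$dataset, spec_0, par_0)$loglik
  expect_equal(ll_q, ll_0, tolerance = 1e-8)
})

test_that("EM log-likelihood traces are monotone across settings", {
  for (s in 1:4) {
    sim <- simulate_lwr_timecourse(
      sim_spec(G = 30, K = 2, random_sd = 0.15, sigma = 0.3), seed = s)
    spec <- design_spec(condition_blocking = TRUE)
    for (opts in list(list(), list(hard_assign = TRUE),
                      list(equal_proportions = TRUE, shared_sigma2 = TRUE))) {
      fit <- do.call(fit_clmm, c(list(sim$dataset, spec, K = 2,
                                      n_restarts = 1, seed = s), opts))
      expect_true(all(diff(fit$loglik_trace) >= -1e-8),
                  info = sprintf("seed %d opts %s", s,
                                 paste(names(opts), collapse = ",")))
    }
  }
})

test_that("masking zero cells reproduces the complete fit bit-for-bit", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 20, K = 2, miss_frac = 0),
                                 seed = 12)
  ds <- sim$dataset
  ds2 <- mask_entries(ds, matrix(integer(0), 0, 2))
  spec <- design_spec(condition_blocking = TRUE)
  f1 <- fit_clmm(ds, spec, K = 2, n_restarts = 2, seed = 4)
  f2 <- fit_clmm(ds2, spec, K = 2, n_restarts = 2, seed = 4)
  expect_identical(f1$params$beta, f2$params$beta)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("gene order permutation permutes E-step outputs correspondingly", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 12, K = 2), seed = 13)
  ds <- sim$dataset
  perm <- rev(seq_along(ds$genes))
  dsp <- expression_dataset(ds$values[perm, ], ds$observations,
                            ds$genes[perm], ds$mask[perm, ])
  spec <- design_spec(condition_blocking = TRUE)
  beta <- matrix(stats::rnorm(2 * 22, sd = 0.3), 2, 22)
  par <- toy_params(2, beta, rep(list(diag(0.01, 2)), 2), c(0.1, 0.1))
  e1 <- clmm_e_step(ds, spec, par)
  e2 <- clmm_e_step(dsp, spec, par)
  expect_equal(unname(e2$posterior), unname(e1$posterior[perm, ]))
  expect_equal(e2$loglik, e1$loglik)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_lwr_timecourse(sim_spec(G = 20, K = 2), seed = 21)
  spec <- design_spec(condition_blocking = TRUE)
  f1 <- fit_clmm(sim$dataset, spec, K = 2, n_restarts = 3, seed = 9)
  f2 <- fit_clmm(sim$dataset, spec, K = 2, n_restarts = 3, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})
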