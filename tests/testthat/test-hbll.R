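test_that("log posterior, gradient and Hessian match finite differences", {
  pr <- blr_fixture()$prob
  ## value at zero: n * log(0.5) with zero prior energy
  expect_equal(log_posterior(numeric(3), pr), 20 * log(0.5), tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:200) {
      w <- rnorm(3, sd = 2)
      g <- log_posterior_grad(w, pr)
      fd <- fd_grad(function(x) log_posterior(x, pr), w)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
    }
    for (i in 1:10) {
      w <- rnorm(3, sd = 2)
      Hm <- hessian_at(w, pr)
      fdH <- sapply(1:3, function(j) {
        e <- numeric(3); e[j] <- 1e-5
        -(log_posterior_grad(w + e, pr) - log_posterior_grad(w - e, pr)) / 2e-5
      })
      expect_lt(max(abs(Hm - fdH) / pmax(abs(fdH), 1e-4)), 1e-4)
      expect_equal(Hm, t(Hm), tolerance = 1e-14)
      expect_gt(min(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
  ## empty problem: curvature is the prior alone
  pr0 <- blr_problem(matrix(0, 0, 2), numeric(0), 3)
  expect_equal(hessian_at(numeric(3), pr0), diag(3, 3))
  expect_error(log_posterior(numeric(2), pr), "dimension")
  expect_error(log_posterior(c(NA, 1, 1), pr), "finite")
})

test_that("MAP estimation is exact on oracle problems and shrinks under strong priors", {
  ## symmetric balanced one-feature problem: bias near zero
  H <- matrix(c(-2, -1, 1, 2), 4, 1)
  pr_sym <- blr_problem(H, c(0, 0, 1, 1), 1)
  w <- map_fit(pr_sym)
  expect_lt(abs(w[2]), 1e-6)
  ## 2-parameter problem vs dense grid search over [-5, 5]^2
  pr2 <- blr_problem(matrix(rnorm(30, sd = 1.5), 30, 1),
                     withr::with_seed(4, rbinom(30, 1, 0.5)), 0.5)
  w2 <- map_fit(pr2)
  grid <- as.matrix(expand.grid(seq(-5, 5, 0.01), seq(-5, 5, 0.01)))
  lp <- apply(grid, 1, function(g) log_posterior(g, pr2))
  expect_equal(w2, unname(grid[which.max(lp), ]), tolerance = 0.011)
  ## ridge limit
  pr_big <- blr_fixture(tau = 1e6)$prob
  expect_lt(sqrt(sum(map_fit(pr_big)^2)), 1e-2)
  ## gradient norm tolerance honoured, deterministic
  pr <- blr_fixture(seed = 3)$prob
  wm <- map_fit(pr)
  expect_lt(sqrt(sum(log_posterior_grad(wm, pr)^2)), 1e-5)
  expect_identical(wm, map_fit(pr))
})

test_that("the leapfrog integrator is time-reversible and near-exact for small steps", {
  gr <- function(q) -q
  q0 <- c(0.3, -1.1); p0 <- c(0.5, 0.2)
  f1 <- qsarcalib:::.leapfrog(q0, p0, gr, identity, 0.1, 25)
  f2 <- qsarcalib:::.leapfrog(f1$q, -f1$p, gr, identity, 0.1, 25)
  expect_lt(max(abs(f2$q - q0)), 1e-8)
  expect_lt(max(abs(-f2$p - p0)), 1e-8)
  ## acceptance approaches 1 as the stepsize shrinks
  s <- hmc_sample(function(w) -w^2 / 2, function(w) -w, 0.5,
                  hmc_config(n_burnin = 10, n_samples = 200,
                             leapfrog_steps = 10, stepsize = 1e-3, seed = 4))
  expect_gt(s$acceptance_rate, 0.999)
})

test_that("HMC reproduces analytic moments of Gaussian targets", {
  ## standard normal moments
  s <- hmc_sample(function(w) -w^2 / 2, function(w) -w, 0,
                  hmc_config(n_burnin = 200, n_samples = 8000,
                             leapfrog_steps = 20, stepsize = 0.1, seed = 1))
  x <- as.numeric(s$samples)
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(x) - 1), 0.08)
  ## correlated 2-D Gaussian with non-identity mass: covariance within
  ## Monte Carlo error of the analytic covariance (detailed-balance proxy)
  Sig <- matrix(c(1, 0.6, 0.6, 2), 2); P <- solve(Sig)
  s2 <- hmc_sample(function(w) -sum(w * (P %*% w)) / 2,
                   function(w) -as.numeric(P %*% w), c(0, 0),
                   hmc_config(n_burnin = 500, n_samples = 20000,
                              leapfrog_steps = 18, stepsize = 0.13,
                              inverse_mass_matrix = Sig, seed = 5))
  cv <- cov(s2$samples)
  for (j in 1:2) {
    ## the variance estimator mixes at the rate of the squared samples
    mc_se <- Sig[j, j] * sqrt(2 / ess(s2$samples[, j]^2))
    expect_lt(abs(cv[j, j] - Sig[j, j]), 3 * mc_se + 0.02)
  }
  expect_lt(abs(cv[1, 2] - 0.6), 0.1)
  ## determinism and divergence guard
  s3 <- hmc_sample(function(w) -w^2 / 2, function(w) -w, 0,
                   hmc_config(10, 50, 5, 0.1, seed = 9))
  s4 <- hmc_sample(function(w) -w^2 / 2, function(w) -w, 0,
                   hmc_config(10, 50, 5, 0.1, seed = 9))
  expect_identical(s3$samples, s4$samples)
  expect_error(
    hmc_sample(function(w) if (w > 0) log(w) else -Inf, function(w) 1 / w, -1,
               hmc_config(10, 50, 5, 0.1, seed = 1)),
    "not finite")
})

test_that("posterior moments match dense quadrature on a small logistic regression", {
  fix <- blr_fixture(n = 25, h = 2, tau = 1, seed = 6)
  pr <- fix$prob
  w_map <- map_fit(pr)
  Hm <- hessian_at(w_map, pr)
  sd_map <- sqrt(diag(solve(Hm)))
  quad <- blr_quad_moments(fix$H, fix$y, fix$tau, w_map, 6 * sd_map,
                           n_grid = 51)
  post <- hmc_sample(function(w) log_posterior(w, pr),
                     function(w) log_posterior_grad(w, pr), w_map,
                     hmc_config(n_burnin = 300, n_samples = 10000,
                                leapfrog_steps = 25, stepsize = 0.12,
                                inverse_mass_matrix = chol2inv(chol(Hm)),
                                seed = 2))
  for (j in 1:3) {
    se <- sd(post$samples[, j]) / sqrt(ess(post$samples[, j]))
    expect_lt(abs(mean(post$samples[, j]) - quad$mean[j]), 3 * se + 1e-3)
    var_se <- quad$var[j] * sqrt(2 / ess(post$samples[, j]^2))
    expect_lt(abs(var(post$samples[, j]) - quad$var[j]), 3 * var_se + 5e-3)
  }
})

test_that("curvature preconditioning decorrelates an ill-conditioned Gaussian", {
  Sig <- diag(c(1, 0.01)); P <- solve(Sig)   # condition number 100
  lpG <- function(w) -sum(w * (P %*% w)) / 2
  grG <- function(w) -as.numeric(P %*% w)
  lag1 <- function(S) mean(sapply(1:2, function(j)
    cor(S[-1, j], S[-nrow(S), j])))
  s_id <- hmc_sample(lpG, grG, c(0, 0),
                     hmc_config(200, 3000, 12, 0.15, "identity", seed = 3))
  s_pc <- hmc_sample(lpG, grG, c(0, 0),
                     hmc_config(200, 3000, 12, 0.15, Sig, seed = 3))
  expect_lt(lag1(s_pc$samples), lag1(s_id$samples))
})

test_that("the fitted Bayesian last layer is seeded, Jensen-damped and prior-dominated at large tau", {
  gen <- toy_dataset(n = 300, d = 64, k = 12, seed = 4)
  d <- gen$data; split <- make_split(3, 4)
  m <- train_mlp(d, split, mlp_config(hidden_size = 4, dropout_rate = 0.1,
                                      max_epochs = 15, patience = 15, seed = 1))
  cfg <- hmc_config(n_burnin = 100, n_samples = 400, leapfrog_steps = 20,
                    stepsize = 0.15, seed = 2)
  post <- fit_hbll(m, d, split, prior_precision = 1, cfg)
  post2 <- fit_hbll(m, d, split, prior_precision = 1, cfg)
  expect_identical(post$samples, post2$samples)
  expect_gt(post$acceptance_rate, 0.5)
  X_te <- d$features[which(d$fold_id == 4), ]
  p <- hbll_predict(post, m, X_te)
  expect_true(all(p > 0 & p < 1))
  ## degenerate posterior: all samples equal -> plain sigmoid
  w_fix <- post$map
  deg <- post; deg$samples <- matrix(w_fix, 50, length(w_fix), byrow = TRUE)
  Ht <- cbind(hidden_features(m, X_te), 1)
  expect_equal(hbll_predict(deg, m, X_te),
               clip_probs(plogis(as.numeric(Ht %*% w_fix))), tolerance = 1e-12)
  ## Jensen damping: where sampled logits share a sign, the averaged
  ## probability is no more extreme than the plug-in MAP probability
  Z <- Ht %*% t(post$samples)
  same_sign <- apply(Z, 1, function(z) all(z > 0) || all(z < 0))
  p_map <- plogis(as.numeric(Ht %*% post$map))
  mc_se <- apply(plogis(Z), 1, sd) / sqrt(ncol(Z))
  idx <- which(same_sign)
  expect_true(all(abs(p[idx] - 0.5) <=
                    abs(p_map[idx] - 0.5) + 3 * mc_se[idx] + 1e-9))
  ## enormous prior precision pins every prediction at 1/2
  post_inf <- fit_hbll(m, d, split, prior_precision = 1e8, cfg)
  expect_lt(max(abs(hbll_predict(post_inf, m, X_te) - 0.5)), 0.01)
  expect_error(hbll_predict(post, m, d$features[, 1:10]), "mismatch")
})

test_that("prior-precision tuning scans the grid and honours the criterion direction", {
  gen <- toy_dataset(n = 300, d = 64, k = 12, seed = 5)
  d <- gen$data; split <- make_split(3, 4)
  m <- train_mlp(d, split, mlp_config(hidden_size = 4, max_epochs = 10,
                                      patience = 10, seed = 1))
  cfg <- hmc_config(n_burnin = 50, n_samples = 200, leapfrog_steps = 15,
                    stepsize = 0.15, seed = 3)
  ## singleton grid returns its element
  one <- tune_prior_precision(m, d, split, tau_grid = 2, cfg)
  expect_equal(one$best_tau, 2)
  tune <- tune_prior_precision(m, d, split, tau_grid = c(0.01, 1, 100), cfg)
  expect_equal(sort(tune$report$tau), c(0.01, 1, 100))
  ## selected tau is no worse than the grid extremes on the criterion
  sc <- tune$report$score
  expect_lte(min(sc[tune$report$tau == tune$best_tau]), min(sc[c(1, 3)]))
  expect_error(tune_prior_precision(m, d, split, numeric(0), cfg), "empty")
})

test_that("posterior archives round-trip", {
  s <- hmc_sample(function(w) -w^2 / 2, function(w) -w, 0,
                  hmc_config(10, 40, 5, 0.1, seed = 2))
  s$map <- 0; s$tau <- 1
  path <- withr::local_tempfile(fileext = ".json")
  save_posterior(s, path)
  back <- load_posterior(path)
  expect_equal(back$samples, s$samples, tolerance = 1e-12)
  expect_equal(back$acceptance_rate, s$acceptance_rate)
  expect_equal(back$config$leapfrog_steps, 5L)
})
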