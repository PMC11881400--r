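## HMC Bayesian last layer: replace the trained MLP's output layer with a
## Bayesian logistic regression on the frozen hidden features. The posterior
## over the h+1 last-layer parameters (weights + bias, isotropic Gaussian
## prior with precision tau) is explored by vanilla HMC with a Metropolis
## correction, initialized at the MAP and preconditioned by the MAP Hessian
## used as the inverse mass matrix. Predictions average the per-sample
## sigmoid probabilities.

#' Bayesian logistic regression problem on frozen features
#'
#' @param H hidden feature matrix (`n x h`), frozen.
#' @param y 0/1 labels of length `n`.
#' @param prior_precision isotropic Gaussian prior precision `tau > 0` on
#'   all `h + 1` parameters including the bias.
#' @return object of class `blr_problem` carrying the bias-augmented design
#'   `Ht = [H | 1]`.
#' @export
blr_problem <- function(H, y, prior_precision) {
  H <- as.matrix(H)
  if (!all(is.finite(H))) stop("hidden features must be finite")
  y <- as.numeric(y)
  if (nrow(H) != length(y)) stop("H and y differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.numeric(prior_precision) || length(prior_precision) != 1L ||
      !is.finite(prior_precision) || prior_precision <= 0)
    stop("prior_precision must be a positive scalar")
  structure(list(Ht = cbind(H, rep(1, nrow(H))), y = y, tau = prior_precision,
                 d = ncol(H) + 1L),
            class = "blr_problem")
}

## stable log(sigmoid(z)) and log(1 - sigmoid(z))
.log_sigmoid <- function(z) ifelse(z < 0, z - log1p(exp(z)), -log1p(exp(-z)))

#' Unnormalized log posterior of the Bayesian logistic regression
#'
#' `sum_i [y_i log s(z_i) + (1 - y_i) log(1 - s(z_i))] - (tau/2) ||w||^2`
#' with `z = Ht w`.
#'
#' @param w parameter vector of length `h + 1` (bias last).
#' @param prob a [blr_problem()].
#' @return scalar log posterior (up to the normalizing constant).
#' @export
log_posterior <- function(w, prob) {
  if (length(w) != prob$d) stop("parameter dimension mismatch")
  if (!all(is.finite(w))) stop("non-finite parameters")
  z <- as.numeric(prob$Ht %*% w)
  sum(prob$y * .log_sigmoid(z) + (1 - prob$y) * .log_sigmoid(-z)) -
    prob$tau / 2 * sum(w^2)
}

#' Analytic gradient of the log posterior
#'
#' `Ht' (y - s(z)) - tau w`.
#'
#' @inheritParams log_posterior
#' @return gradient vector of length `h + 1`.
#' @export
log_posterior_grad <- function(w, prob) {
  if (length(w) != prob$d) stop("parameter dimension mismatch")
  z <- as.numeric(prob$Ht %*% w)
  as.numeric(crossprod(prob$Ht, prob$y - sigmoid(z))) - prob$tau * w
}

#' Negative Hessian of the log posterior
#'
#' `Ht' diag(s(z)(1 - s(z))) Ht + tau I`: the observed information, symmetric
#' positive definite for any `tau > 0` (reduces to `tau I` when the problem
#' has no observations).
#'
#' @inheritParams log_posterior
#' @return `(h+1) x (h+1)` SPD matrix.
#' @export
hessian_at <- function(w, prob) {
  if (length(w) != prob$d) stop("parameter dimension mismatch")
  if (nrow(prob$Ht) == 0) return(diag(prob$tau, prob$d))
  z <- as.numeric(prob$Ht %*% w)
  s <- sigmoid(z)
  Hs <- prob$Ht * sqrt(s * (1 - s))
  M <- crossprod(Hs) + diag(prob$tau, prob$d)
  (M + t(M)) / 2
}

#' Maximum a posteriori estimate
#'
#' Damped Newton iteration on the strictly concave log posterior, run until
#' the gradient norm falls below `tol` relative to its starting value (and
#' in absolute terms), with step halving to guarantee monotone ascent.
#'
#' @param prob a [blr_problem()].
#' @param tol relative gradient-norm tolerance (default `1e-6`).
#' @param max_iter Newton iteration cap.
#' @return the MAP parameter vector.
#' @export
map_fit <- function(prob, tol = 1e-6, max_iter = 100L) {
  w <- numeric(prob$d)
  g <- log_posterior_grad(w, prob)
  g0 <- max(sqrt(sum(g^2)), 1)
  f <- log_posterior(w, prob)
  for (it in seq_len(max_iter)) {
    gn <- sqrt(sum(g^2))
    if (gn <= tol * g0 || gn <= tol) return(w)
    step <- solve(hessian_at(w, prob), g)
    alpha <- 1
    repeat {
      w_new <- w + alpha * step
      f_new <- log_posterior(w_new, prob)
      if (f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10)
        stop("MAP optimizer stalled: no ascent direction found (iter ", it, ")")
    }
    w <- w_new; f <- f_new
    g <- log_posterior_grad(w, prob)
  }
  gn <- sqrt(sum(g^2))
  if (gn <= tol * g0 || gn <= tol) return(w)
  stop(sprintf("MAP did not converge in %d iterations (|grad| = %.3g)",
               max_iter, gn))
}

#' HMC sampler configuration
#'
#' Defaults mirror the production settings (500 burn-in, 1000 samples,
#' `L = 1200` leapfrog steps of size `eps = 0.01`, one chain); desk-scale
#' runs typically shrink `leapfrog_steps` to keep runtimes in seconds.
#'
#' @param n_burnin discarded warm-up iterations.
#' @param n_samples retained samples.
#' @param leapfrog_steps leapfrog steps per trajectory (`L`).
#' @param stepsize integrator step size (`eps`).
#' @param inverse_mass_matrix SPD matrix `A` used as the inverse mass
#'   (kinetic energy `p' A p / 2`, momenta from `N(0, A^-1)`), or
#'   `"identity"`.
#' @param seed RNG seed.
#' @param n_chains independent chains (samples concatenated).
#' @return an `hmc_config` list.
#' @export
hmc_config <- function(n_burnin = 500L, n_samples = 1000L,
                       leapfrog_steps = 1200L, stepsize = 0.01,
                       inverse_mass_matrix = "identity", seed = 1L,
                       n_chains = 1L) {
  if (!identical(inverse_mass_matrix, "identity")) {
    A <- as.matrix(inverse_mass_matrix)
    if (!isSymmetric(A, tol = 1e-8)) stop("inverse mass matrix must be symmetric")
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("inverse mass matrix must be positive definite")
    inverse_mass_matrix <- (A + t(A)) / 2
  }
  structure(list(n_burnin = .check_count(n_burnin, "n_burnin", min = 0L),
                 n_samples = .check_count(n_samples, "n_samples"),
                 leapfrog_steps = .check_count(leapfrog_steps, "leapfrog_steps"),
                 stepsize = .check_fraction(stepsize, "stepsize", 0, Inf,
                                            lo_open = TRUE),
                 inverse_mass_matrix = inverse_mass_matrix,
                 seed = .check_count(seed, "seed", min = 0L),
                 n_chains = .check_count(n_chains, "n_chains")),
            class = "hmc_config")
}

## Leapfrog integrator. A_fun(p) returns A %*% p (dK/dp).
.leapfrog <- function(q, p, grad_fn, A_fun, eps, L) {
  g <- grad_fn(q)
  if (!all(is.finite(g))) return(NULL)
  p <- p + eps / 2 * g
  for (l in seq_len(L)) {
    q <- q + eps * A_fun(p)
    g <- grad_fn(q)
    if (!all(is.finite(g)) || !all(is.finite(q))) return(NULL)
    p <- p + (if (l < L) eps else eps / 2) * g
  }
  list(q = q, p = p)
}

#' Hamiltonian Monte Carlo with Metropolis correction
#'
#' Vanilla HMC: momenta are drawn from `N(0, M)` with `M` the inverse of the
#' supplied inverse-mass matrix `A`; each proposal integrates Hamilton's
#' equations by `L` leapfrog steps of size `eps` and is accepted with
#' probability `min(1, exp(-dH))`. Trajectories hitting non-finite energies
#' are rejected and counted as divergences; the sampler errors out if more
#' than half of all iterations diverge.
#'
#' @param log_post function `w -> scalar` unnormalized log density.
#' @param grad_fn function `w -> gradient`.
#' @param init initial state (must have finite density).
#' @param cfg an [hmc_config()].
#' @return object of class `posterior_samples` with `samples`
#'   (`n_samples*n_chains x d`), `acceptance_rate`, `log_post_trace`,
#'   `n_divergent`.
#' @export
hmc_sample <- function(log_post, grad_fn, init, cfg) {
  stopifnot(inherits(cfg, "hmc_config"))
  d <- length(init)
  if (!is.finite(log_post(init))) stop("target not finite at init")
  if (identical(cfg$inverse_mass_matrix, "identity")) {
    R <- NULL
    A_fun <- identity
    draw_p <- function() rnorm(d)
    kinetic <- function(p) sum(p^2) / 2
  } else {
    A <- cfg$inverse_mass_matrix
    R <- tryCatch(chol(A), error = function(e) chol(A + diag(1e-8, d)))
    A_fun <- function(p) as.numeric(crossprod(R, R %*% p))
    draw_p <- function() backsolve(R, rnorm(d))
    kinetic <- function(p) sum((R %*% p)^2) / 2
  }
  n_iter <- cfg$n_burnin + cfg$n_samples
  all_samples <- vector("list", cfg$n_chains)
  all_trace <- vector("list", cfg$n_chains)
  acc_n <- 0L; div_n <- 0L
  for (ch in seq_len(cfg$n_chains)) {
    samples <- matrix(NA_real_, cfg$n_samples, d)
    trace <- numeric(cfg$n_samples)
    withr::with_seed(cfg$seed + ch - 1L, {
      q <- as.numeric(init)
      lp <- log_post(q)
      for (it in seq_len(n_iter)) {
        p0 <- draw_p()
        H0 <- -lp + kinetic(p0)
        traj <- .leapfrog(q, p0, grad_fn, A_fun, cfg$stepsize,
                          cfg$leapfrog_steps)
        accept <- FALSE
        if (!is.null(traj)) {
          lp_new <- log_post(traj$q)
          H1 <- -lp_new + kinetic(traj$p)
          if (is.finite(H1) && runif(1) < exp(H0 - H1)) {
            q <- traj$q; lp <- lp_new; accept <- TRUE
          }
        } else {
          div_n <- div_n + 1L
        }
        if (accept) acc_n <- acc_n + 1L
        if (it > cfg$n_burnin) {
          samples[it - cfg$n_burnin, ] <- q
          trace[it - cfg$n_burnin] <- lp
        }
      }
    })
    all_samples[[ch]] <- samples
    all_trace[[ch]] <- trace
  }
  total <- n_iter * cfg$n_chains
  if (div_n > total / 2)
    stop(sprintf("HMC persistently divergent: %d of %d trajectories non-finite",
                 div_n, total))
  structure(list(samples = do.call(rbind, all_samples),
                 acceptance_rate = acc_n / total,
                 log_post_trace = unlist(all_trace),
                 n_divergent = div_n, config = cfg),
            class = "posterior_samples")
}

#' @exportS3Method base::print
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d x %d, acceptance %.2f, %d divergent\n",
              nrow(x$samples), ncol(x$samples), x$acceptance_rate,
              x$n_divergent))
  invisible(x)
}

#' Fit the HMC Bayesian last layer
#'
#' Builds the Bayesian logistic regression on the training-fold hidden
#' features of a trained MLP, finds the MAP, preconditions the sampler with
#' the MAP curvature — the momentum covariance (mass matrix) is set to the
#' MAP Hessian, equivalently the inverse mass matrix to its inverse, which
#' de-correlates the parameter space — and samples the posterior by HMC
#' starting at the MAP.
#'
#' @param model a `trained_mlp`.
#' @param data a [bioactivity_dataset()] with folds.
#' @param split a [make_split()] split.
#' @param prior_precision Gaussian prior precision `tau`.
#' @param cfg an [hmc_config()]; its `inverse_mass_matrix` field is replaced
#'   by the inverse of the MAP Hessian.
#' @return `posterior_samples` with the MAP vector attached as `$map` and
#'   the prior precision as `$tau`.
#' @export
fit_hbll <- function(model, data, split, prior_precision,
                     cfg = hmc_config()) {
  tr <- .split_idx(data, split, "train")
  H <- hidden_features(model, data$features[tr, , drop = FALSE])
  prob <- blr_problem(H, data$labels[tr], prior_precision)
  w_map <- map_fit(prob)
  A <- chol2inv(chol(hessian_at(w_map, prob)))
  cfg2 <- hmc_config(n_burnin = cfg$n_burnin, n_samples = cfg$n_samples,
                     leapfrog_steps = cfg$leapfrog_steps,
                     stepsize = cfg$stepsize, inverse_mass_matrix = A,
                     seed = cfg$seed, n_chains = cfg$n_chains)
  post <- hmc_sample(function(w) log_posterior(w, prob),
                     function(w) log_posterior_grad(w, prob),
                     init = w_map, cfg = cfg2)
  post$map <- w_map
  post$tau <- prior_precision
  post
}

#' Posterior predictive probabilities of the Bayesian last layer
#'
#' Mean over posterior samples of `sigmoid([H | 1] w_m)` on the hidden
#' features of `X`.
#'
#' @param samples a `posterior_samples` from [fit_hbll()].
#' @param model the `trained_mlp` providing the frozen hidden layer.
#' @param X feature matrix.
#' @return probability vector (clipped strictly inside (0, 1)).
#' @export
hbll_predict <- function(samples, model, X) {
  H <- hidden_features(model, X)
  Ht <- cbind(H, 1)
  if (ncol(Ht) != ncol(samples$samples))
    stop("posterior sample dimension does not match hidden size + 1")
  P <- sigmoid(Ht %*% t(samples$samples))
  clip_probs(rowMeans(P))
}

#' Tune the prior precision on the validation fold
#'
#' Fits the Bayesian last layer for each candidate `tau`, scores the
#' validation-fold predictive probabilities by the chosen criterion
#' (minimizing `bce`/`ace`/`ece`/`brier`, maximizing `auc`/`acc`), and
#' returns the best `tau`; ties are broken toward the larger (more strongly
#' regularizing) value.
#'
#' @param model a `trained_mlp`.
#' @param data,split dataset and fold split.
#' @param tau_grid positive candidate precisions (default log-spaced
#'   `10^-3 .. 10^3`).
#' @param cfg an [hmc_config()].
#' @param criterion metric name (default `"bce"`).
#' @param n_bins bins for the binned criteria.
#' @return list with `best_tau`, `best_fit` (its `posterior_samples`) and a
#'   per-tau `report` data frame.
#' @export
tune_prior_precision <- function(model, data, split,
                                 tau_grid = 10^seq(-3, 3, by = 1),
                                 cfg = hmc_config(),
                                 criterion = c("bce", "ace", "ece", "brier",
                                               "auc", "acc"),
                                 n_bins = 10L) {
  criterion <- match.arg(criterion)
  if (!length(tau_grid)) stop("tau_grid is empty")
  va <- .split_idx(data, split, "valid")
  X_va <- data$features[va, , drop = FALSE]
  y_va <- data$labels[va]
  maximize <- criterion %in% c("auc", "acc")
  score_fn <- switch(criterion,
                     bce = bce_loss, brier = brier_score,
                     ece = function(p, y) ece(p, y, n_bins),
                     ace = function(p, y) ace(p, y, n_bins),
                     auc = auc_score, acc = accuracy_score)
  tau_grid <- sort(as.numeric(tau_grid))
  rows <- vector("list", length(tau_grid))
  fits <- vector("list", length(tau_grid))
  for (i in seq_along(tau_grid)) {
    fit <- fit_hbll(model, data, split, tau_grid[i], cfg)
    p_va <- hbll_predict(fit, model, X_va)
    rows[[i]] <- data.frame(tau = tau_grid[i], score = score_fn(p_va, y_va),
                            acceptance_rate = fit$acceptance_rate)
    fits[[i]] <- fit
  }
  report <- do.call(rbind, rows)
  s <- if (maximize) report$score else -report$score
  best <- max(which(s == max(s)))        # ties toward larger tau
  list(best_tau = report$tau[best], best_fit = fits[[best]],
       report = report, criterion = criterion)
}

#' Save / load a posterior archive
#'
#' Sample matrix, configuration and acceptance rate in one JSON file.
#'
#' @param samples a `posterior_samples`.
#' @param path file path.
#' @return invisibly, `path` / the restored object.
#' @export
save_posterior <- function(samples, path) {
  cfg <- samples$config
  obj <- list(schema = "qsarcalib/posterior/1", samples = samples$samples,
              acceptance_rate = samples$acceptance_rate,
              log_post_trace = samples$log_post_trace,
              n_divergent = samples$n_divergent,
              map = samples$map, tau = samples$tau,
              config = list(n_burnin = cfg$n_burnin, n_samples = cfg$n_samples,
                            leapfrog_steps = cfg$leapfrog_steps,
                            stepsize = cfg$stepsize, seed = cfg$seed,
                            n_chains = cfg$n_chains))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_posterior
#' @export
load_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "qsarcalib/posterior/1"))
    stop("unrecognized posterior schema: ", obj$schema)
  structure(list(samples = as.matrix(obj$samples),
                 acceptance_rate = obj$acceptance_rate,
                 log_post_trace = as.numeric(obj$log_post_trace),
                 n_divergent = as.integer(obj$n_divergent),
                 config = do.call(hmc_config, as.list(obj$config)),
                 map = if (is.null(obj$map)) NULL else as.numeric(obj$map),
                 tau = obj$tau),
            class = "posterior_samples")
}
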