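## Synthetic datasets with the statistical structure the study assumes:
## sparse clustered binary fingerprints, a sparse logistic ground truth with
## an intercept solved to hit a target active ratio, and probability vectors
## with controlled miscalibration for exercising metrics and calibrators.

#' Configuration for the synthetic fingerprint generator
#'
#' Defaults emulate a desk-scale version of a single-target bioactivity
#' extraction: a few thousand sparse fingerprints grouped into chemical
#' series (clusters), an active ratio of 0.25, and noise-free labels.
#'
#' @param n_compounds number of compounds.
#' @param n_features fingerprint width.
#' @param n_clusters number of chemical series.
#' @param bits_per_compound mean number of set bits per compound.
#' @param within_cluster_overlap probability that a member keeps each
#'   template bit of its cluster (1 = members identical to the template).
#' @param true_weight_sparsity fraction of features with nonzero ground-truth
#'   weight.
#' @param active_ratio_target desired mean of the true activity
#'   probabilities, strictly in (0, 1).
#' @param label_noise label flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 2000L, n_features = 1024L,
                             n_clusters = 40L, bits_per_compound = 40L,
                             within_cluster_overlap = 0.7,
                             true_weight_sparsity = 0.05,
                             active_ratio_target = 0.25,
                             label_noise = 0, seed = 1L) {
  cfg <- list(
    n_compounds = .check_count(n_compounds, "n_compounds"),
    n_features = .check_count(n_features, "n_features"),
    n_clusters = .check_count(n_clusters, "n_clusters"),
    bits_per_compound = .check_count(bits_per_compound, "bits_per_compound"),
    within_cluster_overlap = .check_fraction(within_cluster_overlap,
                                             "within_cluster_overlap"),
    true_weight_sparsity = .check_fraction(true_weight_sparsity,
                                           "true_weight_sparsity"),
    active_ratio_target = .check_fraction(active_ratio_target,
                                          "active_ratio_target",
                                          lo_open = TRUE, hi_open = TRUE),
    label_noise = .check_fraction(label_noise, "label_noise", 0, 0.5,
                                  hi_open = TRUE),
    seed = .check_count(seed, "seed", min = 0L))
  structure(cfg, class = "synthetic_config")
}

## Solve sigmoid-mean(z + b) = target for the intercept b by bisection.
.solve_intercept <- function(z, target, lo = -50, hi = 50, tol = 1e-10) {
  f <- function(b) mean(sigmoid(z + b)) - target
  if (f(lo) > 0 || f(hi) < 0)
    stop("active_ratio_target infeasible for the drawn weights")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a clustered fingerprint dataset with logistic ground truth
#'
#' Each cluster carries a template bit set; members copy template bits with
#' probability `within_cluster_overlap` and add a Poisson number of private
#' bits (none when the overlap is 1). True activity probabilities follow
#' `sigmoid(w . x + b)` with sparse Gaussian weights `w` and the intercept
#' `b` solved by bisection so that the mean true probability matches
#' `active_ratio_target`. Labels are Bernoulli draws, optionally flipped with
#' probability `label_noise`. Folds are assigned cluster-atomically.
#'
#' @param cfg a [synthetic_config()].
#' @param n_folds folds for [assign_folds()] (default 5).
#' @return list with `data` (a [bioactivity_dataset()]), `true_weights`,
#'   `true_intercept`, `true_probs`.
#' @export
gen_fingerprint_dataset <- function(cfg, n_folds = 5L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_compounds; d <- cfg$n_features; k <- cfg$n_clusters
    ## heavy-ish tailed cluster sizes
    wts <- rgamma(k, shape = 1)
    cluster <- sample.int(k, n, replace = TRUE, prob = wts) - 1L
    templates <- lapply(seq_len(k), function(.)
      sample.int(d, min(cfg$bits_per_compound, d)))
    rows <- vector("list", n)
    priv_rate <- cfg$bits_per_compound * (1 - cfg$within_cluster_overlap)
    for (i in seq_len(n)) {
      tmpl <- templates[[cluster[i] + 1L]]
      keep <- tmpl[runif(length(tmpl)) < cfg$within_cluster_overlap]
      n_priv <- if (priv_rate > 0) rpois(1L, priv_rate) else 0L
      priv <- if (n_priv > 0) sample.int(d, min(n_priv, d)) else integer(0)
      bits <- union(keep, priv)
      if (!length(bits)) bits <- tmpl[sample.int(length(tmpl), 1L)]
      rows[[i]] <- sort(bits)
    }
    X <- Matrix::sparseMatrix(i = rep(seq_len(n), lengths(rows)),
                              j = unlist(rows), x = 1, dims = c(n, d))
    support <- runif(d) < cfg$true_weight_sparsity
    w <- rnorm(d) * support
    z <- as.numeric(X %*% w)
    b <- .solve_intercept(z, cfg$active_ratio_target)
    p <- sigmoid(z + b)
    y <- rbinom(n, 1L, p)
    if (cfg$label_noise > 0) {
      flip <- runif(n) < cfg$label_noise
      y <- ifelse(flip, 1L - y, y)
    }
    fold <- assign_folds(cluster, n_folds = n_folds, seed = cfg$seed)
    list(data = bioactivity_dataset(X, y, cluster_id = cluster, fold_id = fold),
         true_weights = w, true_intercept = b, true_probs = p)
  })
}

#' Generate probability vectors with controlled miscalibration
#'
#' Latent calibrated probabilities `p` are drawn from a Beta distribution
#' with mean `base_rate`; labels are Bernoulli draws from `p`; the reported
#' probabilities are `sigmoid(logit(p) / temperature)`. A temperature below 1
#' inflates the logits (overconfidence), above 1 shrinks them toward 0.5
#' (underconfidence), and exactly 1 reports the calibrated probabilities.
#'
#' @param n number of predictions.
#' @param temperature positive distortion temperature.
#' @param base_rate mean of the latent probabilities, in (0, 1).
#' @param seed RNG seed.
#' @param concentration Beta concentration (a + b); small values give the
#'   dispersed confidences needed to exercise binning (default 2).
#' @return list with `probs` (reported), `labels`, `latent` (calibrated
#'   probabilities).
#' @export
gen_miscalibrated_predictions <- function(n, temperature, base_rate = 0.5,
                                          seed = 1L, concentration = 2) {
  n <- .check_count(n, "n")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  .check_fraction(base_rate, "base_rate", lo_open = TRUE, hi_open = TRUE)
  withr::with_seed(as.integer(seed), {
    p <- rbeta(n, base_rate * concentration, (1 - base_rate) * concentration)
    p <- clip_probs(p)
    y <- rbinom(n, 1L, p)
    reported <- clip_probs(sigmoid(qlogis(p) / temperature))
    list(probs = reported, labels = y, latent = p)
  })
}
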