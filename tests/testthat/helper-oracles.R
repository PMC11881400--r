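## Independent brute-force oracles and small fixture builders used across
## the suite. Oracles deliberately share no code with the implementation.

## set-arithmetic Tanimoto
tanimoto_oracle <- function(a, b) {
  A <- which(as.numeric(a) != 0); B <- which(as.numeric(b) != 0)
  length(intersect(A, B)) / length(union(A, B))
}

## O(n^2) single-pass leader clustering over an explicit visiting order
leader_oracle <- function(fps, threshold, ord) {
  fps <- as.matrix(fps)
  cluster <- integer(nrow(fps))
  leaders <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(leaders)) {
      if (tanimoto_oracle(fps[i, ], fps[leaders[k], ]) >= threshold) {
        cluster[i] <- k - 1L; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      leaders <- c(leaders, i)
      cluster[i] <- length(leaders) - 1L
    }
  }
  cluster
}

## Eq.-4 style calibration error with materialized bin membership lists
binned_ce_oracle <- function(probs, y, n_bins, scheme) {
  n <- length(probs)
  members <- vector("list", n_bins)
  if (scheme == "fixed_width") {
    edges <- seq(0, 1, length.out = n_bins + 1)
    for (b in seq_len(n_bins)) {
      inb <- probs >= edges[b] & (if (b == n_bins) probs <= edges[b + 1]
                                  else probs < edges[b + 1])
      members[[b]] <- which(inb)
    }
  } else {
    ord <- order(probs)
    base <- n %/% n_bins; extra <- n %% n_bins
    ## provisional contiguous rank groups, then pull each tied run of equal
    ## predictions into the group of its first member
    grp <- rep(seq_len(n_bins), times = base + (seq_len(n_bins) <= extra))
    ps <- probs[ord]
    for (i in seq_along(ps)[-1]) if (ps[i] == ps[i - 1]) grp[i] <- grp[i - 1]
    for (b in seq_len(n_bins)) members[[b]] <- ord[grp == b]
  }
  total <- 0
  for (b in seq_len(n_bins)) {
    idx <- members[[b]]
    if (!length(idx)) next
    total <- total + length(idx) * abs(mean(y[idx]) - mean(probs[idx]))
  }
  total / n
}

## exhaustive pair-enumeration AUC
auc_oracle <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  wins <- 0
  for (p1 in pos) for (p0 in neg)
    wins <- wins + if (p1 > p0) 1 else if (p1 == p0) 0.5 else 0
  wins / (length(pos) * length(neg))
}

## closed-form paired t statistic
paired_t_oracle <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

## central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

## dense-grid quadrature moments of a Bayesian logistic regression
## posterior (parameters <= 3 incl. bias), written from scratch: stable
## log-likelihood, isotropic Gaussian prior, product grid centred on
## `center` with half-width `half` per dimension
blr_quad_moments <- function(H, y, tau, center, half, n_grid = 51) {
  d <- length(center)
  axes <- lapply(seq_len(d), function(j)
    seq(center[j] - half[j], center[j] + half[j], length.out = n_grid))
  grid <- as.matrix(expand.grid(axes))
  Ht <- cbind(as.matrix(H), 1)
  Z <- Ht %*% t(grid)                   # n x G
  log1pexp <- ifelse(Z > 30, Z + log1p(exp(-Z)), log1p(exp(Z)))
  ll <- as.numeric(crossprod(y, Z)) - colSums(log1pexp) -
    tau / 2 * rowSums(grid^2)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  mu <- colSums(grid * w)
  va <- colSums(sweep(grid, 2, mu)^2 * w)
  list(mean = mu, var = va)
}

## effective sample size via initial-positive-sequence autocorrelation sum
ess <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) { if (r < 0.05) break; s <- s + r }
  max(n / (1 + 2 * s), 10)
}

## small Bayesian logistic regression fixture; keeps the raw pieces
## alongside the problem object so oracles can rebuild it independently
blr_fixture <- function(n = 20, h = 2, tau = 1, seed = 1) {
  pieces <- withr::with_seed(seed, {
    H <- matrix(rnorm(n * h), n, h)
    y <- rbinom(n, 1, plogis(H[, 1] - 0.5 * H[, h]))
    list(H = H, y = y, tau = tau)
  })
  pieces$prob <- blr_problem(pieces$H, pieces$y, tau)
  pieces
}

## small clustered synthetic dataset for model tests
toy_dataset <- function(n = 400, d = 64, k = 15, seed = 3, noise = 0,
                        clusters = NULL) {
  gen <- gen_fingerprint_dataset(synthetic_config(
    n_compounds = n, n_features = d,
    n_clusters = if (is.null(clusters)) k else clusters,
    label_noise = noise, seed = seed))
  gen
}

## random sparse binary fingerprint matrix without all-zero rows
random_fps <- function(n, d, density = 0.15, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(as.numeric(matrix(runif(n * d), n, d) < density), n, d)
    for (i in which(rowSums(m) == 0)) m[i, sample.int(d, 1)] <- 1
    m
  })
}

## a hand-built trained_mlp with chosen parameters (no training)
hand_mlp <- function(W1, b1, W2, b2, dropout_rate = 0) {
  structure(list(W1 = as.matrix(W1), b1 = b1, W2 = W2, b2 = b2,
                 config = mlp_config(hidden_size = length(W2),
                                     dropout_rate = dropout_rate),
                 stopped_epoch = 0L, best_epoch = 0L),
            class = "trained_mlp")
}

## two-row hyperparameter grid: over-capacity vs regularized
capacity_grid <- function() {
  structure(data.frame(hidden_size = c(512L, 16L),
                       dropout_rate = c(0, 0.3),
                       learning_rate = c(3e-3, 1e-3),
                       weight_decay = c(0, 1e-4)),
            class = c("hp_grid", "data.frame"))
}
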