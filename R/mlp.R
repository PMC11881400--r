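## Two-layer baseline classifier on sparse fingerprints: one hidden ReLU
## layer with inverted dropout, a sigmoid output head, Adam with decoupled
## weight decay, and early stopping on validation BCE with best-snapshot
## restore.

#' Hyperparameter configuration for the baseline MLP
#'
#' @param hidden_size hidden units.
#' @param dropout_rate dropout probability on the hidden layer, in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 penalty applied to the weight matrices
#'   (not the biases).
#' @param max_epochs training epoch cap.
#' @param patience epochs without validation improvement before stopping
#'   (0 stops after the first non-improving epoch).
#' @param batch_size minibatch size.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(hidden_size = 50L, dropout_rate = 0.2,
                       learning_rate = 1e-3, weight_decay = 0,
                       max_epochs = 100L, patience = 10L,
                       batch_size = 128L, seed = 1L) {
  cfg <- list(hidden_size = .check_count(hidden_size, "hidden_size"),
              dropout_rate = .check_fraction(dropout_rate, "dropout_rate",
                                             0, 1, hi_open = TRUE),
              learning_rate = .check_fraction(learning_rate, "learning_rate",
                                              0, Inf, lo_open = TRUE),
              weight_decay = .check_fraction(weight_decay, "weight_decay",
                                             0, Inf),
              max_epochs = .check_count(max_epochs, "max_epochs"),
              patience = .check_count(patience, "patience", min = 0L),
              batch_size = .check_count(batch_size, "batch_size"),
              seed = .check_count(seed, "seed", min = 0L))
  if (cfg$patience > cfg$max_epochs) stop("patience must not exceed max_epochs")
  structure(cfg, class = "mlp_config")
}

#' Initialize an untrained two-layer MLP
#'
#' Fan-in-scaled uniform initialization `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' for weights and biases, seeded by `cfg$seed`.
#'
#' @param n_features input dimension.
#' @param cfg an [mlp_config()].
#' @return object of class `trained_mlp` with `W1` (`n_features x h`), `b1`,
#'   `W2` (length `h`), `b2`, `config`, `stopped_epoch = 0`.
#' @export
init_mlp <- function(n_features, cfg) {
  stopifnot(inherits(cfg, "mlp_config"))
  n_features <- .check_count(n_features, "n_features")
  h <- cfg$hidden_size
  withr::with_seed(cfg$seed, {
    lim1 <- 1 / sqrt(n_features)
    lim2 <- 1 / sqrt(h)
    model <- list(
      W1 = matrix(runif(n_features * h, -lim1, lim1), n_features, h),
      b1 = runif(h, -lim1, lim1),
      W2 = runif(h, -lim2, lim2),
      b2 = runif(1, -lim2, lim2),
      config = cfg, stopped_epoch = 0L, best_epoch = 0L)
  })
  structure(model, class = "trained_mlp")
}

#' @exportS3Method base::print
print.trained_mlp <- function(x, ...) {
  cat(sprintf("<trained_mlp> %d features -> %d hidden -> 1, stopped at epoch %d\n",
              nrow(x$W1), length(x$W2), x$stopped_epoch))
  invisible(x)
}

## internal forward: hidden activations with optional dropout mask applied
.forward_hidden <- function(model, X, dropout_active = FALSE) {
  A <- as.matrix(X %*% model$W1)
  A <- sweep(A, 2L, model$b1, `+`)
  A[A < 0] <- 0
  if (dropout_active && model$config$dropout_rate > 0) {
    r <- model$config$dropout_rate
    mask <- matrix(runif(length(A)) >= r, nrow(A), ncol(A)) / (1 - r)
    A <- A * mask
  }
  A
}

#' Forward pass returning logits
#'
#' `logit = W2 . ReLU(W1' x + b1) + b2`. With `dropout_active`, hidden units
#' are zeroed i.i.d. at the configured rate and survivors scaled by
#' `1/(1 - rate)` (inverted dropout), consuming the current RNG stream.
#'
#' @param model a `trained_mlp`.
#' @param X feature matrix (`n x n_features`, sparse or dense).
#' @param dropout_active apply dropout during the pass.
#' @return numeric logit vector.
#' @export
predict_logits <- function(model, X, dropout_active = FALSE) {
  if (ncol(X) != nrow(model$W1))
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), nrow(model$W1)))
  H <- .forward_hidden(model, X, dropout_active)
  as.numeric(H %*% model$W2 + model$b2)
}

#' Predicted activity probabilities
#'
#' Sigmoid of the deterministic logits, clipped inside (0, 1).
#'
#' @inheritParams predict_logits
#' @return probability vector.
#' @export
predict_proba <- function(model, X) {
  clip_probs(sigmoid(predict_logits(model, X)))
}

#' Hidden-layer features (deterministic)
#'
#' `ReLU(W1' x + b1)` with dropout disabled — the frozen representation the
#' Bayesian last layer is fitted to.
#'
#' @inheritParams predict_logits
#' @return `n x hidden_size` matrix.
#' @export
hidden_features <- function(model, X) {
  if (ncol(X) != nrow(model$W1))
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), nrow(model$W1)))
  .forward_hidden(model, X, dropout_active = FALSE)
}

## one Adam step with decoupled weight decay; state mutated functionally
.adam_step <- function(par, grad, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  par <- par - lr * mhat / (sqrt(vhat) + eps)
  if (wd > 0) par <- par - lr * wd * par
  list(par = par, state = state)
}

#' Train the baseline MLP with early stopping
#'
#' Minimizes BCE on the training folds by Adam with decoupled weight decay
#' (weight matrices only), evaluating validation BCE each epoch and
#' restoring the best snapshot. Training is fully reproducible from
#' `cfg$seed`.
#'
#' @param data a [bioactivity_dataset()] with fold assignments.
#' @param split a [make_split()] fold split.
#' @param cfg an [mlp_config()].
#' @param restore_best return the best-validation snapshot (default); with
#'   `FALSE` the final-epoch parameters are kept, which exposes the raw
#'   overfitting behaviour for diagnostics.
#' @return a `trained_mlp` carrying the best-validation snapshot,
#'   `stopped_epoch` (last epoch run) and `best_epoch`.
#' @export
train_mlp <- function(data, split, cfg, restore_best = TRUE) {
  stopifnot(inherits(cfg, "mlp_config"))
  tr <- .split_idx(data, split, "train")
  va <- .split_idx(data, split, "valid")
  if (!length(tr) || !length(va)) stop("empty training or validation fold")
  y_tr <- data$labels[tr]
  if (length(unique(y_tr)) < 2)
    stop("training folds contain a single class")
  X_tr <- data$features[tr, , drop = FALSE]
  X_va <- data$features[va, , drop = FALSE]
  y_va <- data$labels[va]

  model <- init_mlp(ncol(data$features), cfg)
  wd <- cfg$weight_decay; lr <- cfg$learning_rate; r <- cfg$dropout_rate
  n <- length(y_tr)
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  st <- lapply(model[c("W1", "b1", "W2", "b2")],
               function(p) list(m = zero_like(p), v = zero_like(p)))
  best <- list(bce = Inf, snap = NULL, epoch = 0L)
  t_step <- 0L

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X_tr[idx, , drop = FALSE]
        yb <- y_tr[idx]
        A <- as.matrix(Xb %*% model$W1)
        A <- sweep(A, 2L, model$b1, `+`)
        act <- A > 0
        A[!act] <- 0
        if (r > 0) {
          mask <- matrix(runif(length(A)) >= r, nrow(A), ncol(A)) / (1 - r)
          Ad <- A * mask
        } else Ad <- A
        z <- as.numeric(Ad %*% model$W2 + model$b2)
        p <- sigmoid(z)
        dz <- (p - yb) / length(yb)
        gW2 <- as.numeric(crossprod(Ad, dz))
        gb2 <- sum(dz)
        dA <- outer(dz, model$W2)
        if (r > 0) dA <- dA * mask
        dA[!act] <- 0
        gW1 <- as.matrix(crossprod(Xb, dA))
        gb1 <- colSums(dA)
        t_step <- t_step + 1L
        up <- .adam_step(model$W1, gW1, st$W1, lr, wd, t_step)
        model$W1 <- up$par; st$W1 <- up$state
        up <- .adam_step(model$b1, gb1, st$b1, lr, 0, t_step)
        model$b1 <- up$par; st$b1 <- up$state
        up <- .adam_step(model$W2, gW2, st$W2, lr, wd, t_step)
        model$W2 <- up$par; st$W2 <- up$state
        up <- .adam_step(model$b2, gb2, st$b2, lr, 0, t_step)
        model$b2 <- up$par; st$b2 <- up$state
      }
      val_bce <- bce_loss(predict_proba(model, X_va), y_va)
      if (val_bce < best$bce) {
        best <- list(bce = val_bce,
                     snap = model[c("W1", "b1", "W2", "b2")], epoch = epoch)
      } else if (epoch - best$epoch > cfg$patience) {
        model$stopped_epoch <- epoch
        break
      }
      model$stopped_epoch <- epoch
    }
  })
  if (restore_best) model[c("W1", "b1", "W2", "b2")] <- best$snap
  model$best_epoch <- best$epoch
  model$valid_bce <- best$bce
  model
}

#' Save / load an MLP checkpoint
#'
#' Single-file JSON archive holding the four parameter arrays plus the
#' config, with a versioned schema field.
#'
#' @param model a `trained_mlp`.
#' @param path file path.
#' @return invisibly, `path` (`save_mlp`) or the restored model (`load_mlp`).
#' @export
save_mlp <- function(model, path) {
  obj <- list(schema = "qsarcalib/mlp/1",
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              config = unclass(model$config),
              stopped_epoch = model$stopped_epoch,
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "qsarcalib/mlp/1"))
    stop("unrecognized checkpoint schema: ", obj$schema)
  cfg <- do.call(mlp_config, as.list(obj$config))
  structure(list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                 W2 = as.numeric(obj$W2), b2 = as.numeric(obj$b2),
                 config = cfg, stopped_epoch = as.integer(obj$stopped_epoch),
                 best_epoch = as.integer(obj$best_epoch)),
            class = "trained_mlp")
}
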