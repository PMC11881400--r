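## Calibration-aware model selection: exhaustive grid search over the MLP
## hyperparameters driven by one of four validation metrics averaged over
## seeded repeats, and the study engine comparing model architectures with
## paired/unpaired t-tests.

#' Hyperparameter grid
#'
#' Cartesian product of hidden sizes, dropout rates, learning rates and
#' weight decays, enumerated in lexicographic order of the declared
#' arguments (last argument varies fastest).
#'
#' @param hidden_sizes,dropout_rates,learning_rates,weight_decays candidate
#'   values. Defaults span the under- to over-regularization axis.
#' @return an `hp_grid` data frame, one row per configuration.
#' @export
hp_grid <- function(hidden_sizes = c(50L, 200L, 1000L),
                    dropout_rates = c(0, 0.2, 0.4, 0.6),
                    learning_rates = c(1e-3, 1e-4),
                    weight_decays = c(0, 1e-5, 1e-4)) {
  if (!length(hidden_sizes) || !length(dropout_rates) ||
      !length(learning_rates) || !length(weight_decays))
    stop("every grid axis needs at least one value")
  g <- expand.grid(weight_decay = weight_decays,
                   learning_rate = learning_rates,
                   dropout_rate = dropout_rates,
                   hidden_size = hidden_sizes,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("hidden_size", "dropout_rate", "learning_rate", "weight_decay")]
  g <- g[order(match(g$hidden_size, hidden_sizes),
               match(g$dropout_rate, dropout_rates),
               match(g$learning_rate, learning_rates),
               match(g$weight_decay, weight_decays)), , drop = FALSE]
  rownames(g) <- NULL
  structure(g, class = c("hp_grid", "data.frame"))
}

.hp_metric_dir <- function(metric) {
  switch(metric, acc = , auc = "max", bce = , ace = "min",
         stop("unknown hp metric: ", metric))
}

.validation_metric <- function(probs, y, metric, n_bins) {
  switch(metric,
         acc = accuracy_score(probs, y),
         auc = auc_score(probs, y),
         bce = bce_loss(probs, y),
         ace = ace(probs, y, n_bins))
}

#' Exhaustive grid search over MLP hyperparameters
#'
#' Trains each configuration `n_repeats` times (seeds `base_seed ..
#' base_seed + n_repeats - 1`), averages the chosen validation metric, and
#' returns the configuration attaining the optimum in the metric's
#' direction (maximize accuracy/AUC, minimize BCE/ACE). A training failure
#' aborts that configuration with a warning, not the whole search. Ties are
#' broken by grid order.
#'
#' @param data,split dataset and fold split.
#' @param grid an [hp_grid()].
#' @param hp_metric selection metric.
#' @param n_repeats repeats per configuration (default 10).
#' @param base_seed first repeat seed.
#' @param n_bins bins for the ACE criterion.
#' @param max_epochs,patience,batch_size shared training settings.
#' @return object of class `selection_result` with `best_config`
#'   (an [mlp_config()]), `hp_metric`, `per_config` table and `n_repeats`.
#' @export
grid_search <- function(data, split, grid = hp_grid(),
                        hp_metric = c("bce", "ace", "acc", "auc"),
                        n_repeats = 10L, base_seed = 1L, n_bins = 10L,
                        max_epochs = 100L, patience = 10L,
                        batch_size = 128L) {
  hp_metric <- match.arg(hp_metric)
  n_repeats <- .check_count(n_repeats, "n_repeats")
  va <- .split_idx(data, split, "valid")
  X_va <- data$features[va, , drop = FALSE]
  y_va <- data$labels[va]
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    vals <- rep(NA_real_, n_repeats)
    ok <- TRUE
    for (r in seq_len(n_repeats)) {
      cfg <- mlp_config(hidden_size = grid$hidden_size[k],
                        dropout_rate = grid$dropout_rate[k],
                        learning_rate = grid$learning_rate[k],
                        weight_decay = grid$weight_decay[k],
                        max_epochs = max_epochs, patience = patience,
                        batch_size = batch_size,
                        seed = base_seed + r - 1L)
      m <- tryCatch(train_mlp(data, split, cfg), error = function(e) e)
      if (inherits(m, "error")) {
        warning(sprintf("config %d failed on repeat %d: %s", k, r,
                        conditionMessage(m)))
        ok <- FALSE
        break
      }
      vals[r] <- .validation_metric(predict_proba(m, X_va), y_va,
                                    hp_metric, n_bins)
    }
    rows[[k]] <- data.frame(config = k,
                            mean_metric = if (ok) mean(vals) else NA_real_,
                            sd_metric = if (ok) sd(vals) else NA_real_)
  }
  tab <- cbind(as.data.frame(grid), do.call(rbind, rows))
  dir_max <- .hp_metric_dir(hp_metric) == "max"
  s <- if (dir_max) tab$mean_metric else -tab$mean_metric
  if (all(is.na(s))) stop("every grid configuration failed to train")
  best_k <- which.max(ifelse(is.na(s), -Inf, s))  # first optimum in grid order
  best_cfg <- mlp_config(hidden_size = grid$hidden_size[best_k],
                         dropout_rate = grid$dropout_rate[best_k],
                         learning_rate = grid$learning_rate[best_k],
                         weight_decay = grid$weight_decay[best_k],
                         max_epochs = max_epochs, patience = patience,
                         batch_size = batch_size, seed = base_seed)
  structure(list(best_config = best_cfg, hp_metric = hp_metric,
                 per_config = tab, n_repeats = n_repeats,
                 base_seed = as.integer(base_seed)),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> metric %s over %d repeats; best: h=%d, dropout=%.2f, lr=%g, wd=%g\n",
              x$hp_metric, x$n_repeats, x$best_config$hidden_size,
              x$best_config$dropout_rate, x$best_config$learning_rate,
              x$best_config$weight_decay))
  invisible(x)
}

.STUDY_METHODS <- c("mlp", "mlp_p", "mlp_d", "mlp_e", "hbll", "mlp_e_p",
                    "hbll_p")
## methods that are seed-matched modifications of the baseline: compared by
## paired t-tests; everything else (ensembles) unpaired
.PAIRED_SET <- c("mlp", "mlp_p", "mlp_d", "hbll", "hbll_p")

#' Run the model-calibration study
#'
#' Trains baseline repeats and derives the requested model variants from
#' them: `mlp` (baseline), `mlp_p` (Platt on validation logits), `mlp_d`
#' (MC dropout), `hbll` / `hbll_p` (Bayesian last layer, optionally
#' Platt-stacked) share the baseline repeat seeds and are compared by paired
#' t-tests; `mlp_e` / `mlp_e_p` (deep ensembles, optionally Platt-stacked)
#' are trained separately with fewer repeats and compared unpaired. Every
#' method x repeat is scored on the test fold with [evaluate_model()].
#'
#' @param data,split dataset and fold split.
#' @param cfg baseline [mlp_config()] (e.g. the `best_config` of a
#'   [grid_search()]).
#' @param methods subset of
#'   `c("mlp","mlp_p","mlp_d","mlp_e","hbll","mlp_e_p","hbll_p")`.
#' @param n_repeats repeats for non-ensemble methods (default 10).
#' @param n_ensemble_repeats repeats for ensemble methods (default 5).
#' @param n_members ensemble size (default 50).
#' @param n_passes MC dropout forward passes (default 100).
#' @param prior_precision HBLL prior precision; `NULL` tunes it on the
#'   validation fold of the first baseline repeat via
#'   [tune_prior_precision()].
#' @param tau_grid grid for that tuning.
#' @param hmc HMC settings for the HBLL fits.
#' @param n_bins metric bins.
#' @param base_seed first repeat seed; ensemble member seeds are offset far
#'   from the baseline seeds.
#' @param alpha significance level for flagging (default 0.05).
#' @return object of class `study_result` with `per_repeat`, `aggregate`,
#'   `ttests`, `best_flags` and the effective settings.
#' @export
run_study <- function(data, split, cfg,
                      methods = c("mlp", "mlp_p", "hbll"),
                      n_repeats = 10L, n_ensemble_repeats = 5L,
                      n_members = 50L, n_passes = 100L,
                      prior_precision = NULL,
                      tau_grid = 10^seq(-2, 2, by = 1),
                      hmc = hmc_config(), n_bins = 10L, base_seed = 1L,
                      alpha = 0.05) {
  if (!length(methods)) stop("methods must be non-empty")
  methods <- match.arg(methods, .STUDY_METHODS, several.ok = TRUE)
  va <- .split_idx(data, split, "valid")
  te <- .split_idx(data, split, "test")
  X_va <- data$features[va, , drop = FALSE]; y_va <- data$labels[va]
  X_te <- data$features[te, , drop = FALSE]; y_te <- data$labels[te]

  needs_base <- any(methods %in% .PAIRED_SET)
  needs_hbll <- any(methods %in% c("hbll", "hbll_p"))
  rows <- list()
  add_row <- function(method, rep, seed, probs) {
    rep_df <- report_row(evaluate_model(probs, y_te, n_bins))
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(method = method, rep = rep, seed = seed), rep_df)
  }

  if (needs_base) {
    for (r in seq_len(n_repeats)) {
      seed_r <- base_seed + r - 1L
      cfg_r <- cfg; cfg_r$seed <- as.integer(seed_r)
      m <- train_mlp(data, split, cfg_r)
      logit_va <- predict_logits(m, X_va)
      logit_te <- predict_logits(m, X_te)
      if ("mlp" %in% methods)
        add_row("mlp", r, seed_r, clip_probs(sigmoid(logit_te)))
      if ("mlp_p" %in% methods) {
        sc <- fit_platt(logit_va, y_va)
        add_row("mlp_p", r, seed_r, apply_platt(sc, logit_te))
      }
      if ("mlp_d" %in% methods)
        add_row("mlp_d", r, seed_r,
                mc_dropout_predict(m, X_te, n_passes, seed = seed_r))
      if (needs_hbll) {
        if (is.null(prior_precision) && r == 1L) {
          tune <- tune_prior_precision(m, data, split, tau_grid, hmc,
                                       criterion = "bce", n_bins = n_bins)
          prior_precision <- tune$best_tau
        }
        hmc_r <- hmc; hmc_r$seed <- as.integer(hmc$seed + r - 1L)
        post <- fit_hbll(m, data, split, prior_precision, hmc_r)
        p_te <- hbll_predict(post, m, X_te)
        if ("hbll" %in% methods) add_row("hbll", r, seed_r, p_te)
        if ("hbll_p" %in% methods) {
          p_va <- hbll_predict(post, m, X_va)
          add_row("hbll_p", r, seed_r, stack_platt(p_va, y_va, p_te))
        }
      }
    }
  }
  if (any(methods %in% c("mlp_e", "mlp_e_p"))) {
    for (r in seq_len(n_ensemble_repeats)) {
      seed_r <- base_seed + 1000L * r
      ens <- train_ensemble(data, split, cfg, n_members, base_seed = seed_r)
      p_te <- ensemble_predict(ens, X_te)
      if ("mlp_e" %in% methods) add_row("mlp_e", r, seed_r, p_te)
      if ("mlp_e_p" %in% methods) {
        p_va <- ensemble_predict(ens, X_va)
        add_row("mlp_e_p", r, seed_r, stack_platt(p_va, y_va, p_te))
      }
    }
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("bce", "brier", "ece", "ace", "auc", "accuracy")
  agg <- do.call(rbind, lapply(split(per_repeat, per_repeat$method),
    function(df) {
      out <- data.frame(method = df$method[1], n_repeats = nrow(df))
      for (mc in metric_cols) {
        out[[paste0(mc, "_mean")]] <- mean(df[[mc]])
        out[[paste0(mc, "_sd")]] <- sd(df[[mc]])
      }
      out
    }))
  agg <- agg[order(match(agg$method, .STUDY_METHODS)), , drop = FALSE]
  rownames(agg) <- NULL

  ttests <- list(); flags <- list()
  if (length(methods) > 1) {
    pairs <- utils::combn(sort(match(methods, .STUDY_METHODS)), 2)
    tt_rows <- list()
    for (j in seq_len(ncol(pairs))) {
      m1 <- .STUDY_METHODS[pairs[1, j]]; m2 <- .STUDY_METHODS[pairs[2, j]]
      paired <- m1 %in% .PAIRED_SET && m2 %in% .PAIRED_SET
      for (mc in metric_cols) {
        a <- per_repeat[[mc]][per_repeat$method == m1]
        b <- per_repeat[[mc]][per_repeat$method == m2]
        res <- tryCatch(compare_models(a, b, paired = paired),
                        error = function(e) NULL)
        tt_rows[[length(tt_rows) + 1L]] <- data.frame(
          method_a = m1, method_b = m2, metric = mc, paired = paired,
          t_statistic = if (is.null(res)) NA_real_ else res$t_statistic,
          p_value = if (is.null(res)) NA_real_ else res$p_value)
      }
    }
    ttests <- do.call(rbind, tt_rows)
    ## flag, per metric, the best method and those indistinguishable from it
    flag_rows <- list()
    for (mc in metric_cols) {
      dir_max <- mc %in% c("auc", "accuracy")
      mu <- vapply(methods, function(m)
        mean(per_repeat[[mc]][per_repeat$method == m]), numeric(1))
      best <- methods[if (dir_max) which.max(mu) else which.min(mu)]
      for (m in methods) {
        if (m == best) { ns <- TRUE }
        else {
          pv <- ttests$p_value[ttests$metric == mc &
            ((ttests$method_a == m & ttests$method_b == best) |
             (ttests$method_a == best & ttests$method_b == m))]
          ns <- is.na(pv) || pv >= alpha
        }
        flag_rows[[length(flag_rows) + 1L]] <- data.frame(
          metric = mc, method = m, best = m == best,
          indistinguishable_from_best = ns)
      }
    }
    flags <- do.call(rbind, flag_rows)
  }
  structure(list(per_repeat = per_repeat, aggregate = agg, ttests = ttests,
                 best_flags = flags, methods = methods, config = cfg,
                 prior_precision = prior_precision, n_bins = n_bins,
                 base_seed = as.integer(base_seed),
                 n_repeats = as.integer(n_repeats),
                 n_ensemble_repeats = as.integer(n_ensemble_repeats),
                 n_members = as.integer(n_members),
                 n_passes = as.integer(n_passes)),
            class = "study_result")
}

#' @exportS3Method base::print
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> methods: %s\n", paste(x$methods, collapse = ", ")))
  print(x$aggregate[, c("method", "n_repeats", "bce_mean", "brier_mean",
                        "ece_mean", "ace_mean", "auc_mean")], digits = 4)
  invisible(x)
}
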