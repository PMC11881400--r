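## Train-time uncertainty estimation by sampling and averaging in
## probability space: Monte Carlo dropout over stochastic forward passes and
## deep ensembles over random initializations.

#' Monte Carlo dropout prediction
#'
#' Averages `sigmoid(logits)` over `n_passes` stochastic forward passes with
#' dropout active at inference time (a discretization of the posterior
#' predictive average over parameter samples). With dropout rate 0 this
#' reduces exactly to the deterministic prediction.
#'
#' @param model a `trained_mlp`.
#' @param X feature matrix.
#' @param n_passes number of stochastic passes (default 100).
#' @param seed RNG seed for the dropout masks.
#' @return probability vector (clipped).
#' @export
mc_dropout_predict <- function(model, X, n_passes = 100L, seed = 1L) {
  n_passes <- .check_count(n_passes, "n_passes")
  if (model$config$dropout_rate == 0) return(predict_proba(model, X))
  acc <- numeric(nrow(X))
  withr::with_seed(as.integer(seed), {
    for (m in seq_len(n_passes))
      acc <- acc + sigmoid(predict_logits(model, X, dropout_active = TRUE))
  })
  clip_probs(acc / n_passes)
}

#' Train a deep ensemble
#'
#' Members share the architecture config and training data; only the
#' initialization/shuffling seed differs (`base_seed + i - 1` for member
#' `i`).
#'
#' @param data a [bioactivity_dataset()].
#' @param split a [make_split()] split.
#' @param cfg an [mlp_config()]; its seed field is overridden per member.
#' @param n_members ensemble size (default 50).
#' @param base_seed first member seed.
#' @return object of class `ensemble_model` with `members`, `member_seeds`.
#' @export
train_ensemble <- function(data, split, cfg, n_members = 50L, base_seed = 1L) {
  n_members <- .check_count(n_members, "n_members")
  base_seed <- .check_count(base_seed, "base_seed", min = 0L)
  seeds <- base_seed + seq_len(n_members) - 1L
  members <- lapply(seeds, function(s) {
    cfg_i <- cfg; cfg_i$seed <- as.integer(s)
    train_mlp(data, split, cfg_i)
  })
  structure(list(members = members, member_seeds = seeds),
            class = "ensemble_model")
}

#' @exportS3Method base::print
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, seeds %d..%d\n",
              length(x$members), min(x$member_seeds), max(x$member_seeds)))
  invisible(x)
}

#' Ensemble prediction (probability-space average)
#'
#' Unweighted mean of the member probabilities.
#'
#' @param ens an `ensemble_model`.
#' @param X feature matrix.
#' @return probability vector (clipped).
#' @export
ensemble_predict <- function(ens, X) {
  if (!length(ens$members)) stop("empty ensemble")
  acc <- numeric(nrow(X))
  for (m in ens$members) acc <- acc + predict_proba(m, X)
  clip_probs(acc / length(ens$members))
}

#' Save / load an ensemble checkpoint directory
#'
#' One JSON checkpoint per member plus a manifest recording the seeds.
#'
#' @param ens an `ensemble_model`.
#' @param dir directory (created if absent).
#' @return invisibly, `dir` / the restored ensemble.
#' @export
save_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ens$members))
    save_mlp(ens$members[[i]], file.path(dir, sprintf("member_%03d.json", i)))
  jsonlite::write_json(
    list(schema = "qsarcalib/ensemble/1", n_members = length(ens$members),
         member_seeds = ens$member_seeds),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  members <- lapply(seq_len(man$n_members), function(i)
    load_mlp(file.path(dir, sprintf("member_%03d.json", i))))
  structure(list(members = members,
                 member_seeds = as.integer(man$member_seeds)),
            class = "ensemble_model")
}
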