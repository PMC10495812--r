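#' Random-forest ABC model choice
#'
#' Classification forest on (summary statistics -> model label) over the
#' reference table. The selected model is the majority vote at the
#' observed statistics; the prior error rate is the out-of-bag (OOB)
#' misclassification rate (overall and per model); the posterior
#' probability of the selected model is estimated by a regression forest
#' trained on the OOB success indicator, evaluated at the observed
#' statistics (the Pudlo et al. ABC-RF scheme).
#'
#' @param ref a `reference_table` containing at least 2 models.
#' @param obs observed summary-statistic vector (same layout as the
#'   table's statistics).
#' @param n_trees trees per forest (default 1000).
#' @param seed optional RNG seed.
#' @return a `model_choice` object: `selected`, `votes`, `oob_error`
#'   (average), `oob_error_by_model`, `posterior_prob`, `n_trees`.
#' @export
rf_model_choice <- function(ref, obs, n_trees = 1000L, seed = NULL) {
  models <- unique(ref$model)
  if (length(models) < 2L) stop_input("model choice needs at least 2 models")
  X <- ref_stats(ref)
  if (!is.null(names(obs)) &&
      all(paste0("stat_", names(obs)) %in% colnames(X)))
    obs <- obs[sub("^stat_", "", colnames(X))]
  obs <- as.numeric(obs)
  if (length(obs) != ncol(X)) stop_input("`obs` has wrong stat dimension")
  y <- factor(ref$model, levels = models)
  newx <- matrix(obs, nrow = 1, dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    fit <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
    votes <- predict(fit, newdata = newx, type = "vote",
                     norm.votes = FALSE)[1, ]
    selected <- names(votes)[which.max(votes)]
    oob_pred <- fit$predicted
    oob_err_model <- vapply(models, function(m) {
      mean(oob_pred[y == m] != m)
    }, numeric(1))
    oob_err <- mean(oob_pred != y)
    success <- as.numeric(oob_pred == y)
    # binary OOB-success response: regression forest is intentional here
    reg <- suppressWarnings(
      randomForest::randomForest(x = X, y = success, ntree = n_trees))
    post <- predict(reg, newdata = newx)[[1]]
    structure(list(selected = selected, votes = votes,
                   oob_error = oob_err, oob_error_by_model = oob_err_model,
                   posterior_prob = min(max(post, 0), 1),
                   n_trees = as.integer(n_trees)),
              class = "model_choice")
  })
}

#' @export
print.model_choice <- function(x, ...) {
  cat("ABC-RF model choice\n")
  cat("  votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  selected: %s (posterior probability %.3f)\n",
              x$selected, x$posterior_prob))
  cat(sprintf("  OOB prior error rate: %.3f (per model: %s)\n",
              x$oob_error,
              paste(names(x$oob_error_by_model),
                    round(x$oob_error_by_model, 3),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
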