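# First-order optimizer used by both fitting steps. Adam with the usual
# moment defaults (beta1 = 0.9, beta2 = 0.999, eps = 1e-8); only the
# learning rate is exposed, matching how the model is described. Operates
# on a named list of numeric arrays; `objective(params)` must return
# list(loss = scalar, grads = list matching params).

adam_optimize <- function(params, objective, epochs, learning_rate,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  loss_history <- numeric(epochs)
  nm <- names(params)
  for (t in seq_len(epochs)) {
    res <- objective(params)
    if (!is.finite(res$loss)) {
      abort(sprintf("non-finite objective at epoch %d (loss = %s)", t, res$loss))
    }
    loss_history[t] <- res$loss
    bc1 <- 1 - beta1^t
    bc2 <- 1 - beta2^t
    for (k in nm) {
      g <- res$grads[[k]]
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g * g
      params[[k]] <- params[[k]] -
        learning_rate * (m[[k]] / bc1) / (sqrt(v[[k]] / bc2) + eps)
    }
  }
  list(params = params, loss_history = loss_history)
}

#' Fitting configuration
#'
#' Bundles the optimization settings shared by the single-cell and spatial
#' fitting steps. Defaults mirror the settings used for the real data sets:
#' 50,000 epochs at learning rate 0.01, full batch.
#'
#' @param epochs Number of Adam steps (>= 1).
#' @param learning_rate Adam learning rate (> 0); all other Adam
#'   parameters keep their defaults.
#' @param batch_size Cells (or spots) per step; `NULL` = full batch.
#' @param seed Integer seed controlling initialization (and minibatch
#'   draws, when used).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(epochs = 50000, learning_rate = 0.01,
                       batch_size = NULL, seed = 1) {
  if (epochs < 1) abort("`epochs` must be >= 1")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (!is.null(batch_size) && batch_size < 1) abort("`batch_size` must be >= 1")
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = batch_size, seed = as.integer(seed)),
    class = "fit_config"
  )
}
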