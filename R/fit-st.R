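# Step 2: MAP fit on the spatial counts with the single-cell parameters
# frozen. A spot's counts are modelled
#
#   x[s, g] ~ NB(beta[g] * sum_z v[s, z] * r[g, z] + gamma[s] * pos(eps[g]),
#                p[g])
#
# where v[s, z] is a scaled quantity coefficient (spot scaling factor times
# cell count; only the product is identifiable), beta[g] a per-gene
# technique bias between assays, and (gamma[s], pos(eps[g])) a dummy cell
# type with free gene rates that absorbs transcripts the reference cannot
# explain. eps is unconstrained with a standard-normal prior and enters the
# rate through softplus; v, beta, gamma are softplus-positive with flat
# priors. Proportions are the per-spot normalization of v, dummy excluded.

#' Rate of the spatial mixture model at one spot and gene
#'
#' Computes `beta * sum(v * r) + gamma * softplus(eps)`: the negative
#' binomial rate for one gene at one capture location, given the spot's
#' scaled quantity coefficients `v` across types, the gene's technique
#' bias `beta`, reference rates `r`, and the dummy-type contribution.
#'
#' @param v Positive numeric vector of per-type scaled quantities.
#' @param beta Positive scalar gene bias.
#' @param r Positive numeric vector of reference rates, same length as `v`.
#' @param gamma Non-negative scalar dummy quantity (0 disables the dummy).
#' @param eps Unconstrained dummy rate parameter; enters via softplus.
#'   Ignored when `gamma = 0`.
#' @return Positive scalar rate.
#' @export
spot_rate <- function(v, beta, r, gamma = 0, eps = 0) {
  if (any(!is.finite(c(v, beta, r, gamma, eps)))) {
    abort("spot_rate: non-finite input")
  }
  if (length(v) != length(r)) abort("`v` and `r` must have equal length")
  if (any(v < 0) || beta <= 0 || any(r <= 0) || gamma < 0) {
    abort("spot_rate: positivity constraints violated")
  }
  beta * sum(v * r) + gamma * softplus(eps)
}

#' Fit per-spot cell-type quantities on spatial counts
#'
#' Maximum a posteriori fit of the spatial mixture model given frozen
#' single-cell parameters: per-spot scaled quantity coefficients `v[s, z]`,
#' a per-gene technique bias `beta[g]` shared across spots, and a dummy
#' cell type (`gamma[s]`, `eps[g]`) that absorbs expression from cell
#' types missing in the reference and technical noise. The reference rates
#' and success probabilities are held fixed; `eps` carries a standard
#' normal prior on its unconstrained scale, all other parameters flat
#' priors. Genes are aligned to the reference by id; spots with zero total
#' count are dropped with a warning.
#'
#' @param sp Spatial count tibble or matrix, spots in rows.
#' @param params An `sc_fit` (from [fit_sc()] or [read_sc_params()]).
#' @param config A [fit_config()].
#' @param dummy Include the noise-absorbing dummy type? (default `TRUE`).
#' @param prior Keep the standard-normal prior on the dummy rates?
#'   Setting `FALSE` drops the penalty (for studying its effect); without
#'   it the dummy type is free to soak up explanatory power.
#' @param fit_beta Estimate the gene bias? If `FALSE`, `beta` is fixed
#'   at 1.
#' @param init Initialization of the unconstrained parameters. `"auto"`
#'   (default) uses Normal(0, 0.1) when `fit_beta = TRUE` (the shared
#'   bias absorbs the count scale, so the per-spot quantities stay small
#'   and converge quickly) and `"scaled"` otherwise; `"scaled"` starts
#'   each spot's quantities at the value whose predicted total count
#'   matches the observed total, which the optimizer cannot reach quickly
#'   from a small start when `beta` is pinned at 1.
#' @return An object of class `st_fit` with `v`, `beta`, `gamma`, `eps`,
#'   loss history and metadata.
#' @export
fit_st <- function(sp, params, config = fit_config(), dummy = TRUE,
                   fit_beta = TRUE, init = c("auto", "random", "scaled"),
                   prior = TRUE) {
  stopifnot(inherits(params, "sc_fit"))
  init <- match.arg(init)
  if (init == "auto") init <- if (fit_beta) "random" else "scaled"
  x <- as_count_matrix(sp, "spot")
  genes <- params$gene_ids[params$gene_ids %in% colnames(x)]
  if (length(genes) == 0) abort("no genes shared with the reference parameters")
  x <- x[, genes, drop = FALSE]

  tot <- rowSums(x)
  if (any(tot == 0)) {
    warn(sprintf("dropping %d spot(s) with zero total count", sum(tot == 0)))
    x <- x[tot > 0, , drop = FALSE]
  }
  if (nrow(x) == 0) abort("no spots left to fit")

  r <- params$rates[genes, , drop = FALSE]       # G x Z, fixed
  p <- params$probs[genes]                       # G, fixed
  n_s <- nrow(x)
  n_g <- length(genes)
  n_z <- ncol(r)
  types <- colnames(r)

  xsum_g <- colSums(x)
  lgamma_x_const <- sum(lgamma(x + 1))
  log1mp <- log1p(-p)
  logp <- log(p)

  cfg <- config
  batch <- cfg$batch_size
  full_batch <- is.null(batch) || batch >= n_s

  objective <- function(par) {
    v <- softplus(par$v_raw)                     # S x Z
    beta <- if (fit_beta) softplus(par$beta_raw) else rep(1, n_g)
    if (full_batch) {
      rows <- seq_len(n_s)
      scale <- 1
    } else {
      rows <- sample(n_s, batch)
      scale <- n_s / batch
    }
    nb <- length(rows)
    M <- v[rows, , drop = FALSE] %*% t(r)        # S x G mixture part
    beta_row <- rep(beta, each = nb)
    mu <- M * beta_row
    if (dummy) {
      se <- softplus(par$eps)                    # G
      gamma <- softplus(par$gamma_raw)           # S
      mu <- mu + outer(gamma[rows], se)
    }
    xb <- x[rows, , drop = FALSE]
    D <- -(digamma(xb + mu) - digamma(mu) + rep(log1mp, each = nb))
    grads <- list(v_raw = par$v_raw * 0)
    gv <- (D * beta_row) %*% r                   # S x Z
    grads$v_raw[rows, ] <- gv * sigmoid(par$v_raw[rows, , drop = FALSE])
    if (fit_beta) {
      grads$beta_raw <- scale * colSums(D * M) * sigmoid(par$beta_raw)
    }
    if (dummy) {
      grads$gamma_raw <- par$gamma_raw * 0
      grads$gamma_raw[rows] <- as.vector(D %*% se) *
        sigmoid(par$gamma_raw[rows])
      grads$eps <- scale * as.vector(crossprod(D, gamma[rows])) *
        sigmoid(par$eps) + if (prior) par$eps else 0
    }
    musum <- colSums(mu)
    xsb <- if (full_batch) xsum_g else colSums(xb)
    lg_const <- if (full_batch) lgamma_x_const else sum(lgamma(xb + 1))
    nll <- -(sum(lgamma(xb + mu)) - sum(lgamma(mu)) - lg_const +
               sum(xsb * logp) + sum(musum * log1mp))
    loss <- scale * nll + if (dummy && prior) 0.5 * sum(par$eps^2) else 0
    list(loss = loss, grads = grads)
  }

  fit <- withr::with_seed(cfg$seed, {
    start <- if (init == "scaled") {
      # v0 chosen so the predicted total count of each spot matches the
      # observed total at beta = 1, split evenly across types.
      k_sum <- sum(r * (p / (1 - p)))
      v0 <- pmax(rowSums(x) / k_sum, 1e-3)
      list(v_raw = matrix(inv_softplus(v0), n_s, n_z))
    } else {
      list(v_raw = matrix(rnorm(n_s * n_z, 0, 0.1), n_s, n_z))
    }
    if (fit_beta) start$beta_raw <- rnorm(n_g, 0, 0.1)
    if (dummy) {
      start$gamma_raw <- if (init == "scaled") {
        rep(inv_softplus(0.01), n_s)
      } else {
        rnorm(n_s, 0, 0.1)
      }
      start$eps <- rnorm(n_g, 0, 0.1)
    }
    adam_optimize(start, objective, cfg$epochs, cfg$learning_rate)
  })

  v <- softplus(fit$params$v_raw)
  dimnames(v) <- list(rownames(x), types)
  beta <- if (fit_beta) softplus(fit$params$beta_raw) else rep(1, n_g)
  names(beta) <- genes
  gamma <- if (dummy) softplus(fit$params$gamma_raw) else rep(0, n_s)
  names(gamma) <- rownames(x)
  eps <- if (dummy) fit$params$eps else rep(-Inf, n_g)
  names(eps) <- genes

  structure(
    list(
      spot_ids = rownames(x), type_labels = types, gene_ids = genes,
      v = v, beta = beta, gamma = gamma, eps = eps,
      dummy = dummy, fit_beta = fit_beta,
      loss_history = fit$loss_history, config = cfg
    ),
    class = "st_fit"
  )
}

#' Convert a spatial fit into cell-type proportions
#'
#' Normalizes each spot's scaled quantity coefficients to the simplex,
#' `w[s, z] = v[s, z] / sum_z v[s, z]`, excluding the dummy type from both
#' numerator and denominator. The per-spot global scaling factor cancels
#' in this ratio, which is why only proportions (not absolute cell
#' numbers) are identifiable. The dummy type's unnormalized weight is
#' reported separately as `dummy_share = gamma / (gamma + sum_z v[s, z])`.
#'
#' @param fit An `st_fit`.
#' @return A proportion tibble: `spot`, one column per type (rows sum
#'   to 1), and `dummy_share`.
#' @export
compute_proportions <- function(fit) {
  stopifnot(inherits(fit, "st_fit"))
  v <- fit$v
  tot <- rowSums(v)
  if (any(tot <= 0)) abort("cannot normalize a spot with all-zero quantities")
  w <- v / tot
  out <- dplyr::bind_cols(
    tibble(spot = fit$spot_ids),
    as_tibble(as.data.frame(w, check.names = FALSE))
  )
  out$dummy_share <- if (fit$dummy) unname(fit$gamma / (fit$gamma + tot)) else 0
  validate_proportions(out)
  out
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf(
    "<st_fit> %d spots x %d cell types (%d genes)%s\n",
    length(x$spot_ids), length(x$type_labels), length(x$gene_ids),
    if (x$dummy) " + dummy type" else ""
  ))
  if (length(x$loss_history) > 0) {
    cat(sprintf("  neg. log-posterior %.2f -> %.2f over %d epochs\n",
                x$loss_history[1], tail_value(x$loss_history),
                length(x$loss_history)))
  }
  invisible(x)
}

#' @describeIn fit_st Long tibble: one row per (spot, type) with the
#'   scaled quantity `v` and the normalized proportion.
#' @param x An `st_fit` object.
#' @param ... Unused.
#' @method tidy st_fit
#' @export
tidy.st_fit <- function(x, ...) {
  w <- x$v / rowSums(x$v)
  tibble(
    spot = rep(x$spot_ids, times = length(x$type_labels)),
    type = rep(x$type_labels, each = length(x$spot_ids)),
    v = as.vector(x$v),
    proportion = as.vector(w)
  )
}

#' @describeIn fit_st One-row summary: dimensions, epochs, final loss,
#'   mean dummy share.
#' @method glance st_fit
#' @export
glance.st_fit <- function(x, ...) {
  tibble(
    n_spots = length(x$spot_ids), n_types = length(x$type_labels),
    n_genes = length(x$gene_ids), epochs = length(x$loss_history),
    final_loss = tail_value(x$loss_history),
    mean_dummy_share = mean(x$gamma / (x$gamma + rowSums(x$v)))
  )
}

#' @describeIn fit_st Loss-history curve (negative log-posterior per
#'   epoch).
#' @param object An `st_fit` object.
#' @method autoplot st_fit
#' @export
autoplot.st_fit <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_history),
               loss = object$loss_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "negative log-posterior",
                  title = "Spatial MAP fit")
}
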