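#' FTRL-Proximal hyperparameters
#'
#' Per-coordinate learning-rate scale `alpha` and offset `beta`, plus L1 and
#' L2 regularization strengths. L1 truncation zeroes every coordinate whose
#' accumulator stays within `lambda1`, giving sparse wide weights; L2 smooths
#' the updates.
#'
#' @param alpha Learning-rate scale (> 0).
#' @param beta Learning-rate offset (>= 0).
#' @param lambda1,lambda2 L1 / L2 strengths (>= 0).
#' @return An `ftrl_config`.
#' @export
ftrl_config <- function(alpha = 0.1, beta = 1, lambda1 = 1e-4,
                        lambda2 = 1e-4) {
  if (alpha <= 0) stopf("alpha must be > 0")
  if (beta < 0 || lambda1 < 0 || lambda2 < 0) {
    stopf("beta, lambda1 and lambda2 must be >= 0")
  }
  structure(list(alpha = alpha, beta = beta, lambda1 = lambda1,
                 lambda2 = lambda2),
            class = "ftrl_config")
}

#' Initialize FTRL-Proximal state
#'
#' State is one accumulator `z`, one sum of squared gradients `q` and one
#' weight per coordinate. Nonzero initial weights are folded into `z` by
#' inverting the closed-form update at `q = 0`
#' (`z0 = -(lambda2 + beta/alpha) * w0 - lambda1 * sgn(w0)`), so the first
#' proximal step departs from `w0` rather than discarding it.
#'
#' @param w0 Initial weight vector.
#' @param cfg An [ftrl_config()].
#' @return An `ftrl_state` with fields `z`, `q`, `w`.
#' @export
ftrl_state <- function(w0, cfg) {
  w0 <- as.numeric(w0)
  z <- -(cfg$lambda2 + cfg$beta / cfg$alpha) * w0 - cfg$lambda1 * sign(w0)
  structure(list(z = z, q = numeric(length(w0)), w = w0),
            class = "ftrl_state")
}

#' One FTRL-Proximal update
#'
#' Per coordinate `i`:
#' `sigma_i = (sqrt(q_i + g_i^2) - sqrt(q_i)) / alpha`;
#' `q_i <- q_i + g_i^2`; `z_i <- z_i + g_i - sigma_i * w_i`; then
#' `w_i = 0` if `|z_i| <= lambda1`, else
#' `w_i = -(lambda2 + (beta + sqrt(q_i)) / alpha)^-1 *
#' (z_i - lambda1 * sgn(z_i))` -- the closed-form argmin of the
#' follow-the-regularized-leader objective
#' `G.w + (1/2) sum_s sigma_s ||w - w_s||^2 + lambda1 |w| +
#' (1/2) lambda2 w^2`. The tie `|z| = lambda1` truncates to zero (the limit
#' of the else branch). States are values: the input state is not mutated.
#'
#' @param state An [ftrl_state()].
#' @param g Gradient vector (same length as the state).
#' @param cfg An [ftrl_config()].
#' @return The updated `ftrl_state`.
#' @export
ftrl_step <- function(state, g, cfg) {
  if (length(g) != length(state$w)) {
    stopf("gradient length %d does not match state length %d", length(g),
          length(state$w))
  }
  bad <- which(!is.finite(g))
  if (length(bad) > 0) {
    stopf("non-finite gradient at coordinate %d", bad[1])
  }
  q_new <- state$q + g^2
  sigma <- (sqrt(q_new) - sqrt(state$q)) / cfg$alpha
  z <- state$z + g - sigma * state$w
  w <- -(z - cfg$lambda1 * sign(z)) /
    (cfg$lambda2 + (cfg$beta + sqrt(q_new)) / cfg$alpha)
  w[abs(z) <= cfg$lambda1] <- 0
  structure(list(z = z, q = q_new, w = w), class = "ftrl_state")
}

#' Logistic regression trained with FTRL-Proximal
#'
#' Minibatch training of a plain logistic-regression model (weights + bias)
#' on a feature matrix -- the wide branch in isolation, also usable as a
#' generic sparse online classifier.
#'
#' @param X Feature matrix, samples x features.
#' @param y Binary labels.
#' @param cfg An [ftrl_config()].
#' @param n_passes Passes over the data.
#' @param batch_size Minibatch size.
#' @param seed Shuffling seed.
#' @return `list(w, b, loss)` with the per-pass mean training loss.
#' @export
ftrl_logreg_fit <- function(X, y, cfg = ftrl_config(), n_passes = 50,
                            batch_size = 32, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stopf("empty training set")
  p <- ncol(X)
  state <- ftrl_state(numeric(p + 1L), cfg)
  losses <- numeric(n_passes)
  with_seed(seed, {
    for (pass in seq_len(n_passes)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        logit <- as.numeric(Xb %*% state$w[seq_len(p)]) + state$w[p + 1L]
        pr <- sigmoid(logit)
        d <- (pr - yb) / length(idx)
        g <- c(as.numeric(crossprod(Xb, d)), sum(d))
        state <- ftrl_step(state, g, cfg)
        tot <- tot + logistic_loss(pr, yb) * length(idx)
      }
      losses[pass] <- tot / n
    }
  })
  list(w = state$w[seq_len(p)], b = state$w[p + 1L], loss = losses)
}

#' Train the wide-and-deep detector
#'
#' Minibatch training of every trainable parameter -- wide weights, shared
#' bias, embedding table, conv kernels/biases and dense head -- with
#' per-coordinate gradients of the logistic loss fed to [ftrl_step()].
#' Optionally the deep branch can instead use a conventional adaptive
#' (AdaGrad-style) optimizer while the wide branch stays on FTRL, the
#' customary split for wide-and-deep models; the default optimizes the whole
#' mixed model with FTRL.
#'
#' @param model A [widedeep_model()].
#' @param epochs An [epoch_set()] of 30 x 90 training epochs.
#' @param profiles Named list of [subject_profile()]s keyed by subject id
#'   (must cover every id in `epochs$subject_ids`).
#' @param cfg An [ftrl_config()].
#' @param n_passes Passes over the training set.
#' @param batch_size Minibatch size (default 32).
#' @param seed Shuffling seed.
#' @param deep_optimizer `"ftrl"` (default) or `"adagrad"` for the deep
#'   branch.
#' @param adagrad_lr Learning rate of the adaptive deep optimizer.
#' @return `list(model, loss, wide_sparsity)`: the trained model, per-pass
#'   mean training loss, and per-pass fraction of exactly-zero wide weights.
#' @export
fit_widedeep <- function(model, epochs, profiles, cfg = ftrl_config(),
                         n_passes = 3, batch_size = 32, seed = 1,
                         deep_optimizer = c("ftrl", "adagrad"),
                         adagrad_lr = 0.05) {
  deep_optimizer <- match.arg(deep_optimizer)
  n <- n_epochs(epochs)
  if (n == 0) stopf("empty training set")
  enc <- encode_profiles(model, epochs$subject_ids, profiles)
  y <- epochs$labels
  layout <- param_layout(model)
  theta <- pack_params(model)
  P <- length(theta)
  use_wide <- "wide" %in% model$branches
  use_deep <- "deep" %in% model$branches

  # coordinates owned by each optimizer
  deep_names <- c("E", "K1", "b1", "K2", "b2", "K3", "b3", "dense")
  idx_deep <- unlist(layout[deep_names], use.names = FALSE)
  split_deep <- use_deep && deep_optimizer == "adagrad"
  state <- ftrl_state(theta, cfg)
  acc <- numeric(length(idx_deep))    # AdaGrad accumulator (if used)

  Xw_all <- if (use_wide) cbind(flatten_epochs(epochs$epochs), enc$D2, enc$PHI)

  losses <- numeric(n_passes)
  sparsity <- numeric(n_passes)
  iw <- layout$wide_w
  ib <- layout$b
  with_seed(seed, {
    for (pass in seq_len(n_passes)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        m <- length(idx)
        ep_b <- epochs$epochs[idx, , , drop = FALSE]
        D2_b <- enc$D2[idx, , drop = FALSE]
        Xb <- if (use_wide) Xw_all[idx, , drop = FALSE]
        logit <- rep(model$params$b, m)
        if (use_wide) {
          logit <- logit + as.numeric(Xb %*% model$params$wide_w)
        }
        cache <- NULL
        if (use_deep) {
          cache <- deep_forward_batch(model, ep_b, D2_b)
          logit <- logit + cache$logit
        }
        pr <- sigmoid(logit)
        d <- (pr - y[idx]) / m
        g <- numeric(P)
        if (use_wide) g[iw] <- as.numeric(crossprod(Xb, d))
        g[ib] <- sum(d)
        if (use_deep) {
          dg <- deep_backward_batch(model, cache, d)
          for (nm in deep_names) g[layout[[nm]]] <- as.numeric(dg[[nm]])
        }
        if (split_deep) {
          gd <- g[idx_deep]
          acc <- acc + gd^2
          theta_deep <- state$w[idx_deep] - adagrad_lr * gd / sqrt(acc + 1e-8)
          g[idx_deep] <- 0
          state <- ftrl_step(state, g, cfg)
          state$w[idx_deep] <- theta_deep
        } else {
          state <- ftrl_step(state, g, cfg)
        }
        model <- unpack_params(model, state$w)
        tot <- tot + logistic_loss(pr, y[idx]) * m
      }
      losses[pass] <- tot / n
      sparsity[pass] <- mean(state$w[iw] == 0)
    }
  })
  list(model = model, loss = losses, wide_sparsity = sparsity)
}
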