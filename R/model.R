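#' Logistic sigmoid
#'
#' `1 / (1 + exp(-z))`, computed stably and clipped to
#' `[1e-12, 1 - 1e-12]` so downstream log-likelihoods stay finite.
#'
#' @param z Numeric vector of logits.
#' @return Probabilities in (0, 1).
#' @export
sigmoid <- function(z) {
  p <- stats::plogis(z)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Mean logistic (cross-entropy) loss
#'
#' `-(1/m) * sum(y * log p + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-7, 1 - 1e-7]` because the loss is undefined at exactly 0
#' or 1.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels (same length).
#' @return Scalar loss.
#' @export
logistic_loss <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stopf("probs and labels differ in length (%d vs %d)", length(probs),
          length(labels))
  }
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Standalone wide (logistic-regression) model
#'
#' The wide branch in isolation: a weight per input feature plus a bias
#' (2,701 parameters for a bare 30 x 90 epoch input).
#'
#' @param n_features Input length.
#' @return A `wide_model` with zero-initialized weights (the FTRL
#'   convention).
#' @export
wide_model <- function(n_features) {
  structure(list(w = numeric(n_features), b = 0), class = "wide_model")
}

#' Wide-branch logit
#'
#' `w . x + b`; the sigmoid is applied by the caller (or by the combined
#' prediction head).
#'
#' @param x Wide input vector (see [assemble_wide_input()]).
#' @param m A [wide_model()].
#' @return Scalar logit.
#' @export
wide_logit <- function(x, m) {
  if (length(x) != length(m$w)) {
    stopf("input length %d does not match the %d wide weights", length(x),
          length(m$w))
  }
  sum(m$w * x) + m$b
}

## ---------------------------------------------------------------------------
## 1-D convolution along time, applied identically to every row (1 x 7
## filters: no cross-row mixing before the dense head).  Feature maps are
## stored as plain matrices -- N rows (batch x concatenated channels),
## W * C columns with column w + W*(c-1) holding time step w of map c -- so
## the im2col gather, the matmul and the col2im scatter are all fast 2-D
## operations and every reshape is a free dim() change.

conv1d_forward <- function(H, W, Cin, K, bias, stride, pad_left = 0) {
  N <- nrow(H)
  kw <- dim(K)[1]; Cout <- dim(K)[3]
  Wp <- W + pad_left
  if (pad_left > 0) {
    Hp <- matrix(0, N, Wp * Cin)
    tcols <- as.integer(outer(pad_left + seq_len(W), Wp * (seq_len(Cin) - 1L), "+"))
    Hp[, tcols] <- H
  } else {
    Hp <- H
  }
  P <- (Wp - kw) %/% stride + 1L
  sp <- (seq_len(P) - 1L) * stride + 1L
  # gather index over (p fastest; then j, then c): column sp[p]+j-1 + Wp*(c-1)
  gidx <- as.integer(outer(sp, as.integer(outer(seq_len(kw) - 1L,
                                                Wp * (seq_len(Cin) - 1L), "+")), "+"))
  G <- Hp[, gidx, drop = FALSE]
  dim(G) <- c(N * P, kw * Cin)
  Z <- G %*% matrix(K, kw * Cin, Cout)
  Z <- Z + rep(bias, each = N * P)
  dim(Z) <- c(N, P * Cout)
  list(out = Z, G = G, gidx = gidx, sp = sp, N = N, W = W, Wp = Wp,
       Cin = Cin, Cout = Cout, P = P, kw = kw, pad_left = pad_left)
}

conv1d_backward <- function(dOut, cache, K) {
  N <- cache$N; P <- cache$P; Cin <- cache$Cin; Cout <- cache$Cout
  kw <- cache$kw; Wp <- cache$Wp
  dZ <- dOut
  dim(dZ) <- c(N * P, Cout)
  dK <- crossprod(cache$G, dZ)
  dim(dK) <- c(kw, Cin, Cout)
  db <- colSums(dZ)
  dG <- tcrossprod(dZ, matrix(K, kw * Cin, Cout))
  dim(dG) <- c(N, P * kw * Cin)
  dHp <- matrix(0, N, Wp * Cin)
  # scatter-add by kernel tap: for fixed j the target columns are distinct
  for (j in seq_len(kw)) {
    src <- as.integer(outer(seq_len(P) + P * (j - 1L),
                            P * kw * (seq_len(Cin) - 1L), "+"))
    tgt <- as.integer(outer(cache$sp + j - 1L, Wp * (seq_len(Cin) - 1L), "+"))
    dHp[, tgt] <- dHp[, tgt, drop = FALSE] + dG[, src, drop = FALSE]
  }
  dH <- if (cache$pad_left > 0) {
    keep <- as.integer(outer(cache$pad_left + seq_len(cache$W),
                             Wp * (seq_len(Cin) - 1L), "+"))
    dHp[, keep, drop = FALSE]
  } else dHp
  list(dH = dH, dK = dK, db = db)
}

## ---------------------------------------------------------------------------

# Feature-map widths for the three conv layers: kernel 7 throughout, strides
# 2/2/1, one left zero pad on the third layer.  For the 90-sample input this
# gives 42, 18, 13 and a flattened activation of 31*13*16 = 6448.
deep_geometry <- function(n_samples) {
  w1 <- (n_samples - 7L) %/% 2L + 1L
  w2 <- (w1 - 7L) %/% 2L + 1L
  w3 <- (w2 + 1L - 7L) + 1L
  if (w3 < 1L) stopf("input of %d samples is too short for the conv stack", n_samples)
  c(w1, w2, w3)
}

#' Construct a wide-and-deep P300 detector
#'
#' Builds the combined model: a wide logistic-regression branch over the
#' flattened epoch, one-hot participant features and their crosses, and a
#' deep branch that embeds the one-hot vector to a 90-sample row, stacks it
#' under the 30 EEG channels (31 x 90), applies three 1 x 7 convolutions
#' along time with LeakyReLU (feature-map widths 42, 18, 13; 16/32/16
#' filters) and maps the flattened activations to a logit. Both branches
#' share a single bias in the combined logit.
#'
#' Wide weights start at zero (the FTRL convention); deep weights start
#' uniform scaled by fan-in, seeded.
#'
#' @param feature_spec A [sparse_feature_spec()].
#' @param cross A [cross_spec()] (default: all pairwise block crosses).
#' @param n_channels,n_samples Epoch geometry (30 x 90).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param branches Character subset of `c("wide", "deep")`; dropping one
#'   gives the ablated detectors used for comparison runs.
#' @param seed Seed for the deep initialization.
#' @return A `widedeep_model`.
#' @export
widedeep_model <- function(feature_spec, cross = default_cross_spec(feature_spec),
                           n_channels = 30L, n_samples = 90L,
                           leaky_slope = 0.01,
                           branches = c("wide", "deep"), seed = 1) {
  Tt <- feature_spec$total
  k <- cross$k
  d1 <- n_channels * n_samples
  dw <- d1 + Tt + k
  widths <- deep_geometry(n_samples)
  n_flat <- (n_channels + 1L) * widths[3] * 16L
  u <- function(n, s) stats::runif(n, -s, s)
  params <- with_seed(seed, list(
    wide_w = numeric(dw),
    b = 0,
    E = matrix(u(Tt * n_samples, 0.05), Tt, n_samples),
    K1 = array(u(7 * 1 * 16, sqrt(1 / 7)), c(7, 1, 16)),
    b1 = numeric(16),
    K2 = array(u(7 * 16 * 32, sqrt(1 / (7 * 16))), c(7, 16, 32)),
    b2 = numeric(32),
    K3 = array(u(7 * 32 * 16, sqrt(1 / (7 * 32))), c(7, 32, 16)),
    b3 = numeric(16),
    dense = u(n_flat, sqrt(1 / n_flat))
  ))
  structure(
    list(params = params, feature_spec = feature_spec, cross = cross,
         dims = list(n_channels = n_channels, n_samples = n_samples,
                     T = Tt, k = k, d1 = d1, dw = dw, widths = widths,
                     n_flat = n_flat),
         leaky_slope = leaky_slope,
         branches = intersect(c("wide", "deep"), branches)),
    class = "widedeep_model"
  )
}

#' @export
print.widedeep_model <- function(x, ...) {
  cnt <- count_parameters(x)
  cat(sprintf("<widedeep_model> branches: %s; %d wide + %d deep parameters\n",
              paste(x$branches, collapse = "+"), cnt$wide,
              cnt$total - cnt$wide))
  invisible(x)
}

# Flat parameter-vector layout used by the optimizer.
param_layout <- function(model) {
  lens <- vapply(model$params, length, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  Map(function(s, e) s:e, starts, ends)
}

pack_params <- function(model) {
  unlist(model$params, use.names = FALSE)
}

unpack_params <- function(model, theta) {
  layout <- param_layout(model)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    v <- theta[layout[[nm]]]
    if (!is.null(dim(p))) dim(v) <- dim(p)
    model$params[[nm]] <- v
  }
  model
}

# Batched deep forward: epochs (n, ch, s), D2 (n, T).  Returns logits plus
# the caches needed for backprop.
deep_forward_batch <- function(model, epochs, D2) {
  p <- model$params
  d <- model$dims
  n <- dim(epochs)[1]
  R <- D2 %*% p$E                                   # n x 90 embedded rows
  A <- array(0, c(d$n_channels + 1L, n, d$n_samples))
  A[seq_len(d$n_channels), , ] <- aperm(epochs, c(2, 1, 3))
  A[d$n_channels + 1L, , ] <- R
  H0 <- A
  dim(H0) <- c((d$n_channels + 1L) * n, d$n_samples)
  c1 <- conv1d_forward(H0, d$n_samples, 1L, p$K1, p$b1, stride = 2L)
  A1 <- leaky_relu(c1$out, model$leaky_slope)
  c2 <- conv1d_forward(A1, d$widths[1], 16L, p$K2, p$b2, stride = 2L)
  A2 <- leaky_relu(c2$out, model$leaky_slope)
  c3 <- conv1d_forward(A2, d$widths[2], 32L, p$K3, p$b3, stride = 1L,
                       pad_left = 1L)
  A3 <- leaky_relu(c3$out, model$leaky_slope)
  B <- array(A3, c(d$n_channels + 1L, n, d$widths[3] * 16L))
  alf <- aperm(B, c(2, 1, 3))
  dim(alf) <- c(n, d$n_flat)
  logit <- as.numeric(alf %*% p$dense)
  list(logit = logit, alf = alf, c1 = c1, c2 = c2, c3 = c3,
       A1 = A1, A2 = A2, D2 = D2, n = n)
}

deep_backward_batch <- function(model, cache, dlogit) {
  p <- model$params
  d <- model$dims
  n <- cache$n
  ddense <- as.numeric(crossprod(cache$alf, dlogit))
  dalf <- matrix(dlogit, n, 1) %*% matrix(p$dense, 1, d$n_flat)
  dim(dalf) <- c(n, d$n_channels + 1L, d$widths[3] * 16L)
  dA3 <- aperm(dalf, c(2, 1, 3))
  dim(dA3) <- c((d$n_channels + 1L) * n, d$widths[3] * 16L)
  dZ3 <- dA3 * leaky_relu_grad(cache$c3$out, model$leaky_slope)
  g3 <- conv1d_backward(dZ3, cache$c3, p$K3)
  dZ2 <- g3$dH * leaky_relu_grad(cache$c2$out, model$leaky_slope)
  g2 <- conv1d_backward(dZ2, cache$c2, p$K2)
  dZ1 <- g2$dH * leaky_relu_grad(cache$c1$out, model$leaky_slope)
  g1 <- conv1d_backward(dZ1, cache$c1, p$K1)
  nr <- d$n_channels + 1L
  dR <- g1$dH[seq(nr, nr * n, by = nr), , drop = FALSE]   # embedding rows
  dE <- crossprod(cache$D2, dR)
  list(E = dE, K1 = g1$dK, b1 = g1$db, K2 = g2$dK, b2 = g2$db,
       K3 = g3$dK, b3 = g3$db, dense = ddense)
}

# Row-major flattening of a batch of epochs into the wide d1 block.
flatten_epochs <- function(epochs) {
  d <- dim(epochs)
  A <- aperm(epochs, c(3, 2, 1))
  dim(A) <- c(d[3] * d[2], d[1])
  t(A)
}

# One-hot + cross matrices for a vector of per-epoch subject ids, computing
# each distinct participant's encoding once (the embedding/cross work per
# participant is shared across that participant's epochs).
encode_profiles <- function(model, subject_ids, profiles) {
  uids <- unique(subject_ids)
  D2u <- matrix(0, length(uids), model$dims$T)
  PHIu <- matrix(0, length(uids), model$dims$k)
  for (i in seq_along(uids)) {
    pr <- profiles[[uids[i]]]
    if (is.null(pr)) stopf("no profile supplied for subject '%s'", uids[i])
    d2 <- one_hot_encode(pr, model$feature_spec)
    D2u[i, ] <- d2
    if (model$dims$k > 0) PHIu[i, ] <- cross_products(d2, model$cross)
  }
  ix <- match(subject_ids, uids)
  list(D2 = D2u[ix, , drop = FALSE], PHI = PHIu[ix, , drop = FALSE])
}

# Combined logits for a batch.  Returns the deep cache so training can
# backpropagate without recomputing the forward pass.
combined_logits <- function(model, epochs, D2, PHI, keep_cache = FALSE) {
  n <- dim(epochs)[1]
  logit <- rep(model$params$b, n)
  Xw <- NULL
  if ("wide" %in% model$branches) {
    Xw <- cbind(flatten_epochs(epochs), D2, PHI)
    logit <- logit + as.numeric(Xw %*% model$params$wide_w)
  }
  cache <- NULL
  if ("deep" %in% model$branches) {
    cache <- deep_forward_batch(model, epochs, D2)
    logit <- logit + cache$logit
  }
  list(logit = logit, Xw = Xw, deep_cache = if (keep_cache) cache else NULL)
}

#' Deep-branch forward pass for one epoch
#'
#' Runs the generalization branch on a single 30 x 90 epoch and its one-hot
#' participant vector: embedding to a 90-sample row, concatenation to
#' 31 x 90, three 1 x 7 convolutions with LeakyReLU, flatten, dense logit.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param d2 One-hot participant vector (length T).
#' @param model A [widedeep_model()].
#' @return `list(concat = 31 x 90 input tensor, a_lf = flattened activations,
#'   deep_logit = scalar)`.
#' @export
deep_forward <- function(epoch, d2, model) {
  if (length(d2) != model$dims$T) {
    stopf("d2 has length %d but the feature spec expects %d", length(d2),
          model$dims$T)
  }
  ep <- array(epoch, c(1, dim(epoch)))
  cache <- deep_forward_batch(model, ep, matrix(d2, 1))
  concat <- rbind(epoch, as.numeric(matrix(d2, 1) %*% model$params$E))
  list(concat = concat, a_lf = as.numeric(cache$alf),
       deep_logit = cache$logit)
}

#' Combined wide + deep prediction for one epoch
#'
#' `sigmoid(w_wide . [x, phi(x)] + w_conv . a_lf + b)` with the wide input
#' assembled from the epoch and the participant's one-hot/cross features.
#' Identical, bit for bit, to composing [wide_logit()] (with zero wide bias)
#' and [deep_forward()] and applying [sigmoid()].
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param profile A [subject_profile()].
#' @param model A [widedeep_model()].
#' @return Probability that the epoch contains a target response.
#' @export
combined_predict <- function(epoch, profile, model) {
  d2 <- one_hot_encode(profile, model$feature_spec)
  wl <- 0
  if ("wide" %in% model$branches) {
    dphi <- if (model$dims$k > 0) cross_products(d2, model$cross) else numeric(0)
    x <- assemble_wide_input(epoch, d2, dphi)
    wl <- sum(model$params$wide_w * x)
  }
  dl <- if ("deep" %in% model$branches) {
    deep_forward(epoch, d2, model)$deep_logit
  } else 0
  sigmoid(wl + dl + model$params$b)
}

#' Predict target probabilities for an epoch set
#'
#' Batched prediction: each distinct participant's one-hot encoding, cross
#' products and embedded row are computed once and reused across that
#' participant's epochs.
#'
#' @param object A [widedeep_model()].
#' @param epochs An [epoch_set()] (30 x 90 epochs).
#' @param profiles Named list of [subject_profile()]s keyed by subject id.
#' @param ... Ignored.
#' @return Numeric vector of probabilities.
#' @export
predict.widedeep_model <- function(object, epochs, profiles, ...) {
  enc <- encode_profiles(object, epochs$subject_ids, profiles)
  cl <- combined_logits(object, epochs$epochs, enc$D2, enc$PHI)
  sigmoid(cl$logit)
}

#' Count trainable parameters
#'
#' Exact trainable-scalar counts per component. For the default geometry:
#' wide `2700 + T + k + 1` (2,701 with no sparse features), conv layers
#' `16*1*7+16 = 128`, `32*1*7*16+32 = 3616`, `16*7*32+16 = 3600`, embedding
#' `90*T`, dense `6448`.
#'
#' @param model A [widedeep_model()] or [wide_model()].
#' @return Named list of counts including `total`.
#' @export
count_parameters <- function(model) UseMethod("count_parameters")

#' @export
count_parameters.wide_model <- function(model) {
  list(wide = length(model$w) + 1L, total = length(model$w) + 1L)
}

#' @export
count_parameters.widedeep_model <- function(model) {
  p <- model$params
  out <- list(
    wide = length(p$wide_w) + 1L,          # weights + shared bias
    embedding = length(p$E),
    conv1 = length(p$K1) + length(p$b1),
    conv2 = length(p$K2) + length(p$b2),
    conv3 = length(p$K3) + length(p$b3),
    dense = length(p$dense)
  )
  out$total <- sum(unlist(out))
  out
}

#' Save / load a trained model
#'
#' Serializes a [widedeep_model()] -- every weight array plus a JSON block
#' describing the architecture, feature spec and cross spec -- to the
#' package's gzip-compressed JSON container, and reads it back losslessly.
#'
#' @param model A `widedeep_model`.
#' @param path File path (conventionally `.model.json.gz`).
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "widedeep_model"))
  obj <- list(
    format = "p300wd-container", version = 1L, type = "widedeep_model",
    dims = model$dims, leaky_slope = model$leaky_slope,
    branches = as.list(model$branches),
    feature_spec = list(blocks = model$feature_spec$blocks),
    cross_mat_b64 = jsonlite::base64_enc(writeBin(as.integer(model$cross$mat),
                                                  raw(), size = 1)),
    params = lapply(model$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           b64 = b64_doubles(p))
    })
  )
  write_container_json(obj, path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- read_container_json(path)
  if (!identical(obj$type, "widedeep_model")) {
    stopf("'%s' holds a %s, not a widedeep_model", path, obj$type)
  }
  bl <- obj$feature_spec$blocks
  spec <- sparse_feature_spec(as.character(bl$subject),
                              as.character(bl$sex),
                              as.character(bl$age_group))
  k <- as.integer(obj$dims$k)
  cmat <- matrix(as.logical(readBin(jsonlite::base64_dec(obj$cross_mat_b64),
                                    "integer", n = k * spec$total, size = 1)),
                 k, spec$total)
  model <- widedeep_model(spec, cross_spec(cmat, spec),
                          n_channels = as.integer(obj$dims$n_channels),
                          n_samples = as.integer(obj$dims$n_samples),
                          leaky_slope = as.numeric(obj$leaky_slope),
                          branches = unlist(obj$branches))
  for (nm in names(model$params)) {
    p <- obj$params[[nm]]
    d <- as.integer(p$dim)
    v <- unb64_doubles(p$b64, prod(d))
    if (length(d) > 1) dim(v) <- d
    if (nm == "b") v <- as.numeric(v)
    if (nm == "E") dim(v) <- d
    model$params[[nm]] <- v
  }
  model
}
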