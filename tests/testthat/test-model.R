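tiny_spec <- function() sparse_feature_spec(c("a", "b", "c"),
                                            age_groups = c("y", "o"))

test_that("sigmoid and the logistic loss match their closed forms", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  z <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(-z), 1 - sigmoid(z))
  expect_equal(logistic_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_equal(logistic_loss(0.25, 1), -log(0.25))
  expect_lte(logistic_loss(c(1, 0), c(1, 0)), -log(1 - 1e-7) + 1e-12)
  expect_error(logistic_loss(c(0.5, 0.5), 1), "length")
})

test_that("wide_logit is the dot product plus bias", {
  m <- wide_model(5)
  x <- rnorm(5)
  expect_equal(wide_logit(x, m), 0)
  m$w <- c(0, 0, 1, 0, 0)
  expect_equal(wide_logit(x, m), x[3])
  withr::with_seed(3, for (r in 1:10) {
    m$w <- rnorm(5); m$b <- rnorm(1)
    x <- rnorm(5)
    acc <- m$b
    for (i in 1:5) acc <- acc + m$w[i] * x[i]     # explicit summation oracle
    expect_equal(wide_logit(x, m), acc)
  })
  expect_error(wide_logit(rnorm(4), m), "match")
})

test_that("parameter counts match the architecture table", {
  expect_equal(count_parameters(wide_model(2700))$wide, 2701)
  spec <- tiny_spec()
  m <- widedeep_model(spec)
  cnt <- count_parameters(m)
  expect_equal(cnt$conv1, 16 * 1 * 7 + 16)
  expect_equal(cnt$conv2, 32 * 1 * 7 * 16 + 32)
  expect_equal(cnt$conv3, 16 * 7 * 32 + 16)
  expect_equal(cnt$dense, 6448)
  expect_equal(cnt$embedding, 90 * spec$total)
  expect_equal(cnt$wide, 2700 + spec$total + m$dims$k + 1)
  expect_equal(cnt$total, length(p300wd:::pack_params(m)))
})

test_that("the deep branch has the printed geometry", {
  spec <- tiny_spec()
  m <- widedeep_model(spec, seed = 4)
  expect_equal(m$dims$widths, c(42, 18, 13))
  p <- subject_profile("a", sex = "M", age_group = "y")
  d2 <- one_hot_encode(p, spec)
  ep <- matrix(rnorm(2700), 30, 90)
  fw <- deep_forward(ep, d2, m)
  expect_equal(dim(fw$concat), c(31, 90))
  expect_equal(fw$concat[1:30, ], ep)
  expect_length(fw$a_lf, 6448)
  # all-zero parameters give a zero logit
  m0 <- m
  m0$params <- lapply(m0$params, function(x) x * 0)
  expect_equal(deep_forward(ep, d2, m0)$deep_logit, 0)
  expect_error(deep_forward(ep, c(d2, 0), m), "length")
})

test_that("the matrix conv implementation matches a naive loop", {
  withr::with_seed(11, {
    N <- 4L; W <- 12L; Cin <- 3L; Cout <- 2L; kw <- 7L
    H <- matrix(rnorm(N * W * Cin), N, W * Cin)
    K <- array(rnorm(kw * Cin * Cout), c(kw, Cin, Cout))
    bias <- rnorm(Cout)
    for (geom in list(c(stride = 2L, pad = 0L), c(stride = 1L, pad = 1L))) {
      fw <- p300wd:::conv1d_forward(H, W, Cin, K, bias, geom["stride"],
                                    geom["pad"])
      Wp <- W + geom["pad"]
      P <- (Wp - kw) %/% geom["stride"] + 1L
      ref <- array(0, c(N, P, Cout))
      Hp <- array(0, c(N, Wp, Cin))
      Hp[, (geom["pad"] + 1):Wp, ] <- array(H, c(N, W, Cin))
      for (n in 1:N) for (p in 1:P) for (o in 1:Cout) {
        s <- (p - 1) * geom["stride"]
        acc <- bias[o]
        for (j in 1:kw) for (c in 1:Cin) {
          acc <- acc + Hp[n, s + j, c] * K[j, c, o]
        }
        ref[n, p, o] <- acc
      }
      got <- fw$out
      dim(got) <- c(N, P, Cout)
      expect_equal(got, ref)
    }
  })
})

test_that("combined prediction decomposes bit-exactly into its branches", {
  spec <- tiny_spec()
  m <- widedeep_model(spec, seed = 8)
  withr::with_seed(9, {
    m$params$wide_w <- rnorm(m$dims$dw, 0, 0.01)
    m$params$b <- 0.3
    p <- subject_profile("b", sex = "F", age_group = "o")
    for (r in 1:5) {
      ep <- matrix(rnorm(2700), 30, 90)
      d2 <- one_hot_encode(p, spec)
      x <- assemble_wide_input(ep, d2, cross_products(d2, m$cross))
      wl <- sum(m$params$wide_w * x)                # wide logit, bias shared
      dl <- deep_forward(ep, d2, m)$deep_logit
      expect_identical(combined_predict(ep, p, m),
                       sigmoid(wl + dl + m$params$b))
    }
  })
  # an all-zero model predicts exactly 0.5
  m0 <- m
  m0$params <- lapply(m0$params, function(x) x * 0)
  expect_equal(combined_predict(matrix(rnorm(2700), 30, 90),
                                subject_profile("zz", sex = "M",
                                                age_group = "y"), m0), 0.5)
})

test_that("batched prediction with cached encodings equals per-epoch calls", {
  spec <- tiny_spec()
  m <- widedeep_model(spec, seed = 12)
  withr::with_seed(13, {
    m$params$wide_w <- rnorm(m$dims$dw, 0, 0.01)
    n <- 6
    eps <- array(rnorm(n * 30 * 90), c(n, 30, 90))
    profs <- list(a = subject_profile("a", sex = "M", age_group = "y"),
                  b = subject_profile("b", sex = "F", age_group = "o"))
    ids <- rep(c("a", "b"), 3)
    es <- epoch_set(eps, rep(0, n), ids, 100)
    batched <- predict(m, es, profs)
    single <- vapply(seq_len(n), function(i) {
      combined_predict(eps[i, , ], profs[[ids[i]]], m)
    }, 0)
    expect_equal(batched, single, tolerance = 1e-12)
  })
})

test_that("analytic gradients match finite differences on every block", {
  spec <- tiny_spec()
  m <- widedeep_model(spec, seed = 2)
  withr::with_seed(99, {
    n <- 3
    eps <- array(rnorm(n * 30 * 90), c(n, 30, 90))
    D2 <- rbind(one_hot_encode(subject_profile("a", sex = "M", age_group = "y"), spec),
                one_hot_encode(subject_profile("b", sex = "F", age_group = "o"), spec),
                one_hot_encode(subject_profile("c", sex = "M", age_group = "o"), spec))
    PHI <- matrix(rnorm(n * m$dims$k), n, m$dims$k)
    y <- c(1, 0, 1)
    layout <- p300wd:::param_layout(m)
    theta <- p300wd:::pack_params(m)
    theta[layout$wide_w] <- rnorm(length(layout$wide_w), 0, 0.01)
    m <- p300wd:::unpack_params(m, theta)
    loss_at <- function(th) {
      mm <- p300wd:::unpack_params(m, th)
      cl <- p300wd:::combined_logits(mm, eps, D2, PHI)
      logistic_loss(sigmoid(cl$logit), y)
    }
    cl <- p300wd:::combined_logits(m, eps, D2, PHI, keep_cache = TRUE)
    d <- (sigmoid(cl$logit) - y) / n
    g <- numeric(length(theta))
    g[layout$wide_w] <- as.numeric(crossprod(cl$Xw, d))
    g[layout$b] <- sum(d)
    dg <- p300wd:::deep_backward_batch(m, cl$deep_cache, d)
    for (nm in c("E", "K1", "b1", "K2", "b2", "K3", "b3", "dense")) {
      g[layout[[nm]]] <- as.numeric(dg[[nm]])
    }
    h <- 1e-5
    for (nm in names(layout)) {
      for (i in sample(layout[[nm]], min(5, length(layout[[nm]])))) {
        tp <- theta; tp[i] <- tp[i] + h
        tm <- theta; tm[i] <- tm[i] - h
        gn <- (loss_at(tp) - loss_at(tm)) / (2 * h)
        expect_lt(abs(gn - g[i]), 5e-3)
      }
    }
  })
})

test_that("model serialization roundtrips weights and predictions", {
  spec <- tiny_spec()
  m <- widedeep_model(spec, seed = 21)
  withr::with_seed(22, m$params$wide_w <- rnorm(m$dims$dw, 0, 0.01))
  tf <- withr::local_tempfile(fileext = ".model.json.gz")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cross$mat, unname(m$cross$mat))
  expect_identical(m2$branches, m$branches)
  ep <- matrix(seq_len(2700) / 1000, 30, 90)
  p <- subject_profile("b", sex = "F", age_group = "o")
  expect_identical(combined_predict(ep, p, m2), combined_predict(ep, p, m))
})
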