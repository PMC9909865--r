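# Network forward passes and the four loss quantities.

test_that("class probabilities follow the two-logit softmax and are stable", {
  expect_equal(unname(class_probabilities(c(0, 0))), matrix(0.5, 1, 2),
               ignore_attr = TRUE)
  expect_equal(unname(class_probabilities(c(0, log(3)))[1, ]),
               c(0.25, 0.75), tolerance = 1e-12)
  p <- class_probabilities(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(unname(p[1, 1]), 1, tolerance = 1e-12)
  withr::with_seed(1, l <- matrix(rnorm(2000, sd = 5), ncol = 2))
  expect_equal(rowSums(class_probabilities(l)), rep(1, 1000),
               tolerance = 1e-12)
})

test_that("supervised loss is the mean negative log-likelihood", {
  l <- matrix(c(10, -10, -10, 10), 2, byrow = TRUE)
  expect_lt(supervised_loss(l, c("benign", "oncogenic")), 1e-8)
  l0 <- matrix(0, 4, 2)
  expect_equal(supervised_loss(l0, rep(c("benign", "oncogenic"), 2)), log(2))
  withr::with_seed(2, {
    l <- matrix(rnorm(200), ncol = 2)
    y <- sample(1:2, 100, replace = TRUE)
  })
  # elementwise hand-computed cross entropy
  p <- exp(l) / rowSums(exp(l))
  want <- -mean(log(p[cbind(1:100, y)]))
  expect_equal(supervised_loss(l, y), want, tolerance = 1e-9)
  expect_error(supervised_loss(l, rep("unlabeled", 100)), "unlabeled")
})

test_that("real/fake probability equals Z/(Z+1) and the appended-zero-logit softmax complement", {
  expect_equal(real_fake_probability(c(0, 0)), 2 / 3, tolerance = 1e-15)
  expect_lt(real_fake_probability(c(-1000, -1000)), 1e-300)
  withr::with_seed(3, l <- matrix(rnorm(2000, sd = 10), ncol = 2))
  d <- real_fake_probability(l)
  p3 <- t(apply(cbind(l, 0), 1, function(r) {
    e <- exp(r - max(r))
    e / sum(e)
  }))
  expect_lt(max(abs(d - (1 - p3[, 3]))), 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  # strictly inside (0,1) wherever the result is representable
  withr::with_seed(33, lm <- matrix(rnorm(400, sd = 3), ncol = 2))
  dm <- real_fake_probability(lm)
  expect_true(all(dm > 0 & dm < 1))
  # monotone increasing in each logit
  base <- matrix(c(0.3, -0.2), 1)
  expect_gt(real_fake_probability(base + c(0.1, 0)),
            real_fake_probability(base))
  expect_gt(real_fake_probability(base + c(0, 0.1)),
            real_fake_probability(base))
})

test_that("unsupervised loss matches its displayed formula", {
  expect_equal(unsupervised_loss(matrix(0, 1, 2), matrix(0, 1, 2)),
               -(log(2 / 3) + log(1 / 3)), tolerance = 1e-12)
  # optimal-discriminator limit
  expect_lt(unsupervised_loss(matrix(20, 5, 2), matrix(-20, 5, 2)), 1e-7)
  # naive evaluation oracle in the non-overflow regime
  withr::with_seed(4, {
    lr <- matrix(rnorm(100), ncol = 2)
    lf <- matrix(rnorm(100), ncol = 2)
  })
  dr <- rowSums(exp(lr)) / (rowSums(exp(lr)) + 1)
  df <- rowSums(exp(lf)) / (rowSums(exp(lf)) + 1)
  expect_equal(unsupervised_loss(lr, lf), -(mean(log(dr)) + mean(log(1 - df))),
               tolerance = 1e-9)
  expect_equal(discriminator_loss(0.5, 1.0), 1.5)
})

test_that("feature matching is the squared norm of the mean-feature difference", {
  a <- matrix(rnorm(50), 10)
  expect_equal(feature_matching_loss(a, a), 0)
  b <- sweep(a, 2, c(0.3, -0.4, 0, 0, 0), "+")
  expect_equal(feature_matching_loss(b, a), 0.25, tolerance = 1e-12)
  withr::with_seed(5, {
    r <- matrix(rnorm(200), 20)
    f <- matrix(rnorm(100), 10)
  })
  expect_equal(feature_matching_loss(r, f),
               sum((colMeans(r) - colMeans(f))^2), tolerance = 1e-9)
  expect_error(feature_matching_loss(r, matrix(0, 4, 3)), "mismatch")
})

test_that("generator output lies in [0,1] and is deterministic in evaluation mode", {
  withr::with_seed(6, {
    model <- sgan_model(generator_spec(noise_dim = 12, hidden = c(8, 8, 8),
                                       output_dim = 40),
                        discriminator_spec(input_dim = 40,
                                           channels = c(2, 4, 4)))
    z <- matrix(rnorm(500 * 12), 500)
  })
  out <- generator_forward(model, z)
  expect_equal(dim(out), c(500L, 40L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, generator_forward(model, z))
  expect_error(generator_forward(model, matrix(0, 5, 3)), "noise dimension")
})

test_that("discriminator exposes two logits and the penultimate features", {
  withr::with_seed(7, {
    model <- sgan_model(generator_spec(noise_dim = 6, hidden = c(4, 4, 4),
                                       output_dim = 30),
                        discriminator_spec(input_dim = 30,
                                           channels = c(2, 4, 4)))
    x <- matrix(runif(20 * 30), 20)
  })
  fw <- discriminator_forward(model, x)
  expect_equal(ncol(fw$logits), 2L)
  expect_true(all(is.finite(fw$logits)))
  expect_equal(nrow(fw$features), 20L)
  expect_error(discriminator_forward(model, x[, 1:10]), "expects")
})

test_that("analytic gradients match finite differences", {
  eps <- 1e-6
  withr::with_seed(8, {
    model <- sgan_model(generator_spec(noise_dim = 5, hidden = c(4, 4, 4),
                                       output_dim = 15, dropout = 0),
                        discriminator_spec(input_dim = 15,
                                           channels = c(2, 3, 3)))
    X <- matrix(runif(6 * 15), 6)
    y <- rep(1:2, 3)
  })
  disc <- model$discriminator
  fw <- oncosgan:::disc_forward(disc, X)
  bw <- oncosgan:::disc_backward(disc, fw$cache,
                                 dlogits = oncosgan:::supervised_loss_grad(fw$logits, y),
                                 need_input_grad = TRUE)
  loss_d <- function(d, Xm = X) {
    supervised_loss(oncosgan:::disc_forward(d, Xm)$logits, y)
  }
  for (leaf in list(c("conv", 1L, "K"), c("conv", 3L, "K"), c("head", "W"))) {
    p <- disc$params[[leaf[1]]]
    p <- if (length(leaf) == 3L) p[[as.integer(leaf[2])]][[leaf[3]]] else p[[leaf[2]]]
    g_an <- bw$grads[[leaf[1]]]
    g_an <- if (length(leaf) == 3L) g_an[[as.integer(leaf[2])]][[leaf[3]]] else g_an[[leaf[2]]]
    g_num <- p * 0
    for (i in seq_along(p)) {
      d2 <- disc
      setp <- function(v) {
        if (length(leaf) == 3L) {
          d2$params[[leaf[1]]][[as.integer(leaf[2])]][[leaf[3]]][i] <<- v
        } else {
          d2$params[[leaf[1]]][[leaf[2]]][i] <<- v
        }
      }
      setp(p[i] + eps); f1 <- loss_d(d2)
      setp(p[i] - eps); f0 <- loss_d(d2)
      g_num[i] <- (f1 - f0) / (2 * eps)
    }
    expect_lt(max(abs(g_num - g_an)), 1e-7)
  }
  # input gradient
  gX <- X * 0
  for (i in seq_along(X)) {
    X2 <- X; X2[i] <- X[i] + eps; f1 <- loss_d(disc, X2)
    X2[i] <- X[i] - eps; f0 <- loss_d(disc, X2)
    gX[i] <- (f1 - f0) / (2 * eps)
  }
  expect_lt(max(abs(gX - bw$dX)), 1e-7)

  # generator side (through training-mode batch normalization)
  gen <- model$generator
  Z <- matrix(rnorm(8 * 5), 8)
  target <- matrix(runif(8 * 15), 8)
  loss_g <- function(g) {
    sum((oncosgan:::gen_forward(g, Z, training = TRUE)$out - target)^2)
  }
  fwg <- oncosgan:::gen_forward(gen, Z, training = TRUE)
  gr <- oncosgan:::gen_backward(gen, fwg$cache, 2 * (fwg$out - target))
  for (nm in c("W", "gamma", "beta")) {
    p <- gen$params$layers[[2]][[nm]]
    g_num <- p * 0
    for (i in seq_along(p)) {
      g2 <- gen
      g2$params$layers[[2]][[nm]][i] <- p[i] + eps; f1 <- loss_g(g2)
      g2$params$layers[[2]][[nm]][i] <- p[i] - eps; f0 <- loss_g(g2)
      g_num[i] <- (f1 - f0) / (2 * eps)
    }
    expect_lt(max(abs(g_num - gr$layers[[2]][[nm]])), 1e-6)
  }
})

test_that("a discriminator step on separable data strictly decreases its loss", {
  blobs <- make_blobs(n_per_class = 32L, d = 20L, sep = 8, seed = 9)
  withr::with_seed(10, {
    model <- sgan_model(tiny_gspec(20L), tiny_dspec(20L))
    fake <- matrix(runif(32 * 20), 32)
  })
  cfg <- quick_config(learning_rate = 0.01)
  opt <- oncosgan:::adam_init(model$discriminator$params)
  before <- {
    fwl <- discriminator_forward(model, blobs$x)
    fwu <- discriminator_forward(model, blobs$x)
    fwf <- discriminator_forward(model, fake)
    discriminator_loss(supervised_loss(fwl$logits, blobs$y),
                       unsupervised_loss(fwu$logits, fwf$logits))
  }
  st <- discriminator_step(model, opt, blobs$x, blobs$y, blobs$x, fake, cfg)
  after <- {
    fwl <- discriminator_forward(st$model, blobs$x)
    fwf <- discriminator_forward(st$model, fake)
    discriminator_loss(supervised_loss(fwl$logits, blobs$y),
                       unsupervised_loss(fwl$logits, fwf$logits))
  }
  expect_equal(discriminator_loss(st$sup, st$unsup), before,
               tolerance = 1e-10)
  expect_lt(after, before)
})
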