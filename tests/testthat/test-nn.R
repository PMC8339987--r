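# Finite-difference gradient checks for every network building block
# (central differences; ReLU layers use small random nets where the
# pre-activations stay away from the kink with overwhelming probability).

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("LSTM forward/backward gradients are exact", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5, 3)
  p <- ctstager:::init_lstm(3, 4)
  dH <- matrix(rnorm(5 * 4), 5, 4)
  loss <- function(X, p) sum(ctstager:::lstm_forward(X, p)$H * dH)
  fw <- ctstager:::lstm_forward(X, p)
  bk <- ctstager:::lstm_backward(dH, fw, p)
  expect_lt(max(abs(num_grad(function(x) loss(matrix(x, 5, 3), p), as.vector(X)) -
                      as.vector(bk$dX))), 1e-6)
  for (nm in c("W", "U", "b")) {
    got <- bk$grads[[nm]]
    num <- num_grad(function(v) { p2 <- p; p2[[nm]][] <- v; loss(X, p2) },
                    as.vector(p[[nm]]))
    expect_lt(max(abs(num - as.vector(got))), 1e-6)
  }
})

test_that("attention pooling gradients are exact", {
  set.seed(2)
  H <- matrix(rnorm(6 * 4), 6, 4)
  p <- list(Wa = ctstager:::init_mat(4, 3), ba = rnorm(3), va = rnorm(3))
  dctx <- rnorm(4)
  loss <- function(H, p) sum(ctstager:::attn_forward(H, p)$ctx * dctx)
  fw <- ctstager:::attn_forward(H, p)
  bk <- ctstager:::attn_backward(dctx, fw, p)
  expect_lt(max(abs(num_grad(function(x) loss(matrix(x, 6, 4), p), as.vector(H)) -
                      as.vector(bk$dH))), 1e-6)
  for (nm in names(p)) {
    num <- num_grad(function(v) { p2 <- p; p2[[nm]][] <- v; loss(H, p2) },
                    as.vector(p[[nm]]))
    expect_lt(max(abs(num - as.vector(bk$grads[[nm]]))), 1e-6)
  }
})

test_that("dilated convolution gradients are exact", {
  set.seed(3)
  X <- matrix(rnorm(6 * 3), 6, 3)
  p <- ctstager:::init_conv(3, 2)
  dA <- matrix(rnorm(6 * 2), 6, 2)
  for (dil in c(1L, 2L)) {
    loss <- function(X, p) sum(ctstager:::conv_forward(X, p, dil)$A * dA)
    fw <- ctstager:::conv_forward(X, p, dil)
    bk <- ctstager:::conv_backward(dA, fw, p, dil)
    expect_lt(max(abs(num_grad(function(x) loss(matrix(x, 6, 3), p), as.vector(X)) -
                        as.vector(bk$dX))), 1e-5)
    for (nm in names(p)) {
      num <- num_grad(function(v) { p2 <- p; p2[[nm]][] <- v; loss(X, p2) },
                      as.vector(p[[nm]]))
      expect_lt(max(abs(num - as.vector(bk$grads[[nm]]))), 1e-5)
    }
  }
})

full_model_grad_check <- function(arch) {
  cfg <- ner_config(char_embedding_dim = 3, seg_embedding_dim = 2,
                    hidden_units = 4, dropout_rate = 0, seed = 1)
  ex <- list(char_ids = c(2L, 3L, 4L, 2L, 5L), seg_ids = c(1L, 2L, 4L, 1L, 1L),
             gold = c(1L, 2L, 3L, 1L, 4L))
  labs <- paste0("L", 1:5)
  ## draw parameters whose ReLU pre-activations stay away from the kink,
  ## where the loss is genuinely non-differentiable and finite
  ## differences are meaningless
  repeat {
    p <- ctstager:::init_ner_params(arch, 6L, cfg, 5L)
    if (arch == "bilstm_crf") break
    fwd0 <- ctstager:::ner_encode(p, arch, ex, cfg, train = FALSE)
    zs <- c(fwd0$enc$c0$cache$Z,
            unlist(lapply(fwd0$enc$blocks, function(b)
              c(b$s1$cache$Z, b$s2$cache$Z, b$s3$cache$Z))))
    if (min(abs(zs)) > 1e-3) break
  }
  lossfun <- function(p) {
    fwd <- ctstager:::ner_encode(p, arch, ex, cfg, train = FALSE)
    ctstager:::crf_loss_grad(fwd$emissions,
                             ctstager:::as_crf_params(p$crf, labs), ex$gold)$loss
  }
  eps <- 1e-6
  fwd <- ctstager:::ner_encode(p, arch, ex, cfg, train = FALSE)
  cg <- ctstager:::crf_loss_grad(fwd$emissions,
                                 ctstager:::as_crf_params(p$crf, labs), ex$gold)
  g <- ctstager:::ner_backward(p, arch, ex, cfg, fwd, cg$d_emissions)
  fl_p <- ctstager:::flatten_params(p)
  fl_g <- ctstager:::flatten_params(g)
  worst <- 0
  for (k in setdiff(names(fl_p), c("crf.transitions", "crf.start", "crf.stop"))) {
    for (ii in sample(length(fl_p[[k]]), min(5L, length(fl_p[[k]])))) {
      up <- fl_p; up[[k]][ii] <- up[[k]][ii] + eps
      dn <- fl_p; dn[[k]][ii] <- dn[[k]][ii] - eps
      num <- (lossfun(ctstager:::unflatten_params(up, p)) -
                lossfun(ctstager:::unflatten_params(dn, p))) / (2 * eps)
      worst <- max(worst, abs(num - fl_g[[k]][ii]))
    }
  }
  worst
}

test_that("end-to-end tagger gradients are exact for both architectures", {
  set.seed(4)
  expect_lt(full_model_grad_check("bilstm_crf"), 1e-5)
  set.seed(5)
  expect_lt(full_model_grad_check("idcnn_crf"), 1e-5)
})

test_that("relation-classifier gradients are exact", {
  set.seed(6)
  cfg <- rc_config(embedding_dim = 3, hidden_units = 4, attention_dim = 3,
                   dropout_rate = 0)
  p <- list(E = ctstager:::init_mat(7, 3),
            lstm_f = ctstager:::init_lstm(3, 4), lstm_b = ctstager:::init_lstm(3, 4),
            attn = list(Wa = ctstager:::init_mat(8, 3), ba = rep(0, 3),
                        va = runif(3, -0.1, 0.1)),
            Wo = ctstager:::init_mat(8, 5), bo = rep(0, 5))
  ids <- c(2L, 3L, 4L, 5L, 2L, 6L); y <- 3L
  loss <- function(p) {
    f <- ctstager:::rc_forward(p, ids, cfg)
    -log(ctstager:::softmax(f$logits)[y])
  }
  f <- ctstager:::rc_forward(p, ids, cfg)
  pr <- ctstager:::softmax(f$logits)
  dlog <- pr; dlog[y] <- dlog[y] - 1
  g <- ctstager:::rc_backward(p, ids, cfg, f, dlog)
  fl_p <- ctstager:::flatten_params(p)
  fl_g <- ctstager:::flatten_params(g)
  eps <- 1e-5
  for (k in names(fl_p)) {
    for (ii in sample(length(fl_p[[k]]), min(5L, length(fl_p[[k]])))) {
      up <- fl_p; up[[k]][ii] <- up[[k]][ii] + eps
      dn <- fl_p; dn[[k]][ii] <- dn[[k]][ii] - eps
      num <- (loss(ctstager:::unflatten_params(up, p)) -
                loss(ctstager:::unflatten_params(dn, p))) / (2 * eps)
      expect_lt(abs(num - fl_g[[k]][ii]), 1e-5)
    }
  }
})

test_that("Adam reduces a simple quadratic objective deterministically", {
  p <- list(w = matrix(c(3, -2, 1, 4), 2, 2))
  st <- ctstager:::adam_new(p)
  for (i in 1:200) {
    g <- list(w = 2 * p$w)
    up <- ctstager:::adam_step(p, g, st, lr = 0.1)
    p <- up$params; st <- up$state
  }
  expect_lt(max(abs(p$w)), 0.05)
})
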