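## Minimal neural toolkit in base R: embeddings, LSTM / bidirectional
## LSTM, dilated width-3 convolutions, additive attention, dense layers,
## dropout and Adam. Forward functions return caches; backward functions
## consume them. Everything is validated by finite-difference gradient
## checks in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_mat <- function(nr, nc, scale = sqrt(6 / (nr + nc))) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

init_lstm <- function(input_dim, hidden) {
  H <- hidden
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1   # forget-gate bias
  list(W = init_mat(input_dim, 4L * H), U = init_mat(H, 4L * H), b = b)
}

lstm_forward <- function(X, p) {
  T_ <- nrow(X); H <- ncol(p$U)/4L
  ii <- 1:H; ff <- (H+1L):(2L*H); gg <- (2L*H+1L):(3L*H); oo <- (3L*H+1L):(4L*H)
  Z0 <- X %*% p$W
  I <- Fm <- G <- O <- C <- HC <- Hs <- matrix(0, T_, H)
  h <- rep(0, H); cc <- rep(0, H)
  dZ_cache_Hprev <- matrix(0, T_, H)
  for (t in seq_len(T_)) {
    dZ_cache_Hprev[t, ] <- h
    z <- Z0[t, ] + as.vector(h %*% p$U) + p$b
    i <- sigmoid(z[ii]); f <- sigmoid(z[ff]); g <- tanh(z[gg]); o <- sigmoid(z[oo])
    cprev <- cc
    cc <- f * cprev + i * g
    hc <- tanh(cc)
    h <- o * hc
    I[t, ] <- i; Fm[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- cc; HC[t, ] <- hc; Hs[t, ] <- h
  }
  list(H = Hs, cache = list(X = X, I = I, F = Fm, G = G, O = O, C = C,
                            HC = HC, Hprev = dZ_cache_Hprev))
}

lstm_backward <- function(dH, fw, p) {
  cache <- fw$cache
  T_ <- nrow(dH); H <- ncol(dH)
  dZ <- matrix(0, T_, 4L * H)
  ii <- 1:H; ff <- (H+1L):(2L*H); gg <- (2L*H+1L):(3L*H); oo <- (3L*H+1L):(4L*H)
  dh_next <- rep(0, H); dc_next <- rep(0, H)
  for (t in rev(seq_len(T_))) {
    dh <- dH[t, ] + dh_next
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]; o <- cache$O[t, ]
    hc <- cache$HC[t, ]
    cprev <- if (t > 1L) cache$C[t - 1L, ] else rep(0, H)
    do_ <- dh * hc
    dc <- dh * o * (1 - hc^2) + dc_next
    di <- dc * g; dg <- dc * i; df <- dc * cprev
    dc_next <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do_ * o * (1 - o))
    dZ[t, ] <- dz
    dh_next <- as.vector(dz %*% t(p$U))
  }
  list(dX = dZ %*% t(p$W),
       grads = list(W = t(cache$X) %*% dZ,
                    U = t(cache$Hprev) %*% dZ,
                    b = colSums(dZ)))
}

## bidirectional LSTM: output is [forward ; backward] concatenation
bilstm_forward <- function(X, pf, pb) {
  T_ <- nrow(X)
  fw <- lstm_forward(X, pf)
  bw <- lstm_forward(X[rev(seq_len(T_)), , drop = FALSE], pb)
  list(H = cbind(fw$H, bw$H[rev(seq_len(T_)), , drop = FALSE]),
       fw = fw, bw = bw)
}

bilstm_backward <- function(dH, st, pf, pb) {
  T_ <- nrow(dH); H <- ncol(dH)/2L
  bf <- lstm_backward(dH[, 1:H, drop = FALSE], st$fw, pf)
  db <- lstm_backward(dH[rev(seq_len(T_)), (H+1L):(2L*H), drop = FALSE], st$bw, pb)
  list(dX = bf$dX + db$dX[rev(seq_len(T_)), , drop = FALSE],
       grads_f = bf$grads, grads_b = db$grads)
}

## width-3 dilated convolution over time
shift_rows <- function(X, k) {
  ## returns X shifted so row t holds X[t - k, ] (zero padded)
  T_ <- nrow(X); out <- matrix(0, T_, ncol(X))
  if (k >= 0) { if (T_ > k) out[(k + 1L):T_, ] <- X[seq_len(T_ - k), , drop = FALSE] }
  else { k <- -k; if (T_ > k) out[seq_len(T_ - k), ] <- X[(k + 1L):T_, , drop = FALSE] }
  out
}

init_conv <- function(din, dout) {
  list(W1 = init_mat(din, dout), W2 = init_mat(din, dout),
       W3 = init_mat(din, dout), b = rep(0, dout))
}

conv_forward <- function(X, p, dilation) {
  Xm <- shift_rows(X, dilation); Xp <- shift_rows(X, -dilation)
  Z <- Xm %*% p$W1 + X %*% p$W2 + Xp %*% p$W3
  Z <- sweep(Z, 2L, p$b, "+")
  A <- pmax(Z, 0)
  list(A = A, cache = list(X = X, Xm = Xm, Xp = Xp, Z = Z))
}

conv_backward <- function(dA, st, p, dilation) {
  dZ <- dA * (st$cache$Z > 0)
  dX <- shift_rows(dZ %*% t(p$W1), -dilation) + dZ %*% t(p$W2) +
    shift_rows(dZ %*% t(p$W3), dilation)
  list(dX = dX,
       grads = list(W1 = t(st$cache$Xm) %*% dZ, W2 = t(st$cache$X) %*% dZ,
                    W3 = t(st$cache$Xp) %*% dZ, b = colSums(dZ)))
}

## additive (tanh) attention pooling over time
attn_forward <- function(H, p) {
  U <- tanh(sweep(H %*% p$Wa, 2L, p$ba, "+"))
  s <- as.vector(U %*% p$va)
  s <- s - max(s)
  a <- exp(s) / sum(exp(s))
  list(ctx = as.vector(t(H) %*% a), cache = list(H = H, U = U, a = a))
}

attn_backward <- function(dctx, st, p) {
  H <- st$cache$H; U <- st$cache$U; a <- st$cache$a
  dH <- a %o% dctx
  da <- as.vector(H %*% dctx)
  ds <- a * (da - sum(da * a))
  dU <- ds %o% p$va
  dZ <- dU * (1 - U^2)
  list(dH = dH + dZ %*% t(p$Wa),
       grads = list(Wa = t(H) %*% dZ, ba = colSums(dZ), va = as.vector(t(U) %*% ds)))
}

softmax <- function(x) { x <- x - max(x); e <- exp(x); e / sum(e) }

## embedding gradient: scatter-add rows of dX into a V x d matrix
emb_grad <- function(dX, ids, V) {
  g <- matrix(0, V, ncol(dX))
  agg <- rowsum(dX, group = ids)
  g[as.integer(rownames(agg)), ] <- agg
  g
}

## inverted dropout; returns the mask (1/keep scaled) or NULL when off
dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix(stats::rbinom(dim1 * dim2, 1L, keep), dim1, dim2) / keep
}

## ---- Adam over a nested named list of parameters --------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

adam_new <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(x) x * 0), v = lapply(fl, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(params); fg <- flatten_params(grads)
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(fp)) {
    g <- fg[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mh <- state$m[[k]] / (1 - beta1^t)
    vh <- state$v[[k]] / (1 - beta2^t)
    fp[[k]] <- fp[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = unflatten_params(fp, params), state = state)
}

unflatten_params <- function(flat, template, prefix = "") {
  for (nm in names(template)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(template[[nm]])) {
      template[[nm]] <- unflatten_params(flat, template[[nm]], key)
    } else if (!is.null(flat[[key]])) {
      template[[nm]] <- flat[[key]]
    }
  }
  template
}

## elementwise sum of two nested grad lists (a may be NULL)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) acc_grads(a[[nm]], b[[nm]]) else a[[nm]] + b[[nm]]
  }
  a
}
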