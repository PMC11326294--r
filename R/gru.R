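# Minimal gated-recurrent-unit sequence classifier: GRU cell -> dropout on
# the final hidden state -> layer normalization -> affine -> logistic output.
# Written directly in base R (batched matrix algebra, analytic gradients,
# Adam); the network is tiny (input 2, hidden 3) so this trains in seconds
# on one CPU.  Gradients are checked against finite differences in the test
# suite.

.gru_init <- function(input_size, hidden_size, seed) {
  set.seed(seed)
  s <- 1 / sqrt(hidden_size)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  list(Wi = u(3 * hidden_size, input_size),
       Wh = u(3 * hidden_size, hidden_size),
       bi = stats::runif(3 * hidden_size, -s, s),
       bh = stats::runif(3 * hidden_size, -s, s),
       gamma = rep(1, hidden_size), beta = rep(0, hidden_size),
       w = stats::runif(hidden_size, -s, s),
       b = stats::runif(1, -s, s),
       H = hidden_size, I = input_size)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# X: array (B, T, I); returns list with probs and the cache for backprop.
# drop_mask: NULL (eval) or a (B, H) inverted-dropout mask.
.gru_forward <- function(par, X, drop_mask = NULL, ln_eps = 1e-5) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- par$H
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  h <- matrix(0, B, H)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, par$I)
    Ai <- xt %*% t(par$Wi) + matrix(par$bi, B, 3 * H, byrow = TRUE)
    Ah <- h %*% t(par$Wh) + matrix(par$bh, B, 3 * H, byrow = TRUE)
    r <- .sigmoid(Ai[, i1, drop = FALSE] + Ah[, i1, drop = FALSE])
    z <- .sigmoid(Ai[, i2, drop = FALSE] + Ah[, i2, drop = FALSE])
    q <- Ah[, i3, drop = FALSE]
    nn <- tanh(Ai[, i3, drop = FALSE] + r * q)
    cache[[t]] <- list(x = xt, h_prev = h, r = r, z = z, q = q, nn = nn)
    h <- (1 - z) * nn + z * h
  }
  hd <- if (is.null(drop_mask)) h else h * drop_mask
  mu <- rowMeans(hd)
  va <- rowMeans((hd - mu)^2)
  sd_ <- sqrt(va + ln_eps)
  xh <- (hd - mu) / sd_
  y <- xh * matrix(par$gamma, B, H, byrow = TRUE) +
    matrix(par$beta, B, H, byrow = TRUE)
  logit <- drop(y %*% par$w) + par$b
  list(prob = .sigmoid(logit), cache = cache, h = h, hd = hd, xh = xh,
       sd = sd_, y = y, drop_mask = drop_mask)
}

# Backward pass for mean BCE loss; returns gradient list matching par.
.gru_backward <- function(par, X, fwd, target) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- par$H
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  g <- list(Wi = 0 * par$Wi, Wh = 0 * par$Wh, bi = 0 * par$bi,
            bh = 0 * par$bh, gamma = 0 * par$gamma, beta = 0 * par$beta,
            w = 0 * par$w, b = 0)
  dlogit <- (fwd$prob - target) / B
  g$w <- drop(t(fwd$y) %*% dlogit)
  g$b <- sum(dlogit)
  dy <- outer(dlogit, par$w)
  g$gamma <- colSums(dy * fwd$xh)
  g$beta <- colSums(dy)
  dxh <- dy * matrix(par$gamma, B, H, byrow = TRUE)
  # layer-norm backward (means over the H features, per sample)
  dhd <- (dxh - rowMeans(dxh) - fwd$xh * rowMeans(dxh * fwd$xh)) / fwd$sd
  dh <- if (is.null(fwd$drop_mask)) dhd else dhd * fwd$drop_mask
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dz <- dh * (cc$h_prev - cc$nn) * cc$z * (1 - cc$z)
    dnn <- dh * (1 - cc$z) * (1 - cc$nn^2)
    dr <- dnn * cc$q * cc$r * (1 - cc$r)
    dAi <- cbind(dr, dz, dnn)
    dAh <- cbind(dr, dz, dnn * cc$r)
    g$Wi <- g$Wi + t(dAi) %*% cc$x
    g$Wh <- g$Wh + t(dAh) %*% cc$h_prev
    g$bi <- g$bi + colSums(dAi)
    g$bh <- g$bh + colSums(dAh)
    dh <- dh * cc$z + dAh %*% par$Wh
  }
  g
}

.bce_loss <- function(prob, target, eps = 1e-12) {
  -mean(target * log(prob + eps) + (1 - target) * log(1 - prob + eps))
}

.adam_init <- function(par) {
  nm <- c("Wi", "Wh", "bi", "bh", "gamma", "beta", "w", "b")
  list(m = lapply(par[nm], function(p) 0 * p),
       v = lapply(par[nm], function(p) 0 * p), t = 0)
}

.adam_step <- function(par, grad, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(st$m)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grad[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}
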