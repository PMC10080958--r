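# Minimal convolutional-network engine (forward + backprop) sufficient for
# the eyes-open/eyes-closed classifier: 3x3 same-padding convolutions
# implemented as nine shifted GEMMs, per-channel batch normalization, ReLU,
# 2x2 max pooling, a fully connected softmax head, and plain SGD. The
# environment provides no deep-learning framework, so the architecture is
# implemented directly; gradients are verified against finite differences
# in the test suite.
#
# Activations are arrays of dim (h, w, n, c): spatial dims first so a 3x3
# shift is a contiguous sub-assignment and the channel GEMM is a single
# reshape.

shift2 <- function(x, di, dj) {
  # zero-padded spatial shift of (h, w, n, c): out[i, j] = x[i + di, j + dj]
  d <- dim(x); h <- d[1]; w <- d[2]
  out <- array(0, d)
  si <- max(1, 1 + di):min(h, h + di)
  sj <- max(1, 1 + dj):min(w, w + dj)
  out[si - di, sj - dj, , ] <- x[si, sj, , , drop = FALSE]
  out
}

conv3_fwd <- function(x, W, b) {
  # W: list of 9 (cin x cout) matrices in (di, dj) order; b: cout vector
  d <- dim(x); cin <- d[4]; cout <- ncol(W[[1]])
  acc <- matrix(0, d[1] * d[2] * d[3], cout)
  k <- 0L
  cache_shifts <- vector("list", 9L)
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    xs <- shift2(x, di, dj)
    cache_shifts[[k]] <- xs
    dim(xs) <- c(d[1] * d[2] * d[3], cin)
    acc <- acc + xs %*% W[[k]]
  }
  acc <- sweep(acc, 2, b, "+")
  dim(acc) <- c(d[1], d[2], d[3], cout)
  list(y = acc, x_shifts = cache_shifts, dims = d)
}

conv3_bwd <- function(cache, W, dy) {
  d <- cache$dims; cin <- d[4]
  dym <- dy; dim(dym) <- c(d[1] * d[2] * d[3], ncol(W[[1]]))
  dW <- vector("list", 9L)
  dx <- array(0, d)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    xs <- cache$x_shifts[[k]]
    dim(xs) <- c(d[1] * d[2] * d[3], cin)
    dW[[k]] <- crossprod(xs, dym)
    dxs <- dym %*% t(W[[k]])
    dim(dxs) <- c(d[1], d[2], d[3], cin)
    # adjoint of shift(+di, +dj) is shift(-di, -dj)
    dx <- dx + shift2(dxs, -di, -dj)
  }
  db <- colSums(dym)
  list(dx = dx, dW = dW, db = db)
}

bn_fwd <- function(x, gamma, beta, running, train, momentum = 0.9,
                   eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(m, d[4])
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    var <- colMeans(xc^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * var
  } else {
    mu <- running$mean; var <- running$var
    xc <- sweep(xm, 2, mu)
  }
  inv <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, dims = d, running = running)
}

bn_bwd <- function(cache, gamma, dy) {
  d <- cache$dims; m <- d[1] * d[2] * d[3]
  dym <- dy; dim(dym) <- c(m, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  # dx = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, "*")
  dx <- sweep(t1 - t2, 2, cache$inv, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dy) dy * cache$mask

pool2_fwd <- function(x) {
  d <- dim(x); h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , , drop = FALSE]
  b <- x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , , drop = FALSE]
  cc <- x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE]
  dd <- x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE]
  m1 <- pmax(a, b); w1 <- ifelse(a >= b, 1L, 2L)
  m2 <- pmax(cc, dd); w2i <- ifelse(cc >= dd, 3L, 4L)
  y <- pmax(m1, m2)
  winner <- ifelse(m1 >= m2, w1, w2i)   # first maximum wins
  list(y = y, winner = winner, dims = d)
}

pool2_bwd <- function(cache, dy) {
  d <- cache$dims
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  dx <- array(0, d)
  odd_i <- seq(1, 2 * h2, 2); odd_j <- seq(1, 2 * w2, 2)
  for (q in 1:4) {
    sel <- (cache$winner == q) * dy
    ii <- if (q %in% c(1, 3)) odd_i else odd_i + 1L
    jj <- if (q %in% c(1, 2)) odd_j else odd_j + 1L
    dx[ii, jj, , ] <- dx[ii, jj, , , drop = FALSE] + sel
  }
  dx
}

cnn_init <- function(input_px, filters, n_class = 2L) {
  mk_conv <- function(cin, cout) {
    sd <- sqrt(2 / (9 * cin))
    list(W = lapply(1:9, function(k) matrix(stats::rnorm(cin * cout, 0, sd),
                                            cin, cout)),
         b = rep(0, cout),
         gamma = rep(1, cout), beta = rep(0, cout),
         running = list(mean = rep(0, cout), var = rep(1, cout)))
  }
  f <- filters
  p_side <- input_px %/% 4L           # after two 2x2 pools
  n_flat <- p_side * p_side * f[3]
  list(conv1 = mk_conv(1L, f[1]),
       conv2 = mk_conv(f[1], f[2]),
       conv3 = mk_conv(f[2], f[3]),
       fc = list(W = matrix(stats::rnorm(n_flat * n_class, 0,
                                         sqrt(2 / n_flat)), n_flat, n_class),
                 b = rep(0, n_class)),
       input_px = input_px, filters = f, n_class = n_class)
}

cnn_forward <- function(net, x, train = FALSE) {
  # x: array (h, w, n) in [0, 1]
  d <- dim(x)
  a <- array(x, c(d[1], d[2], d[3], 1L))
  caches <- list()
  for (li in 1:3) {
    p <- net[[paste0("conv", li)]]
    cv <- conv3_fwd(a, p$W, p$b)
    bn <- bn_fwd(cv$y, p$gamma, p$beta, p$running, train)
    if (train) net[[paste0("conv", li)]]$running <- bn$running
    rl <- relu_fwd(bn$y)
    if (li < 3) {
      pl <- pool2_fwd(rl$y)
      a <- pl$y
    } else pl <- NULL
    caches[[li]] <- list(cv = cv, bn = bn, rl = rl, pl = pl)
    if (li == 3) a <- rl$y
  }
  dd <- dim(a)
  flat <- aperm(a, c(3, 1, 2, 4))
  dim(flat) <- c(dd[3], dd[1] * dd[2] * dd[4])
  logits <- sweep(flat %*% net$fc$W, 2, net$fc$b, "+")
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, flat = flat, flat_dims = dd,
       caches = caches, net = net)
}

cnn_loss_grad <- function(net, x, y_onehot) {
  fw <- cnn_forward(net, x, train = TRUE)
  n <- nrow(fw$probs)
  loss <- -mean(rowSums(y_onehot * log(pmax(fw$probs, 1e-12))))
  dlogits <- (fw$probs - y_onehot) / n
  grads <- list()
  grads$fc <- list(W = crossprod(fw$flat, dlogits), b = colSums(dlogits))
  dflat <- dlogits %*% t(net$fc$W)
  dd <- fw$flat_dims
  dim(dflat) <- c(dd[3], dd[1], dd[2], dd[4])
  da <- aperm(dflat, c(2, 3, 1, 4))
  for (li in 3:1) {
    cache <- fw$caches[[li]]
    p <- net[[paste0("conv", li)]]
    if (li < 3) da <- pool2_bwd(cache$pl, da)
    da <- relu_bwd(cache$rl, da)
    bnb <- bn_bwd(cache$bn, p$gamma, da)
    cvb <- conv3_bwd(cache$cv, p$W, bnb$dx)
    grads[[paste0("conv", li)]] <- list(dW = cvb$dW, db = cvb$db,
                                        dgamma = bnb$dgamma,
                                        dbeta = bnb$dbeta)
    da <- cvb$dx
  }
  list(loss = loss, grads = grads, net = fw$net, probs = fw$probs)
}

cnn_sgd_step <- function(net, grads, lr) {
  for (li in 1:3) {
    nm <- paste0("conv", li)
    for (k in 1:9) net[[nm]]$W[[k]] <- net[[nm]]$W[[k]] - lr * grads[[nm]]$dW[[k]]
    net[[nm]]$b <- net[[nm]]$b - lr * grads[[nm]]$db
    net[[nm]]$gamma <- net[[nm]]$gamma - lr * grads[[nm]]$dgamma
    net[[nm]]$beta <- net[[nm]]$beta - lr * grads[[nm]]$dbeta
  }
  net$fc$W <- net$fc$W - lr * grads$fc$W
  net$fc$b <- net$fc$b - lr * grads$fc$b
  net
}

cnn_predict_probs <- function(net, x, chunk = 512L) {
  n <- dim(x)[3]
  out <- matrix(NA_real_, n, net$n_class)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out[i0:i1, ] <- cnn_forward(net, x[, , i0:i1, drop = FALSE],
                                train = FALSE)$probs
  }
  out
}
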