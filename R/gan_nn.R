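# Minimal fully connected neural-network engine for the conditional GAN:
# dense / batch-normalization / activation / dropout layers with reverse-mode
# gradients and an Adam optimizer. Matrices are row-major batches (n x d).
# This is deliberately self-contained: the adversarial training loop needs
# full control over freezing, weight snapshots and bit-reproducible RNG.

.glorotInit <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

.denseLayer <- function(fanIn, fanOut) {
  list(type = "dense", W = .glorotInit(fanIn, fanOut),
       b = matrix(0, 1, fanOut))
}

.batchnormLayer <- function(d, momentum = 0.99, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, d), beta = rep(0, d),
       runMean = rep(0, d), runVar = rep(1, d),
       momentum = momentum, eps = eps)
}

.actLayer <- function(kind) list(type = "act", kind = kind)  # relu / lrelu
.dropoutLayer <- function(rate) list(type = "dropout", rate = rate)

# Forward pass; returns list(out, caches). `training` switches dropout on and
# batchnorm to batch statistics (updating the running averages in place via
# the returned network).
.nnForward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% ly$W + matrix(ly$b, nrow(X), ncol(ly$W), byrow = TRUE)
    } else if (ly$type == "batchnorm") {
      if (training) {
        mu <- colMeans(X)
        va <- colMeans(X^2) - mu^2
        net$layers[[i]]$runMean <- ly$momentum * ly$runMean + (1 - ly$momentum) * mu
        net$layers[[i]]$runVar <- ly$momentum * ly$runVar + (1 - ly$momentum) * va
      } else {
        mu <- ly$runMean
        va <- ly$runVar
      }
      inv <- 1 / sqrt(va + ly$eps)
      xhat <- sweep(sweep(X, 2, mu, "-"), 2, inv, "*")
      caches[[i]] <- list(xhat = xhat, inv = inv)
      X <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else if (ly$type == "act") {
      caches[[i]] <- list(X = X)
      X <- if (ly$kind == "relu") pmax(X, 0) else
        ifelse(X > 0, X, 0.2 * X)
    } else if (ly$type == "dropout") {
      if (training) {
        mask <- matrix(stats::runif(length(X)) >= ly$rate, nrow(X)) /
          (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else caches[[i]] <- list(mask = NULL)
    }
  }
  list(out = X, caches = caches, net = net)
}

# Backward pass from dOut; returns list(grads, dX). grads[[i]] holds dW/db or
# dgamma/dbeta for parameterized layers, NULL otherwise.
.nnBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dX <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$X, dX), b = colSums(dX))
      dX <- tcrossprod(dX, ly$W)
    } else if (ly$type == "batchnorm") {
      xhat <- ca$xhat
      dgamma <- colSums(dX * xhat)
      dbeta <- colSums(dX)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      n <- nrow(dX)
      dxhat <- sweep(dX, 2, ly$gamma, "*")
      dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dX), byrow = TRUE) -
                    sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
                  2, ca$inv, "*")
    } else if (ly$type == "act") {
      dX <- if (ly$kind == "relu") dX * (ca$X > 0) else
        dX * ifelse(ca$X > 0, 1, 0.2)
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) dX <- dX * ca$mask
    }
  }
  list(grads = grads, dX = dX)
}

.adamInit <- function(net) {
  lapply(net$layers, function(ly) {
    if (ly$type == "dense")
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else if (ly$type == "batchnorm")
      list(mg = ly$gamma * 0, vg = ly$gamma * 0,
           mb = ly$beta * 0, vb = ly$beta * 0)
    else NULL
  })
}

.adamStep <- function(net, state, grads, lr, beta1, beta2, t, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v, step = lr * (m / corr1) / (sqrt(v / corr2) + eps))
  }
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    st <- state[[i]]
    if (ly$type == "dense") {
      u <- upd(st$mW, st$vW, g$W)
      net$layers[[i]]$W <- ly$W - u$step
      state[[i]]$mW <- u$m; state[[i]]$vW <- u$v
      u <- upd(st$mb, st$vb, matrix(g$b, 1))
      net$layers[[i]]$b <- ly$b - u$step
      state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    } else if (ly$type == "batchnorm") {
      u <- upd(st$mg, st$vg, g$gamma)
      net$layers[[i]]$gamma <- ly$gamma - u$step
      state[[i]]$mg <- u$m; state[[i]]$vg <- u$v
      u <- upd(st$mb, st$vb, g$beta)
      net$layers[[i]]$beta <- ly$beta - u$step
      state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    }
  }
  list(net = net, state = state)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy on logits; returns loss and dLogit (mean-reduced).
.bceLogits <- function(logits, targets) {
  p <- .sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(targets * log(p + eps) + (1 - targets) * log(1 - p + eps))
  list(loss = loss, dLogit = (p - targets) / length(targets))
}

.oneHot <- function(labels, nClasses) {
  out <- matrix(0, length(labels), nClasses)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}
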