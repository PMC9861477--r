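# Compact feed-forward network engine: sequential layers (2D valid
# convolution via im2col, ReLU, 2x2 max pool, flatten, dense), softmax
# cross-entropy loss, Adam updates.  All randomness (init, shuffling) goes
# through R's RNG so a single set.seed() makes training bit-reproducible.

he_init <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

nn_layer_conv <- function(filters, kernel, in_channels) {
  list(type = "conv", kh = kernel, kw = kernel, cin = in_channels,
       W = he_init(filters, kernel * kernel * in_channels),
       b = numeric(filters))
}
nn_layer_dense <- function(nout, nin, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, nout, nin) else he_init(nout, nin)
  list(type = "dense", W = W, b = numeric(nout))
}

# input [H,W,C,N] -> conv output [oh,ow,F,N]
conv_forward <- function(layer, x) {
  d <- dim(x)
  oh <- d[1] - layer$kh + 1; ow <- d[2] - layer$kw + 1
  cols <- nn_im2col(x, layer$kh, layer$kw)
  z <- layer$W %*% cols + layer$b          # F x (oh*ow*N)
  out <- aperm(array(z, c(nrow(layer$W), oh, ow, d[4])), c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, dims = d, oh = oh, ow = ow))
}
conv_backward <- function(layer, cache, gout) {
  f <- nrow(layer$W)
  gz <- array(aperm(gout, c(3, 1, 2, 4)), c(f, cache$oh * cache$ow * cache$dims[4]))
  gW <- gz %*% t(cache$cols)
  gb <- rowSums(gz)
  gcols <- t(layer$W) %*% gz
  gx <- nn_col2im(gcols, cache$dims[1], cache$dims[2], cache$dims[3],
                  cache$dims[4], layer$kh, layer$kw)
  list(gx = gx, gW = gW, gb = gb)
}

net_forward <- function(net, x, train = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(ly, x); x <- cf$out; caches[[i]] <- cf$cache
    } else if (ly$type == "relu") {
      caches[[i]] <- x > 0; x <- x * (x > 0)
    } else if (ly$type == "pool") {
      mp <- nn_maxpool2(x)
      caches[[i]] <- list(idx = mp$idx, dims = dim(x))
      x <- mp$out
    } else if (ly$type == "flatten") {
      caches[[i]] <- dim(x)
      x <- matrix(x, prod(dim(x)[1:3]), dim(x)[4])
    } else if (ly$type == "dense") {
      caches[[i]] <- x
      x <- ly$W %*% x + ly$b
    }
  }
  list(logits = x, caches = caches)
}

net_backward <- function(net, caches, gout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      bw <- conv_backward(ly, caches[[i]], gout)
      grads[[i]] <- list(gW = bw$gW, gb = bw$gb); gout <- bw$gx
    } else if (ly$type == "relu") {
      gout <- gout * caches[[i]]
    } else if (ly$type == "pool") {
      gout <- nn_maxpool2_bwd(gout, caches[[i]]$idx, caches[[i]]$dims)
    } else if (ly$type == "flatten") {
      gout <- array(gout, caches[[i]])
    } else if (ly$type == "dense") {
      grads[[i]] <- list(gW = gout %*% t(caches[[i]]), gb = rowSums(gout))
      gout <- t(ly$W) %*% gout
    }
  }
  grads
}

softmax_probs <- function(logits) {
  z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(e), ncol(e), byrow = TRUE)
}

# y: integer class index (1-based), length N
softmax_xent <- function(logits, y) {
  p <- softmax_probs(logits)
  n <- ncol(p)
  picked <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  g <- p
  g[cbind(y, seq_len(n))] <- g[cbind(y, seq_len(n))] - 1
  list(loss = loss, grad = g / n, probs = p)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly)
    if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                             mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(net, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * grads[[i]]$gW
    s$vW <- b2 * s$vW + (1 - b2) * grads[[i]]$gW^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[i]]$gb
    s$vb <- b2 * s$vb + (1 - b2) * grads[[i]]$gb^2
    mhatW <- s$mW / (1 - b1^t); vhatW <- s$vW / (1 - b2^t)
    mhatb <- s$mb / (1 - b1^t); vhatb <- s$vb / (1 - b2^t)
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# x: [H,W,C,N] array or (features x N) matrix; y: 1-based integer classes
nn_train <- function(net, x, y, epochs, lr, batch_size) {
  n <- if (is.matrix(x)) ncol(x) else dim(x)[4]
  state <- adam_init(net)
  t <- 0
  curves <- data.frame(epoch = integer(0), loss = numeric(0),
                       accuracy = numeric(0))
  take <- function(idx) {
    if (is.matrix(x)) x[, idx, drop = FALSE]
    else x[, , , idx, drop = FALSE]
  }
  for (ep in seq_len(max(epochs, 0))) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      fw <- net_forward(net, take(idx))
      sx <- softmax_xent(fw$logits, y[idx])
      grads <- net_backward(net, fw$caches, sx$grad)
      t <- t + 1
      up <- adam_step(net, grads, state, lr, t)
      net <- up$net; state <- up$state
      tot_loss <- tot_loss + sx$loss * length(idx)
      tot_correct <- tot_correct +
        sum(apply(sx$probs, 2, which.max) == y[idx])
    }
    curves <- rbind(curves, data.frame(epoch = ep, loss = tot_loss / n,
                                       accuracy = tot_correct / n))
  }
  list(net = net, curves = curves)
}

nn_predict_probs <- function(net, x) {
  n <- if (is.matrix(x)) ncol(x) else dim(x)[4]
  out <- matrix(0, n, 2)
  bs <- 256
  for (s in seq(1, n, by = bs)) {
    idx <- s:min(s + bs - 1, n)
    xb <- if (is.matrix(x)) x[, idx, drop = FALSE] else x[, , , idx, drop = FALSE]
    out[idx, ] <- t(softmax_probs(net_forward(net, xb, train = FALSE)$logits))
  }
  out
}
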