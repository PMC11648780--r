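# Compact neural-network training engine.
#
# Data conventions:
#   * convolutional domain: arrays (H, W, C, B)
#   * dense domain:         matrices (features, B)
# Layers are plain lists; a network is list(layers = ..., input_side).
# Forward returns per-layer caches consumed by the backward pass; Adam
# states live alongside the parameters. Everything is deterministic given
# the R RNG state (dropout masks and batch shuffling draw from it).

nn_conv <- function(in_c, out_c, k = 3L, stride = 2L, pad = 1L) {
  list(type = "conv", part = "encoder", in_c = in_c, out_c = out_c,
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       W = NULL, b = NULL)
}
nn_relu <- function(part = "encoder") list(type = "relu", part = part)
nn_flatten <- function() list(type = "flatten", part = "encoder")
nn_linear <- function(n_in, n_out, part = "head", name = NULL)
  list(type = "linear", part = part, n_in = n_in, n_out = n_out,
       name = name, W = NULL, b = NULL)
nn_batchnorm <- function(n, part = "head")
  list(type = "batchnorm", part = part, n = n, gamma = NULL, beta = NULL,
       running_mean = rep(0, n), running_var = rep(1, n),
       momentum = 0.1, eps = 1e-5)
nn_dropout <- function(p, part = "head") list(type = "dropout", part = part,
                                              p = p)

# He-style initialization, drawing from the current RNG stream.
nn_init <- function(net) {
  net$layers <- lapply(net$layers, function(l) {
    if (l$type == "conv") {
      fan_in <- l$k * l$k * l$in_c
      l$W <- matrix(rnorm(l$out_c * fan_in, 0, sqrt(2 / fan_in)),
                    l$out_c, fan_in)
      l$b <- rep(0, l$out_c)
    } else if (l$type == "linear") {
      l$W <- matrix(rnorm(l$n_out * l$n_in, 0, sqrt(2 / l$n_in)),
                    l$n_out, l$n_in)
      l$b <- rep(0, l$n_out)
    } else if (l$type == "batchnorm") {
      l$gamma <- rep(1, l$n); l$beta <- rep(0, l$n)
    }
    l
  })
  net
}

.pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# Forward pass. Returns list(out = logits (K x B), embedding (E x B),
# caches) — caches only when backward = TRUE.
nn_forward <- function(net, x, training = FALSE, backward = FALSE) {
  nl <- length(net$layers)
  caches <- if (backward) vector("list", nl) else NULL
  bn_stats <- vector("list", nl)
  embedding <- NULL
  cur <- x
  for (li in seq_len(nl)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      d <- dim(cur)
      xp <- .pad_batch(cur, l$pad)
      dp <- dim(xp)
      xcol <- im2col_cpp(xp, dp[1], dp[2], dp[3], dp[4], l$k, l$stride)
      y <- l$W %*% xcol + l$b
      ho <- (dp[1] - l$k) %/% l$stride + 1L
      wo <- (dp[2] - l$k) %/% l$stride + 1L
      if (backward)
        caches[[li]] <- list(xcol = xcol, dp = dp, ho = ho, wo = wo)
      cur <- array(aperm(array(y, c(l$out_c, ho * wo, d[4])), c(2, 1, 3)),
                   c(ho, wo, l$out_c, d[4]))
    } else if (l$type == "relu") {
      mask <- cur > 0
      cur <- cur * mask
      if (backward) caches[[li]] <- mask
    } else if (l$type == "flatten") {
      d <- dim(cur)
      if (backward) caches[[li]] <- d
      dim(cur) <- c(prod(d[1:3]), d[4])
    } else if (l$type == "linear") {
      if (backward) caches[[li]] <- cur
      cur <- l$W %*% cur + l$b
      if (!is.null(l$name) && l$name == "embedding") embedding <- cur
    } else if (l$type == "batchnorm") {
      if (training) {
        mu <- rowMeans(cur)
        v <- rowMeans((cur - mu)^2)
        istd <- 1 / sqrt(v + l$eps)
        xhat <- (cur - mu) * istd
        bn_stats[[li]] <- list(mu = mu, v = v, n = ncol(cur))
        net$layers[[li]]$running_mean <-
          (1 - l$momentum) * l$running_mean + l$momentum * mu
        net$layers[[li]]$running_var <-
          (1 - l$momentum) * l$running_var + l$momentum * v
      } else {
        istd <- 1 / sqrt(l$running_var + l$eps)
        xhat <- (cur - l$running_mean) * istd
      }
      if (backward) caches[[li]] <- list(xhat = xhat, istd = istd)
      cur <- l$gamma * xhat + l$beta
    } else if (l$type == "dropout") {
      if (training && l$p > 0) {
        mask <- (matrix(runif(length(cur)), nrow(cur)) >= l$p) / (1 - l$p)
        cur <- cur * mask
        if (backward) caches[[li]] <- mask
      } else if (backward) caches[[li]] <- NULL
    }
  }
  list(out = cur, embedding = embedding, caches = caches, net = net,
       bn_stats = bn_stats)
}

# Recalibrate batch-norm running statistics with exact moments over a data
# pool ("precise BN"): forward in training mode (batch statistics used for
# normalization downstream) and aggregate per-layer batch moments, combining
# within-batch variance with the between-batch variance of the means.
nn_recalibrate_bn <- function(net, x, batch_size = 64L) {
  n <- dim(x)[4]
  acc <- list()
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    if (length(idx) < 2L) next
    fwd <- nn_forward(net, x[, , , idx, drop = FALSE], training = TRUE)
    for (li in seq_along(fwd$bn_stats)) {
      s <- fwd$bn_stats[[li]]
      if (is.null(s)) next
      key <- as.character(li)
      a <- acc[[key]]
      if (is.null(a)) a <- list(sum_mu = 0, sum_m2 = 0, sum_v = 0, n = 0)
      a$sum_mu <- a$sum_mu + s$mu * s$n
      a$sum_m2 <- a$sum_m2 + s$mu^2 * s$n
      a$sum_v <- a$sum_v + s$v * s$n
      a$n <- a$n + s$n
      acc[[key]] <- a
    }
  }
  for (key in names(acc)) {
    a <- acc[[key]]
    li <- as.integer(key)
    mu_bar <- a$sum_mu / a$n
    net$layers[[li]]$running_mean <- mu_bar
    net$layers[[li]]$running_var <-
      a$sum_v / a$n + a$sum_m2 / a$n - mu_bar^2
  }
  net
}

# Backward pass from dlogits (K x B); returns grads list parallel to layers.
nn_backward <- function(net, fwd, dout) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  cur <- dout
  for (li in rev(seq_len(nl))) {
    l <- net$layers[[li]]
    cache <- fwd$caches[[li]]
    if (l$type == "conv") {
      d4 <- dim(cur)  # (Ho, Wo, F, B)
      dy <- array(aperm(cur, c(3, 1, 2, 4)), c(l$out_c, d4[1] * d4[2] * d4[4]))
      grads[[li]] <- list(W = dy %*% t(cache$xcol), b = rowSums(dy))
      dxcol <- crossprod(l$W, dy)
      dxp <- col2im_cpp(dxcol, cache$dp[1], cache$dp[2], cache$dp[3],
                        cache$dp[4], l$k, l$stride)
      cur <- if (l$pad > 0)
        dxp[l$pad + seq_len(cache$dp[1] - 2L * l$pad),
            l$pad + seq_len(cache$dp[2] - 2L * l$pad), , , drop = FALSE]
      else dxp
    } else if (l$type == "relu") {
      cur <- cur * cache
    } else if (l$type == "flatten") {
      dim(cur) <- cache
    } else if (l$type == "linear") {
      grads[[li]] <- list(W = cur %*% t(cache), b = rowSums(cur))
      cur <- crossprod(l$W, cur)
    } else if (l$type == "batchnorm") {
      xhat <- cache$xhat; istd <- cache$istd
      grads[[li]] <- list(gamma = rowSums(cur * xhat), beta = rowSums(cur))
      dxhat <- cur * l$gamma
      cur <- istd * (dxhat - rowMeans(dxhat) -
                       xhat * rowMeans(dxhat * xhat))
    } else if (l$type == "dropout") {
      if (!is.null(cache)) cur <- cur * cache
    }
  }
  grads
}

# Label-smoothing cross-entropy on logits (K x B). y: integer in 1..K.
# loss = mean_b[(1 - eps) * NLL(true) + eps * mean_k NLL(k)];
# dlogits = (softmax - w) / B with w = (1 - eps) * onehot + eps / K.
smoothed_ce <- function(logits, y, eps, with_grad = TRUE) {
  k <- nrow(logits); b <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- sweep(logits, 2, m)
  lse <- log(colSums(exp(z)))
  logp <- sweep(z, 2, lse)
  nll_true <- -logp[cbind(y, seq_len(b))]
  nll_mean <- -colMeans(logp)
  loss <- mean((1 - eps) * nll_true + eps * nll_mean)
  if (!with_grad) return(list(loss = loss))
  w <- matrix(eps / k, k, b)
  w[cbind(y, seq_len(b))] <- w[cbind(y, seq_len(b))] + (1 - eps)
  dlogits <- (exp(logp) - w) / b
  list(loss = loss, dlogits = dlogits)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    ps <- intersect(names(l), c("W", "b", "gamma", "beta"))
    ps <- ps[!vapply(l[ps], is.null, logical(1))]
    if (!length(ps)) return(NULL)
    stats::setNames(lapply(ps, function(p)
      list(m = l[[p]] * 0, v = l[[p]] * 0)), ps)
  })
}

adam_step <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, freeze_encoder = FALSE) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g) || is.null(state[[li]])) next
    if (freeze_encoder && net$layers[[li]]$part == "encoder") next
    for (p in names(state[[li]])) {
      gp <- g[[if (p %in% c("gamma", "beta")) p else p]]
      if (is.null(gp)) next
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gp
      st$v <- beta2 * st$v + (1 - beta2) * gp^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[li]][[p]] <- net$layers[[li]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# Training loop. x: (H, W, 3, N); y: integer labels 1..K.
# Batches of size < 2 are dropped (batch statistics are undefined).
nn_train <- function(net, x, y, epochs, batch_size, lr, eps_smooth, seed,
                     freeze_encoder = FALSE) {
  n <- dim(x)[4]
  state <- adam_init(net)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      losses <- c(); correct <- 0L; seen <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]
        fwd <- nn_forward(net, xb, training = TRUE, backward = TRUE)
        net <- fwd$net  # batch-norm running stats
        ls <- smoothed_ce(fwd$out, yb, eps_smooth)
        grads <- nn_backward(net, fwd, ls$dlogits)
        t <- t + 1L
        upd <- adam_step(net, grads, state, t, lr,
                         freeze_encoder = freeze_encoder)
        net <- upd$net; state <- upd$state
        losses <- c(losses, ls$loss)
        correct <- correct + sum(max.col(t(fwd$out)) == yb)
        seen <- seen + length(idx)
      }
      history <- rbind(history,
                       data.frame(epoch = ep,
                                  loss = if (length(losses)) mean(losses)
                                         else NA_real_,
                                  accuracy = correct / max(seen, 1L)))
    }
    # exact batch-norm statistics over the full pool for inference
    net <- nn_recalibrate_bn(net, x)
  })
  list(net = net, history = history, n_steps = t)
}

# Batched deterministic inference. Returns embeddings (N x E) and
# logits (N x K).
nn_predict <- function(net, x, batch_size = 64L) {
  n <- dim(x)[4]
  emb <- NULL; logits <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- nn_forward(net, x[, , , idx, drop = FALSE], training = FALSE)
    emb <- rbind(emb, t(fwd$embedding))
    logits <- rbind(logits, t(fwd$out))
  }
  list(embeddings = emb, logits = logits)
}
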