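# Neural-network primitives with explicit forward/backward passes.
#
# All feature tensors are 4-d arrays (H, W, C, N).  Every layer exposes
# a *_fw function returning list(y, cache, [pm]) and a *_bw function
# taking (cache, dy) and returning list(dx, grads) where `grads` mirrors
# the trainable entries of the layer's parameter list.  Convolution and
# max pooling run in compiled code; everything else is vectorized R.

.he_conv <- function(k, cin, cout) {
  list(W = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

.bn_params <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c))
}

conv_fw <- function(x, pm) {
  y <- .conv2d_fw(x, pm$W, pm$b)
  list(y = y, cache = list(x = x, W = pm$W))
}

conv_bw <- function(cache, dy) {
  r <- .conv2d_bw(cache$x, cache$W, dy)
  list(dx = r$dx, grads = list(W = r$dw, b = r$db))
}

relu_fw <- function(x) {
  y <- .relu_fw(x)
  list(y = y, cache = y)
}

relu_bw <- function(cache, dy) {
  .relu_bw(cache, dy)
}

# Batch normalization over (H, W, N) per channel.  Training mode uses
# batch statistics and updates the running moments in `pm`.
bn_fw <- function(x, pm, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    st <- .bn_stats(x)
    mu <- st$mean
    v <- st$var
    pm$rm <- momentum * pm$rm + (1 - momentum) * mu
    pm$rv <- momentum * pm$rv + (1 - momentum) * v
  } else {
    mu <- pm$rm
    v <- pm$rv
  }
  istd <- 1 / sqrt(v + eps)
  a <- pm$gamma * istd
  y <- .bn_apply(x, a, pm$beta - a * mu)
  list(y = y, pm = pm,
       cache = list(x = x, mu = mu, istd = istd, gamma = pm$gamma,
                    training = training))
}

bn_bw <- function(cache, dy) {
  r <- .bn_bw(cache$x, dy, cache$gamma, cache$mu, cache$istd,
              cache$training)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

maxpool_fw <- function(x) {
  r <- .maxpool2_fw(x)
  list(y = r$y, cache = list(idx = r$idx, dim = dim(x)))
}

maxpool_bw <- function(cache, dy) {
  .maxpool2_bw(cache$idx, dy, cache$dim)
}

up2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up2_bw <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(1, d[2], by = 2)
  dy[o1, , , , drop = FALSE][, o2, , , drop = FALSE] +
    dy[o1 + 1, , , , drop = FALSE][, o2, , , drop = FALSE] +
    dy[o1, , , , drop = FALSE][, o2 + 1, , , drop = FALSE] +
    dy[o1 + 1, , , , drop = FALSE][, o2 + 1, , , drop = FALSE]
}

avg2_fw <- function(x) up2_bw(x) * 0.25

avg2_bw <- function(dy) up2_fw(dy) * 0.25

concat_fw <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  list(y = out, cache = c(da[3], db[3]))
}

concat_bw <- function(cache, dy) {
  list(da = dy[, , seq_len(cache[1]), , drop = FALSE],
       db = dy[, , cache[1] + seq_len(cache[2]), , drop = FALSE])
}

softmax2_fw <- function(z) {
  z1 <- z[, , 1, , drop = FALSE]; z2 <- z[, , 2, , drop = FALSE]
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  s <- e1 + e2
  p <- z
  p[, , 1, ] <- e1 / s
  p[, , 2, ] <- e2 / s
  p
}

# dL/dz from dL/dp for a channel-wise softmax
softmax2_bw <- function(p, dp) {
  s <- p[, , 1, , drop = FALSE] * dp[, , 1, , drop = FALSE] +
    p[, , 2, , drop = FALSE] * dp[, , 2, , drop = FALSE]
  dz <- p
  dz[, , 1, ] <- p[, , 1, , drop = FALSE] * (dp[, , 1, , drop = FALSE] - s)
  dz[, , 2, ] <- p[, , 2, , drop = FALSE] * (dp[, , 2, , drop = FALSE] - s)
  dz
}

## ---- composite units -------------------------------------------------

# Two successive same-padded 3x3 convolutions, each followed by
# (optional) batch normalization and ReLU.
fcu_init <- function(cin, cout, use_bn) {
  pm <- list(conv1 = .he_conv(3, cin, cout), conv2 = .he_conv(3, cout, cout))
  if (use_bn) {
    pm$bn1 <- .bn_params(cout)
    pm$bn2 <- .bn_params(cout)
  }
  pm
}

fcu_fw <- function(x, pm, training, use_bn) {
  caches <- list()
  c1 <- conv_fw(x, pm$conv1); caches$conv1 <- c1$cache; h <- c1$y
  if (use_bn) {
    b1 <- bn_fw(h, pm$bn1, training); pm$bn1 <- b1$pm
    caches$bn1 <- b1$cache; h <- b1$y
  }
  r1 <- relu_fw(h); caches$relu1 <- r1$cache; h <- r1$y
  c2 <- conv_fw(h, pm$conv2); caches$conv2 <- c2$cache; h <- c2$y
  if (use_bn) {
    b2 <- bn_fw(h, pm$bn2, training); pm$bn2 <- b2$pm
    caches$bn2 <- b2$cache; h <- b2$y
  }
  r2 <- relu_fw(h); caches$relu2 <- r2$cache
  list(y = r2$y, cache = caches, pm = pm)
}

fcu_bw <- function(cache, dy, use_bn) {
  grads <- list()
  d <- relu_bw(cache$relu2, dy)
  if (use_bn) {
    b <- bn_bw(cache$bn2, d); grads$bn2 <- b$grads; d <- b$dx
  }
  cv <- conv_bw(cache$conv2, d); grads$conv2 <- cv$grads; d <- cv$dx
  d <- relu_bw(cache$relu1, d)
  if (use_bn) {
    b <- bn_bw(cache$bn1, d); grads$bn1 <- b$grads; d <- b$dx
  }
  cv <- conv_bw(cache$conv1, d); grads$conv1 <- cv$grads
  list(dx = cv$dx, grads = grads)
}

# Residual unit: conv path conv-bn-relu-conv-bn plus a shortcut
# (identity when channels match, 1x1 projection otherwise), then ReLU.
res_init <- function(cin, cout, use_bn) {
  pm <- fcu_init(cin, cout, use_bn)
  if (cin != cout) {
    pm$proj <- .he_conv(1, cin, cout)
    if (use_bn) pm$projbn <- .bn_params(cout)
  }
  pm
}

res_fw <- function(x, pm, training, use_bn) {
  caches <- list()
  c1 <- conv_fw(x, pm$conv1); caches$conv1 <- c1$cache; h <- c1$y
  if (use_bn) {
    b1 <- bn_fw(h, pm$bn1, training); pm$bn1 <- b1$pm
    caches$bn1 <- b1$cache; h <- b1$y
  }
  r1 <- relu_fw(h); caches$relu1 <- r1$cache; h <- r1$y
  c2 <- conv_fw(h, pm$conv2); caches$conv2 <- c2$cache; h <- c2$y
  if (use_bn) {
    b2 <- bn_fw(h, pm$bn2, training); pm$bn2 <- b2$pm
    caches$bn2 <- b2$cache; h <- b2$y
  }
  if (is.null(pm$proj)) {
    short <- x
  } else {
    pc <- conv_fw(x, pm$proj); caches$proj <- pc$cache; short <- pc$y
    if (use_bn) {
      pb <- bn_fw(short, pm$projbn, training); pm$projbn <- pb$pm
      caches$projbn <- pb$cache; short <- pb$y
    }
  }
  r2 <- relu_fw(h + short); caches$relu2 <- r2$cache
  caches$has_proj <- !is.null(pm$proj)
  list(y = r2$y, cache = caches, pm = pm)
}

res_bw <- function(cache, dy, use_bn) {
  grads <- list()
  d <- relu_bw(cache$relu2, dy) # gradient at (main + short)
  # shortcut branch
  if (cache$has_proj) {
    ds <- d
    if (use_bn) {
      b <- bn_bw(cache$projbn, ds); grads$projbn <- b$grads; ds <- b$dx
    }
    pc <- conv_bw(cache$proj, ds); grads$proj <- pc$grads
    dx_short <- pc$dx
  } else {
    dx_short <- d
  }
  # main branch
  dm <- d
  if (use_bn) {
    b <- bn_bw(cache$bn2, dm); grads$bn2 <- b$grads; dm <- b$dx
  }
  cv <- conv_bw(cache$conv2, dm); grads$conv2 <- cv$grads; dm <- cv$dx
  dm <- relu_bw(cache$relu1, dm)
  if (use_bn) {
    b <- bn_bw(cache$bn1, dm); grads$bn1 <- b$grads; dm <- b$dx
  }
  cv <- conv_bw(cache$conv1, dm); grads$conv1 <- cv$grads
  list(dx = cv$dx + dx_short, grads = grads)
}

# Attention gate.  The skip (fine scale) is average-pooled to the gate's
# scale; both are mapped by 1x1 convolutions into an inner space, added,
# ReLU'd, reduced to one channel by psi and squashed to [0, 1]; the
# coefficient map is nearest-upsampled and multiplies the skip.
ag_init <- function(c_skip, c_gate) {
  fi <- max(1L, c_skip %/% 2L)
  list(wx = .he_conv(1, c_skip, fi),
       wg = .he_conv(1, c_gate, fi),
       psi = .he_conv(1, fi, 1L))
}

ag_fw <- function(skip, gate, pm) {
  if (!all(dim(gate)[1:2] * 2L == dim(skip)[1:2])) {
    stop("attention gate expects the gating signal at half the skip's ",
         "spatial size (skip ", paste(dim(skip)[1:2], collapse = "x"),
         ", gate ", paste(dim(gate)[1:2], collapse = "x"), ")")
  }
  caches <- list()
  xs <- avg2_fw(skip)
  cx <- conv_fw(xs, pm$wx); caches$wx <- cx$cache
  cg <- conv_fw(gate, pm$wg); caches$wg <- cg$cache
  a <- cx$y + cg$y
  r <- relu_fw(a); caches$relu <- r$cache
  cp <- conv_fw(r$y, pm$psi); caches$psi <- cp$cache
  alpha_s <- 1 / (1 + exp(-cp$y))
  alpha <- up2_fw(alpha_s)
  cs <- dim(skip)[3]
  alpha_b <- alpha[, , rep(1L, cs), , drop = FALSE]
  caches$alpha_s <- alpha_s
  caches$alpha_b <- alpha_b
  caches$skip <- skip
  list(y = skip * alpha_b, cache = caches, alpha = alpha)
}

ag_bw <- function(cache, dy) {
  grads <- list()
  dskip <- dy * cache$alpha_b
  dab <- dy * cache$skip
  # sum the broadcast gradient over channels
  d <- dim(dab)
  tmp <- aperm(dab, c(1, 2, 4, 3))
  dim(tmp) <- c(d[1] * d[2] * d[4], d[3])
  dalpha <- array(rowSums(tmp), c(d[1], d[2], d[4], 1))
  dalpha <- aperm(dalpha, c(1, 2, 4, 3))
  dalpha_s <- up2_bw(dalpha)
  ds <- dalpha_s * cache$alpha_s * (1 - cache$alpha_s)
  cp <- conv_bw(cache$psi, ds); grads$psi <- cp$grads
  dh <- relu_bw(cache$relu, cp$dx)
  cx <- conv_bw(cache$wx, dh); grads$wx <- cx$grads
  cg <- conv_bw(cache$wg, dh); grads$wg <- cg$grads
  dskip <- dskip + avg2_bw(cx$dx)
  list(dskip = dskip, dgate = cg$dx, grads = grads)
}

# Decoder upsampling block: nearest 2x upsample then 3x3 conv
# (+ optional BN) + ReLU.
upc_init <- function(cin, cout, use_bn) {
  pm <- list(conv = .he_conv(3, cin, cout))
  if (use_bn) pm$bn <- .bn_params(cout)
  pm
}

upc_fw <- function(x, pm, training, use_bn) {
  caches <- list(in_dim = dim(x))
  u <- up2_fw(x)
  cv <- conv_fw(u, pm$conv); caches$conv <- cv$cache; h <- cv$y
  if (use_bn) {
    b <- bn_fw(h, pm$bn, training); pm$bn <- b$pm
    caches$bn <- b$cache; h <- b$y
  }
  r <- relu_fw(h); caches$relu <- r$cache
  list(y = r$y, cache = caches, pm = pm)
}

upc_bw <- function(cache, dy, use_bn) {
  grads <- list()
  d <- relu_bw(cache$relu, dy)
  if (use_bn) {
    b <- bn_bw(cache$bn, d); grads$bn <- b$grads; d <- b$dx
  }
  cv <- conv_bw(cache$conv, d); grads$conv <- cv$grads
  list(dx = up2_bw(cv$dx), grads = grads)
}

## ---- parameter bookkeeping ------------------------------------------

.BN_STATE_NAMES <- c("rm", "rv")

# keys of a list: names where present, positional indices otherwise
# (encoder/decoder levels are positional lists)
.tree_keys <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  ifelse(nm == "", as.character(seq_along(x)), nm)
}

# flatten trainable parameters (skipping BN running moments) into a
# named list keyed by slash-joined paths
flatten_params <- function(pm, prefix = "") {
  out <- list()
  keys <- .tree_keys(pm)
  for (i in seq_along(pm)) {
    if (keys[i] %in% .BN_STATE_NAMES) next
    v <- pm[[i]]
    path <- if (prefix == "") keys[i] else paste0(prefix, "/", keys[i])
    if (is.list(v)) {
      out <- c(out, flatten_params(v, path))
    } else if (!is.null(v) && !is.logical(v)) {
      out[[path]] <- v
    }
  }
  out
}

# elementwise walk: params <- f(params, grads, path) over the grads
# tree; named entries match by name, unnamed ones by position
.walk_update <- function(pm, gr, f, prefix = "") {
  keys <- .tree_keys(gr)
  nms <- names(gr)
  for (i in seq_along(gr)) {
    key <- if (!is.null(nms) && nms[i] != "") nms[i] else i
    path <- if (prefix == "") keys[i] else paste0(prefix, "/", keys[i])
    if (is.list(gr[[i]])) {
      pm[[key]] <- .walk_update(pm[[key]], gr[[i]], f, path)
    } else if (!is.null(gr[[i]]) && !is.logical(gr[[i]])) {
      pm[[key]] <- f(pm[[key]], gr[[i]], path)
    }
  }
  pm
}

# sum two gradient trees of identical structure
.add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  nms <- names(b)
  for (i in seq_along(b)) {
    key <- if (!is.null(nms) && nms[i] != "") nms[i] else i
    a[[key]] <- if (is.list(b[[i]])) .add_grads(a[[key]], b[[i]])
    else a[[key]] + b[[i]]
  }
  a
}

## ---- Adam optimizer --------------------------------------------------

adam_init <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  .walk_update(params, grads, function(p, g, path) {
    m <- st$m[[path]]
    v <- st$v[[path]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    st$m[[path]] <- m
    st$v[[path]] <- v
    p - st$lr * (m / bc1) / (sqrt(v / bc2) + st$eps)
  })
}
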