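# Pluggable classifier backends. The contract: a backend config object with
# methods fit_backend(backend, images, labels) -> handle and
# predict_proba(handle, images) -> n x L probability matrix (rows sum to 1).

#' Train a classifier backend
#' @param backend a backend configuration object.
#' @param images list of images.
#' @param labels factor of class labels.
#' @return a trained handle usable with [predict_proba()].
#' @export
fit_backend <- function(backend, images, labels) UseMethod("fit_backend")

#' Predict class probabilities
#' @param handle a trained backend handle.
#' @param images list of images.
#' @return n x L matrix of class probabilities (columns named by level).
#' @export
predict_proba <- function(handle, images) UseMethod("predict_proba")

backend_config <- function(backend) UseMethod("backend_config")

#' @export
backend_config.default <- function(backend) unclass(backend)

# ---- image -> tensor helpers -------------------------------------------

# list of connectivity_image / plain arrays -> (size, size, 3, N) in [0, 1]
images_to_array <- function(images, size) {
  N <- length(images)
  out <- array(0, c(size, size, 3L, N))
  for (n in seq_len(N)) {
    px <- if (inherits(images[[n]], "connectivity_image"))
      images[[n]]$pixels else images[[n]]
    px <- px / if (max(px) > 1) 255 else 1
    h <- dim(px)[1L]; w <- dim(px)[2L]
    if (h == size && w == size) {
      out[, , , n] <- px
    } else {
      rmap <- floor((seq_len(h) - 0.5) * size / h) + 1L
      cmap <- floor((seq_len(w) - 0.5) * size / w) + 1L
      for (ch in 1:3) {
        tmp <- rowsum(px[, , ch], rmap) / as.vector(table(rmap))
        out[, , ch, n] <- t(rowsum(t(tmp), cmap) / as.vector(table(cmap)))
      }
    }
  }
  out
}

# ---- minimal conv-net engine -------------------------------------------
# Activations live as (H*W*N) x C matrices; 3x3 same-padding convolution is
# nine gathered matrix products (one per kernel offset), pooling is 2x2
# average via four gathered index vectors. Everything is plain BLAS.

nn_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, N) {
  key <- sprintf("c%d_%d_%d", H, W, N)
  hit <- nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep.int(seq_len(H), W * N)
  j <- rep.int(rep(seq_len(W), each = H), N)
  n <- rep(seq_len(N), each = H * W)
  base <- Hp * Wp * (n - 1L)
  off <- vector("list", 9L)
  o <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    o <- o + 1L
    off[[o]] <- (i + 1L + dy) + Hp * (j + dx) + base
  }
  out <- list(inner = (i + 1L) + Hp * j + base, off = off,
              np = Hp * Wp * N)
  nn_cache[[key]] <- out
  out
}

# layer$W is a (9*Cin) x Cout matrix: one im2col-style GEMM per layer
conv_forward <- function(X, layer, H, W, N) {
  ci <- conv_indices(H, W, N)
  cin <- ncol(X)
  Xp <- matrix(0, ci$np, cin)
  Xp[ci$inner, ] <- X
  S <- matrix(0, H * W * N, 9L * cin)
  for (o in 1:9)
    S[, (o - 1L) * cin + seq_len(cin)] <- Xp[ci$off[[o]], , drop = FALSE]
  out <- S %*% layer$W
  out <- sweep(out, 2L, layer$b, "+")
  list(out = out, S = S, ci = ci, cin = cin)
}

conv_backward <- function(dOut, cache, layer) {
  dW <- crossprod(cache$S, dOut)
  dS <- tcrossprod(dOut, layer$W)
  dXp <- matrix(0, cache$ci$np, cache$cin)
  for (o in 1:9) {
    idx <- cache$ci$off[[o]]
    cols <- (o - 1L) * cache$cin + seq_len(cache$cin)
    dXp[idx, ] <- dXp[idx, , drop = FALSE] + dS[, cols, drop = FALSE]
  }
  list(dW = dW, db = colSums(dOut), dX = dXp[cache$ci$inner, , drop = FALSE])
}

pool_indices <- function(H, W, N) {
  key <- sprintf("p%d_%d_%d", H, W, N)
  hit <- nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep.int(seq_len(Ho), Wo * N)
  jo <- rep.int(rep(seq_len(Wo), each = Ho), N)
  n <- rep(seq_len(N), each = Ho * Wo)
  base <- H * W * (n - 1L)
  idx <- vector("list", 4L)
  o <- 0L
  for (b in 0:1) for (a in 0:1) {
    o <- o + 1L
    idx[[o]] <- (2L * io - 1L + a) + H * (2L * jo - 2L + b) + base
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  nn_cache[[key]] <- out
  out
}

pool_forward <- function(X, H, W, N) {
  pi_ <- pool_indices(H, W, N)
  out <- (X[pi_$idx[[1L]], , drop = FALSE] + X[pi_$idx[[2L]], , drop = FALSE] +
          X[pi_$idx[[3L]], , drop = FALSE] + X[pi_$idx[[4L]], , drop = FALSE]) / 4
  list(out = out, pi = pi_)
}

pool_backward <- function(dOut, cache, H, W, N) {
  dX <- matrix(0, H * W * N, ncol(dOut))
  for (o in 1:4)
    dX[cache$pi$idx[[o]], ] <- dOut / 4
  dX
}

# (Ho*Wo*N) x C  ->  N x (Ho*Wo*C)
flatten_fwd <- function(X, HW, N) {
  matrix(aperm(array(X, c(HW, N, ncol(X))), c(2L, 1L, 3L)), N, HW * ncol(X))
}

flatten_bwd <- function(dF, HW, N, C) {
  matrix(aperm(array(dF, c(N, HW, C)), c(2L, 1L, 3L)), HW * N, C)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

cnn_init <- function(input_size, channels, n_classes, seed) {
  set.seed(seed)
  he <- function(n_in, n_out, fan = n_in)
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan)), n_in, n_out)
  sizes <- c(3L, channels)
  layers <- vector("list", length(channels))
  s <- input_size
  for (l in seq_along(channels)) {
    layers[[l]] <- list(W = he(9L * sizes[l], sizes[l + 1L]),
                        b = numeric(channels[l]))
    s <- s %/% 2L
  }
  d_fc <- s * s * channels[length(channels)]
  list(conv = layers, fc_W = he(d_fc, n_classes), fc_b = numeric(n_classes),
       spatial = s, d_fc = d_fc)
}

cnn_forward <- function(params, X4, train = FALSE) {
  dims <- dim(X4)
  H <- dims[1L]; N <- dims[4L]
  X <- matrix(aperm(X4, c(1L, 2L, 4L, 3L)), H * H * N, 3L)
  caches <- list()
  s <- H
  for (l in seq_along(params$conv)) {
    cf <- conv_forward(X, params$conv[[l]], s, s, N)
    relu_mask <- cf$out > 0
    A <- cf$out * relu_mask
    pf <- pool_forward(A, s, s, N)
    if (train)
      caches[[l]] <- list(conv = cf, mask = relu_mask, pool = pf,
                          s = s)
    X <- pf$out
    s <- s %/% 2L
  }
  Fm <- flatten_fwd(X, s * s, N)
  logits <- sweep(Fm %*% params$fc_W, 2L, params$fc_b, "+")
  list(logits = logits, probs = softmax_rows(logits), Fm = Fm,
       caches = caches, s = s, N = N)
}

cnn_backward <- function(params, fw, y_onehot) {
  N <- fw$N
  dlogits <- (fw$probs - y_onehot) / N
  grads <- list(fc_W = crossprod(fw$Fm, dlogits), fc_b = colSums(dlogits))
  dX <- flatten_bwd(dlogits %*% t(params$fc_W), fw$s * fw$s, N,
                    ncol(params$conv[[length(params$conv)]]$W))
  for (l in rev(seq_along(params$conv))) {
    ca <- fw$caches[[l]]
    s <- ca$s
    dA <- pool_backward(dX, ca$pool, s, s, N)
    dA <- dA * ca$mask
    cb <- conv_backward(dA, ca$conv, params$conv[[l]])
    grads[[paste0("conv", l)]] <- cb[c("dW", "db")]
    dX <- cb$dX
  }
  grads
}

adam_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(x, g, m, v, t, lr, b1, b2, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(x = x - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

#' From-scratch convolutional network backend
#'
#' A small 3-block CNN (3x3 same-padding convolutions with ReLU and 2x2
#' average pooling, then a softmax layer) implemented in base R and
#' trainable on one CPU in minutes. Images are block-averaged down to
#' `input_size` pixels before entering the network (connectivity images are
#' uniform cell blocks, so no information is lost at the native matrix
#' resolution). Trained with ADAM on the cross-entropy loss; fully
#' deterministic for a fixed seed.
#'
#' @param input_size network input edge length (default 35, the native
#'   connectivity-matrix resolution).
#' @param channels feature channels of the three blocks.
#' @param epochs training epochs (default 15).
#' @param batch_size mini-batch size (default 32).
#' Inputs are centered (pixel values shifted to `[-0.5, 0.5]`) so ReLU
#' channels are not systematically dead on all-positive images.
#'
#' @param lr ADAM learning rate.
#' @param beta1,beta2 ADAM moment decay factors.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return backend configuration of class `small_cnn`.
#' @export
small_cnn <- function(input_size = 35, channels = c(8L, 16L, 32L),
                      epochs = 15, batch_size = 32, lr = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  structure(list(backend = "small_cnn", input_size = as.integer(input_size),
                 channels = as.integer(channels), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "small_cnn")
}

#' @export
fit_backend.small_cnn <- function(backend, images, labels) {
  if (!length(images)) stop("empty training set")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  lv <- levels(labels)
  if (length(lv) < 2L) stop("need at least 2 classes in training data")
  X4 <- images_to_array(images, backend$input_size) - 0.5
  y <- as.integer(labels)
  params <- cnn_init(backend$input_size, backend$channels, length(lv),
                     backend$seed)
  st <- list(t = 0L,
             m = NULL, v = NULL)
  # flatten parameter tree into a named list for ADAM bookkeeping
  get_par <- function() {
    out <- list(fc_W = params$fc_W, fc_b = params$fc_b)
    for (l in seq_along(params$conv)) {
      out[[sprintf("c%d_W", l)]] <- params$conv[[l]]$W
      out[[sprintf("c%d_b", l)]] <- params$conv[[l]]$b
    }
    out
  }
  set_par <- function(p) {
    params$fc_W <<- p$fc_W; params$fc_b <<- p$fc_b
    for (l in seq_along(params$conv)) {
      params$conv[[l]]$W <<- p[[sprintf("c%d_W", l)]]
      params$conv[[l]]$b <<- p[[sprintf("c%d_b", l)]]
    }
  }
  pvec <- get_par()
  st$m <- lapply(pvec, function(x) x * 0)
  st$v <- lapply(pvec, function(x) x * 0)
  n <- length(y)
  for (ep in seq_len(backend$epochs)) {
    set.seed(backend$seed + 1000L * ep)
    ord <- sample(n)
    for (b0 in seq(1L, n, by = backend$batch_size)) {
      idx <- ord[b0:min(b0 + backend$batch_size - 1L, n)]
      fw <- cnn_forward(params, X4[, , , idx, drop = FALSE], train = TRUE)
      Y1 <- matrix(0, length(idx), length(lv))
      Y1[cbind(seq_along(idx), y[idx])] <- 1
      gr <- cnn_backward(params, fw, Y1)
      gvec <- list(fc_W = gr$fc_W, fc_b = gr$fc_b)
      for (l in seq_along(params$conv)) {
        gvec[[sprintf("c%d_W", l)]] <- gr[[paste0("conv", l)]]$dW
        gvec[[sprintf("c%d_b", l)]] <- gr[[paste0("conv", l)]]$db
      }
      st$t <- st$t + 1L
      pvec <- get_par()
      for (nm in names(pvec)) {
        up <- adam_update(pvec[[nm]], gvec[[nm]], st$m[[nm]], st$v[[nm]],
                          st$t, backend$lr, backend$beta1, backend$beta2)
        pvec[[nm]] <- up$x; st$m[[nm]] <- up$m; st$v[[nm]] <- up$v
      }
      set_par(pvec)
    }
  }
  structure(list(params = params, levels = lv, config = backend),
            class = "small_cnn_fit")
}

#' @export
predict_proba.small_cnn_fit <- function(handle, images) {
  if (!length(images)) stop("empty prediction set")
  X4 <- images_to_array(images, handle$config$input_size) - 0.5
  probs <- matrix(NA_real_, length(images), length(handle$levels))
  for (b0 in seq(1L, length(images), by = 256L)) {
    idx <- b0:min(b0 + 255L, length(images))
    fw <- cnn_forward(handle$params, X4[, , , idx, drop = FALSE])
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- handle$levels
  probs
}

#' @export
backend_config.small_cnn <- function(backend) unclass(backend)

# ---- transfer-learning adapter -----------------------------------------

#' Transfer-learning backend (architecture-agnostic hook)
#'
#' Adapter for a user-supplied pretrained image network: the network's final
#' fully connected layer is discarded and replaced by a fresh 4-output
#' softmax head trained on the penultimate-layer features with the standard
#' fine-tuning recipe (ADAM, learning rate 8e-4, mini-batch 32, gradient
#' decay factor 0.99, cross-entropy, at most 30 epochs). The supplied
#' network must be a list with a `features(images)` function returning an
#' n-by-d feature matrix and a non-null `final_fc` element marking the layer
#' being replaced; anything else is a configuration error. No pretrained
#' weights ship with the package.
#'
#' @param network the pretrained network adapter (see above).
#' @param epochs maximum training epochs (default 30).
#' @param batch_size mini-batch size (default 32).
#' @param lr initial learning rate (default 8e-4).
#' @param grad_decay gradient (first-moment) decay factor (default 0.99).
#' @param seed RNG seed.
#' @return backend configuration of class `transfer_backend`.
#' @export
transfer_backend <- function(network, epochs = 30, batch_size = 32,
                             lr = 8e-4, grad_decay = 0.99, seed = 1L) {
  if (!is.list(network) || !is.function(network$features))
    stop("configuration error: network must provide a features() function")
  if (is.null(network$final_fc))
    stop("configuration error: network has no final fully connected layer ",
         "to replace")
  structure(list(backend = "transfer", network = network,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, grad_decay = grad_decay, seed = as.integer(seed)),
            class = "transfer_backend")
}

#' @export
fit_backend.transfer_backend <- function(backend, images, labels) {
  if (!length(images)) stop("empty training set")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  lv <- levels(labels)
  Fm <- backend$network$features(images)
  if (!is.matrix(Fm) || nrow(Fm) != length(images))
    stop("network features() must return an n-by-d matrix")
  # standardize penultimate features so the fixed fine-tuning learning rate
  # behaves the same regardless of the feature scale of the supplied network
  mu <- colMeans(Fm)
  sd_ <- apply(Fm, 2L, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Fm <- sweep(sweep(Fm, 2L, mu), 2L, sd_, "/")
  y <- as.integer(labels)
  set.seed(backend$seed)
  W <- matrix(stats::rnorm(ncol(Fm) * length(lv), sd = 0.01), ncol(Fm))
  b <- numeric(length(lv))
  mW <- W * 0; vW <- W * 0; mb <- b * 0; vb <- b * 0; t <- 0L
  n <- length(y)
  for (ep in seq_len(backend$epochs)) {
    set.seed(backend$seed + 1000L * ep)
    ord <- sample(n)
    for (b0 in seq(1L, n, by = backend$batch_size)) {
      idx <- ord[b0:min(b0 + backend$batch_size - 1L, n)]
      P <- softmax_rows(sweep(Fm[idx, , drop = FALSE] %*% W, 2L, b, "+"))
      Y1 <- matrix(0, length(idx), length(lv))
      Y1[cbind(seq_along(idx), y[idx])] <- 1
      dL <- (P - Y1) / length(idx)
      gW <- crossprod(Fm[idx, , drop = FALSE], dL)
      gb <- colSums(dL)
      t <- t + 1L
      uW <- adam_update(W, gW, mW, vW, t, backend$lr, backend$grad_decay, 0.999)
      W <- uW$x; mW <- uW$m; vW <- uW$v
      ub <- adam_update(b, gb, mb, vb, t, backend$lr, backend$grad_decay, 0.999)
      b <- ub$x; mb <- ub$m; vb <- ub$v
    }
  }
  structure(list(W = W, b = b, mu = mu, sd = sd_, levels = lv,
                 network = backend$network,
                 config = backend[setdiff(names(backend), "network")]),
            class = "transfer_fit")
}

#' @export
predict_proba.transfer_fit <- function(handle, images) {
  if (!length(images)) stop("empty prediction set")
  Fm <- handle$network$features(images)
  Fm <- sweep(sweep(Fm, 2L, handle$mu), 2L, handle$sd, "/")
  probs <- softmax_rows(sweep(Fm %*% handle$W, 2L, handle$b, "+"))
  colnames(probs) <- handle$levels
  probs
}

#' @export
backend_config.transfer_backend <- function(backend) {
  c(backend[setdiff(names(backend), "network")], list(network = "user-supplied"))
}
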