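#' Lightweight CNN architecture specification
#'
#' The patch classifier is a five-stage network: three convolution
#' stages of `(kernel, stride, filters)` = (7, 2, 40), (5, 2, 60),
#' (3, 2, 120), each followed by sigmoid activation and 2x2 max-pooling,
#' then two fully connected stages of 100 and 50 sigmoid units and a
#' softmax output layer. The small stride-2 kernels keep spatial
#' resolution long enough to capture insects only a few pixels wide.
#' With same-padding convolutions the input side must run the ladder
#' 64 -> 32 -> 16 -> 8 -> 4 -> 2 -> 1 in integer steps, which fixes the
#' default input at 64 px.
#'
#' @param input_side Patch side length in pixels (default 64).
#' @return A list describing the layer stack; errors if `input_side`
#'   produces a non-integer stage size.
#' @export
cnn_lw_spec <- function(input_side = 64) {
  conv <- list(c(k = 7, s = 2, f = 40),
               c(k = 5, s = 2, f = 60),
               c(k = 3, s = 2, f = 120))
  side <- input_side
  for (cv in conv) {
    side <- floor((side - 1) / unname(cv["s"])) + 1  # same padding, odd kernel
    if (side %% 2 != 0 && side != 1)
      stop("input side ", input_side, " gives odd pre-pool size ", side)
    if (side %% 2 == 0) side <- side / 2 else
      stop("input side ", input_side, " cannot be max-pooled at size ", side)
  }
  list(conv = conv, fc = c(100, 50), input_side = input_side,
       final_side = unname(side),
       flat_features = unname(conv[[3]]["f"] * side^2))
}

#' Build the lightweight CNN classifier
#'
#' Constructs a trainable classifier with the [cnn_lw_spec()] stack plus
#' a dense softmax layer over `classes`. Weights are initialized from a
#' zero-mean Gaussian; the historical default standard deviation is 1,
#' but that saturates the sigmoid stages, so smaller values (e.g. 0.05)
#' train far better and `init_sd` is exposed for that reason. Training
#' uses cross-entropy loss and adaptive moment estimation
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`); see [cnn_train()].
#'
#' @param classes Character vector of output labels (the first stage
#'   gate `C1` uses `c("background", "foreground")`, the category stage
#'   `C2` the insect vocabulary plus `"background"`).
#' @param input_side Patch side length (default 64).
#' @param init_sd Weight initialization standard deviation (default 1).
#' @param seed Integer seed for the initialization draw.
#' @return A classifier of class `c("cnn_lw", "stickypest_classifier")`;
#'   parameters live in its `env` field.
#' @export
build_cnn_lw <- function(classes, input_side = 64, init_sd = 1, seed = 1L) {
  spec <- cnn_lw_spec(input_side)
  K <- length(classes)
  if (K < 2L) stop("need at least two classes")
  env <- new.env(parent = emptyenv())
  local_seed(seed, {
    cv <- spec$conv
    env$params <- list(
      W1 = matrix(stats::rnorm(7 * 7 * 3 * 40, sd = init_sd), 7 * 7 * 3, 40),
      b1 = numeric(40),
      W2 = matrix(stats::rnorm(5 * 5 * 40 * 60, sd = init_sd), 5 * 5 * 40, 60),
      b2 = numeric(60),
      W3 = matrix(stats::rnorm(3 * 3 * 60 * 120, sd = init_sd), 3 * 3 * 60, 120),
      b3 = numeric(120),
      W4 = matrix(stats::rnorm(spec$flat_features * 100, sd = init_sd),
                  spec$flat_features, 100),
      b4 = numeric(100),
      W5 = matrix(stats::rnorm(100 * 50, sd = init_sd), 100, 50),
      b5 = numeric(50),
      W6 = matrix(stats::rnorm(50 * K, sd = init_sd), 50, K),
      b6 = numeric(K)
    )
  })
  env$adam <- NULL
  model <- new_classifier(
    classes,
    predict_fn = NULL,               # filled in below, needs `model`
    spec = spec, env = env,
    subclass = "cnn_lw"
  )
  model$predict_fn <- function(patch) {
    p <- cnn_probs(model, list(patch))
    j <- which.max(p[1, ])
    list(label = classes[j], confidence = unname(p[1, j]))
  }
  model
}

# ---- array plumbing ---------------------------------------------------

# Stack a list of H x W x 3 patches into [N, side, side, 3] in [0, 1],
# resizing where needed.
stack_patches <- function(patches, side) {
  n <- length(patches)
  X <- array(0, c(n, side, side, 3L))
  for (i in seq_len(n)) {
    p <- patches[[i]]
    if (dim(p)[1] != side || dim(p)[2] != side) p <- resize_patch(p, side)
    X[i, , , ] <- p / 255
  }
  X
}

# im2col: gather k x k x C receptive fields at stride s after zero
# padding, as a [N*oh*ow, k*k*C] matrix. Column order is (ky, kx, c)
# with ky fastest; row order is (n, y, x) with n fastest. col2im below
# must mirror both orders exactly.
im2col <- function(x, k, s, pad) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(N, Hp, Wp, C))
  xp[, pad + seq_len(H), pad + seq_len(W), ] <- x
  oh <- (Hp - k) %/% s + 1L; ow <- (Wp - k) %/% s + 1L
  cols <- matrix(0, N * oh * ow, k * k * C)
  col <- 0L
  for (cc in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    col <- col + 1L
    ys <- seq.int(ky, by = s, length.out = oh)
    xs <- seq.int(kx, by = s, length.out = ow)
    cols[, col] <- as.vector(xp[, ys, xs, cc])
  }
  list(cols = cols, oh = oh, ow = ow, N = N, H = H, W = W, C = C,
       k = k, s = s, pad = pad)
}

col2im <- function(dcols, meta) {
  with(meta, {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    dxp <- array(0, c(N, Hp, Wp, C))
    col <- 0L
    for (cc in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
      col <- col + 1L
      ys <- seq.int(ky, by = s, length.out = oh)
      xs <- seq.int(kx, by = s, length.out = ow)
      dxp[, ys, xs, cc] <- dxp[, ys, xs, cc] +
        array(dcols[, col], c(N, oh, ow))
    }
    dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  })
}

conv_forward <- function(x, Wm, b, k, s, pad) {
  meta <- im2col(x, k, s, pad)
  outmat <- sweep(meta$cols %*% Wm, 2L, b, "+")
  out <- array(outmat, c(meta$N, meta$oh, meta$ow, ncol(Wm)))
  list(out = out, meta = meta)
}

conv_backward <- function(dout, Wm, meta) {
  nf <- ncol(Wm)
  doutmat <- matrix(dout, meta$N * meta$oh * meta$ow, nf)
  list(dW = crossprod(meta$cols, doutmat),
       db = colSums(doutmat),
       dx = col2im(doutmat %*% t(Wm), meta))
}

# 2x2 max-pool, stride 2. Ties route the gradient to the first maximal
# cell in (1,1), (2,1), (1,2), (2,2) scan order.
pool_forward <- function(x) {
  d <- dim(x)
  sl <- list(x[, seq.int(1L, d[2], 2L), seq.int(1L, d[3], 2L), , drop = FALSE],
             x[, seq.int(2L, d[2], 2L), seq.int(1L, d[3], 2L), , drop = FALSE],
             x[, seq.int(1L, d[2], 2L), seq.int(2L, d[3], 2L), , drop = FALSE],
             x[, seq.int(2L, d[2], 2L), seq.int(2L, d[3], 2L), , drop = FALSE])
  out <- pmax(sl[[1]], sl[[2]], sl[[3]], sl[[4]])
  list(out = out, slices = sl, in_dim = d)
}

pool_backward <- function(dout, pf) {
  d <- pf$in_dim
  dx <- array(0, d)
  taken <- array(FALSE, dim(dout))
  idx <- list(list(1L, 1L), list(2L, 1L), list(1L, 2L), list(2L, 2L))
  for (j in 1:4) {
    m <- (pf$slices[[j]] == pf$out) & !taken
    taken <- taken | m
    dx[, seq.int(idx[[j]][[1]], d[2], 2L),
       seq.int(idx[[j]][[2]], d[3], 2L), ] <- dout * m
  }
  dx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass; X is [N, side, side, 3] in [0, 1]. Returns the
# cached intermediates needed for backprop.
cnn_forward <- function(params, X) {
  c1 <- conv_forward(X, params$W1, params$b1, 7L, 2L, 3L)
  a1 <- sigmoid(c1$out); p1 <- pool_forward(a1)
  c2 <- conv_forward(p1$out, params$W2, params$b2, 5L, 2L, 2L)
  a2 <- sigmoid(c2$out); p2 <- pool_forward(a2)
  c3 <- conv_forward(p2$out, params$W3, params$b3, 3L, 2L, 1L)
  a3 <- sigmoid(c3$out); p3 <- pool_forward(a3)
  n <- dim(X)[1]
  flat <- matrix(p3$out, n, length(p3$out) / n)
  z4 <- sweep(flat %*% params$W4, 2L, params$b4, "+"); a4 <- sigmoid(z4)
  z5 <- sweep(a4 %*% params$W5, 2L, params$b5, "+"); a5 <- sigmoid(z5)
  z6 <- sweep(a5 %*% params$W6, 2L, params$b6, "+")
  probs <- softmax_rows(z6)
  list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
       c3 = c3, a3 = a3, p3 = p3, flat = flat, a4 = a4, a5 = a5,
       probs = probs)
}

# Backward pass for mean cross-entropy; y is an integer class vector.
cnn_backward <- function(params, fwd, y) {
  n <- nrow(fwd$probs)
  dz6 <- fwd$probs
  dz6[cbind(seq_len(n), y)] <- dz6[cbind(seq_len(n), y)] - 1
  dz6 <- dz6 / n
  g <- list()
  g$W6 <- crossprod(fwd$a5, dz6); g$b6 <- colSums(dz6)
  da5 <- dz6 %*% t(params$W6)
  dz5 <- da5 * fwd$a5 * (1 - fwd$a5)
  g$W5 <- crossprod(fwd$a4, dz5); g$b5 <- colSums(dz5)
  da4 <- dz5 %*% t(params$W5)
  dz4 <- da4 * fwd$a4 * (1 - fwd$a4)
  g$W4 <- crossprod(fwd$flat, dz4); g$b4 <- colSums(dz4)
  dflat <- dz4 %*% t(params$W4)
  dp3 <- array(dflat, dim(fwd$p3$out))
  da3 <- pool_backward(dp3, fwd$p3)
  dz3 <- da3 * fwd$a3 * (1 - fwd$a3)
  bk3 <- conv_backward(dz3, params$W3, fwd$c3$meta)
  g$W3 <- bk3$dW; g$b3 <- bk3$db
  da2 <- pool_backward(bk3$dx, fwd$p2)
  dz2 <- da2 * fwd$a2 * (1 - fwd$a2)
  bk2 <- conv_backward(dz2, params$W2, fwd$c2$meta)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  da1 <- pool_backward(bk2$dx, fwd$p1)
  dz1 <- da1 * fwd$a1 * (1 - fwd$a1)
  bk1 <- conv_backward(dz1, params$W1, fwd$c1$meta)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

cnn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y)], 1e-12)))
}

#' Class probabilities from the CNN
#'
#' @param model A classifier from [build_cnn_lw()].
#' @param patches List of `H x W x 3` patches in `[0, 255]` (resized
#'   internally to the model's input side).
#' @return An `N x K` matrix of softmax probabilities; rows sum to 1.
#' @export
cnn_probs <- function(model, patches) {
  X <- stack_patches(patches, model$spec$input_side)
  p <- cnn_forward(model$env$params, X)$probs
  colnames(p) <- model$classes
  p
}

#' Train the lightweight CNN
#'
#' Mini-batch training with cross-entropy loss and adaptive moment
#' estimation (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`). Parameters
#' are updated in place inside the model's environment.
#'
#' @param model A classifier from [build_cnn_lw()].
#' @param patches List of training patches (`H x W x 3`, `[0, 255]`).
#' @param labels Character vector of labels, one per patch; every label
#'   must be in `model$classes`.
#' @param steps Number of optimization steps (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Learning rate (default 1e-3).
#' @param seed Seed for batch sampling.
#' @return The model, invisibly, with a `loss` attribute holding the
#'   per-step training loss.
#' @export
cnn_train <- function(model, patches, labels, steps = 200, batch_size = 32,
                      lr = 1e-3, seed = 1L) {
  y_all <- match(labels, model$classes)
  if (anyNA(y_all)) stop("labels outside the model vocabulary")
  side <- model$spec$input_side
  X_all <- stack_patches(patches, side)
  n <- length(labels)
  env <- model$env
  if (is.null(env$adam)) {
    env$adam <- list(m = lapply(env$params, function(p) p * 0),
                     v = lapply(env$params, function(p) p * 0), t = 0L)
  }
  losses <- numeric(steps)
  local_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(n, min(batch_size, n))
      X <- X_all[idx, , , , drop = FALSE]
      y <- y_all[idx]
      fwd <- cnn_forward(env$params, X)
      losses[step] <- cnn_loss(fwd$probs, y)
      g <- cnn_backward(env$params, fwd, y)
      env$adam$t <- env$adam$t + 1L
      t <- env$adam$t
      for (nm in names(env$params)) {
        env$adam$m[[nm]] <- 0.9 * env$adam$m[[nm]] + 0.1 * g[[nm]]
        env$adam$v[[nm]] <- 0.999 * env$adam$v[[nm]] + 0.001 * g[[nm]]^2
        mhat <- env$adam$m[[nm]] / (1 - 0.9^t)
        vhat <- env$adam$v[[nm]] / (1 - 0.999^t)
        env$params[[nm]] <- env$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  })
  env$loss <- losses
  attr(model, "loss") <- losses
  invisible(model)
}

#' Training-set accuracy of the CNN
#'
#' @inheritParams cnn_train
#' @return Fraction of patches whose argmax class matches the label.
#' @export
cnn_accuracy <- function(model, patches, labels) {
  p <- cnn_probs(model, patches)
  mean(model$classes[max.col(p, ties.method = "first")] == labels)
}
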