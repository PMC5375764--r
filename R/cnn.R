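# A compact convolutional network for AE-GDI classification.
#
# Architecture: conv1 -> maxpool -> conv2 .. conv_Nconv -> maxpool -> fc1
# (ReLU) -> fc2 -> softmax, with ReLU after every convolution, no zero
# padding (each conv shrinks both spatial dimensions by kernel-1), 2x2
# stride-2 floor max pooling, and dropout before each fully connected layer
# at training time. Trained by minimizing cross-entropy with Adam on
# mini-batches; weights initialized randomly and orthogonally. Convolutions
# are evaluated as im2col gathers followed by a single matrix product, so the
# heavy lifting stays in BLAS.

#' Specify the CNN architecture
#'
#' @param classes Output classes: 2 for authentication, the number of
#'   enrolled subjects for labeling.
#' @param input_height,input_width AE-GDI height (max delay) and width
#'   (window), defaults 32 and 64.
#' @param channels Input channels `Nl` (1 = acceleration only, 2 = both).
#' @param feature_maps Feature maps per convolution layer; its length is the
#'   number of convolution layers `Nconv`. The second pooling layer is
#'   omitted when `Nconv` is 1.
#' @param kernel Convolution kernel `c(height, width)`, default `c(3, 3)`;
#'   the TCNN ablation uses `c(1, 3)`.
#' @param pool Pooling kernel (and stride) `c(height, width)`, default
#'   `c(2, 2)`; the TCNN ablation uses `c(1, 2)`.
#' @param fc1_width Output width of the first fully connected layer.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(classes, input_height = 32, input_width = 64,
                     channels = 2, feature_maps = c(32, 64, 64),
                     kernel = c(3, 3), pool = c(2, 2), fc1_width = 1024) {
  stopifnot(classes >= 2, length(feature_maps) >= 1, all(feature_maps >= 1),
            length(kernel) == 2, length(pool) == 2, fc1_width >= 1)
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 channels = as.integer(channels),
                 feature_maps = as.integer(feature_maps),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 fc1_width = as.integer(fc1_width),
                 classes = as.integer(classes),
                 n_conv = length(feature_maps)),
            class = "cnn_spec")
}

#' Specify the temporal-convolution (TCNN) ablation
#'
#' Same stack as [cnn_spec()] but with 1x3 convolution kernels and 1x2
#' pooling, treating the AE-GDI as stacked 1D delay series: the image height
#' passes through every layer unchanged.
#'
#' @inheritParams cnn_spec
#' @param ... Further arguments passed to [cnn_spec()].
#' @return A `cnn_spec`.
#' @export
tcnn_spec <- function(classes, ...) {
  cnn_spec(classes, kernel = c(1, 3), pool = c(1, 2), ...)
}

#' The full-cohort gait-labeling architecture
#'
#' Instantiates the published-scale network: two input channels, 32x64
#' input, first fully connected layer of width 1024 and a 744-way softmax,
#' with the per-layer feature-map counts read from the packaged
#' configuration file (`inst/config/cnn-full.yaml`).
#'
#' @param config Path to a YAML file holding `feature_maps`, `fc1_width`
#'   and `classes`; defaults to the packaged configuration.
#' @return A `cnn_spec`.
#' @export
full_labeling_spec <- function(config = system.file("config", "cnn-full.yaml",
                                                    package = "aegdi")) {
  cfg <- yaml::read_yaml(config)
  cnn_spec(classes = cfg$classes, channels = 2,
           feature_maps = unlist(cfg$feature_maps),
           fc1_width = cfg$fc1_width)
}

#' Layer-by-layer spatial dimensions of the stack
#'
#' Applies the no-padding convolution arithmetic (each conv reduces height
#' by `kernel_h - 1` and width by `kernel_w - 1`) and floor pooling, raising
#' an error naming the first layer whose output dimension would be
#' non-positive.
#'
#' @param spec A `cnn_spec`.
#' @return A data frame with columns `layer`, `height`, `width`, `maps`.
#' @export
cnn_shapes <- function(spec) {
  h <- spec$input_height; w <- spec$input_width
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  ph <- spec$pool[1]; pw <- spec$pool[2]
  rows <- list(list(layer = "input", height = h, width = w,
                    maps = spec$channels))
  pool_after <- if (spec$n_conv == 1) 1L else c(1L, spec$n_conv)
  for (i in seq_len(spec$n_conv)) {
    h <- h - kh + 1L; w <- w - kw + 1L
    if (h < 1 || w < 1) {
      stop(sprintf("conv%d output dimension non-positive (%dx%d)", i, h, w),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- list(layer = sprintf("conv%d", i),
                                      height = h, width = w,
                                      maps = spec$feature_maps[i])
    if (i %in% pool_after) {
      h <- h %/% ph; w <- w %/% pw
      if (h < 1 || w < 1) {
        stop(sprintf("pooling after conv%d leaves no activations", i),
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- list(
        layer = sprintf("mp%d", if (i == 1L) 1L else 2L),
        height = h, width = w, maps = spec$feature_maps[i])
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# im2col gather indices: P[r, l] is the flat (column-major h,w,c) input index
# feeding row r of the patch matrix for output position l.
im2col_index <- function(h, w, cin, kh, kw) {
  oh <- h - kh + 1L; ow <- w - kw + 1L
  pi <- rep(seq_len(kh), times = kw * cin)
  pj <- rep(rep(seq_len(kw), each = kh), times = cin)
  ch <- rep(seq_len(cin), each = kh * kw)
  roff <- (pi - 1L) + (pj - 1L) * h + (ch - 1L) * h * w
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- (oi - 1L) + (oj - 1L) * h
  outer(roff, base, `+`) + 1L
}

orthogonal_matrix <- function(rows, cols) {
  big <- max(rows, cols); small <- min(rows, cols)
  A <- matrix(stats::rnorm(big * small), big, small)
  qr_ <- qr(A)
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), small, small)
  if (rows >= cols) Q else t(Q)
}

#' Build a model from a specification
#'
#' Precomputes the im2col gather and scatter maps for every convolution and
#' initializes all weight matrices orthogonally (kernels flattened) from the
#' seed; biases start at zero.
#'
#' @param spec A `cnn_spec`.
#' @param seed Integer seed governing initialization.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  shp <- cnn_shapes(spec)  # validates dimensions
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  ph <- spec$pool[1]; pw <- spec$pool[2]
  pool_after <- if (spec$n_conv == 1) 1L else c(1L, spec$n_conv)
  layers <- list()
  with_seed(seed, {
    h <- spec$input_height; w <- spec$input_width; cin <- spec$channels
    for (i in seq_len(spec$n_conv)) {
      oh <- h - kh + 1L; ow <- w - kw + 1L
      maps <- spec$feature_maps[i]
      P <- im2col_index(h, w, cin, kh, kw)
      S <- Matrix::sparseMatrix(i = as.vector(P), j = seq_along(P), x = 1,
                                dims = c(h * w * cin, length(P)))
      layers[[length(layers) + 1L]] <- list(
        type = "conv", name = sprintf("conv%d", i),
        W = orthogonal_matrix(maps, nrow(P)), b = numeric(maps),
        P = P, S = S, in_dim = c(h, w, cin), oh = oh, ow = ow, maps = maps)
      h <- oh; w <- ow; cin <- maps
      if (i %in% pool_after) {
        layers[[length(layers) + 1L]] <- list(
          type = "pool", name = sprintf("mp%d", if (i == 1L) 1L else 2L),
          ph = ph, pw = pw, in_dim = c(h, w, cin),
          out_dim = c(h %/% ph, w %/% pw, cin))
        h <- h %/% ph; w <- w %/% pw
      }
    }
    flat <- h * w * cin
    layers[[length(layers) + 1L]] <- list(
      type = "fc", name = "fl1", W = orthogonal_matrix(spec$fc1_width, flat),
      b = numeric(spec$fc1_width), activation = "relu")
    layers[[length(layers) + 1L]] <- list(
      type = "fc", name = "fl2", W = orthogonal_matrix(spec$classes,
                                                       spec$fc1_width),
      b = numeric(spec$classes), activation = "linear")
  })
  model <- structure(list(spec = spec, layers = layers, history = numeric()),
                     class = "cnn_model")
  model$n_params <- count_parameters(model)
  model
}

#' Count trainable parameters
#'
#' Total size of all convolution kernels, convolution biases, fully
#' connected weight matrices and fully connected biases.
#'
#' @param model A `cnn_model` (or a `cnn_spec`, which is built arithmetically
#'   without allocating weights).
#' @return Integer-valued total.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "cnn_spec")) {
    spec <- model
    shp <- cnn_shapes(spec)
    kh <- spec$kernel[1]; kw <- spec$kernel[2]
    total <- 0
    cin <- spec$channels
    for (i in seq_len(spec$n_conv)) {
      total <- total + (kh * kw * cin + 1) * spec$feature_maps[i]
      cin <- spec$feature_maps[i]
    }
    last <- shp[nrow(shp), ]
    flat <- last$height * last$width * last$maps
    total <- total + flat * spec$fc1_width + spec$fc1_width
    total <- total + spec$fc1_width * spec$classes + spec$classes
    return(total)
  }
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$layers, function(l) {
    if (l$type == "pool") 0 else length(l$W) + length(l$b)
  }, numeric(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d classes, %s feature maps, %s parameters\n",
              x$spec$classes, paste(x$spec$feature_maps, collapse = "/"),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

conv_forward <- function(layer, X) {
  B <- dim(X)[4]
  Xm <- matrix(X, ncol = B)
  GM <- matrix(Xm[as.vector(layer$P), , drop = FALSE], nrow = nrow(layer$P))
  Z <- layer$W %*% GM + layer$b
  out <- aperm(array(Z, c(layer$maps, layer$oh * layer$ow, B)), c(2, 1, 3))
  dim(out) <- c(layer$oh, layer$ow, layer$maps, B)
  list(out = out, GM = GM)
}

conv_backward <- function(layer, dOut, GM, B) {
  # dOut: (oh, ow, maps, B) -> (maps, L*B)
  dZ <- aperm(dOut, c(3, 1, 2, 4))
  dim(dZ) <- c(layer$maps, layer$oh * layer$ow * B)
  dW <- tcrossprod(dZ, GM)
  db <- rowSums(dZ)
  dPatch <- crossprod(layer$W, dZ)                    # kkc x (L*B)
  dim(dPatch) <- c(nrow(layer$P) * ncol(layer$P), B)  # (kkc*L) x B
  dX <- as.matrix(layer$S %*% dPatch)
  dim(dX) <- c(layer$in_dim, B)
  list(dW = dW, db = db, dX = dX)
}

pool_forward <- function(layer, X) {
  d <- dim(X)
  oh <- layer$out_dim[1]; ow <- layer$out_dim[2]
  best <- NULL; arg <- NULL; k <- 0L
  for (b in seq_len(layer$pw)) {
    for (a in seq_len(layer$ph)) {
      k <- k + 1L
      cur <- X[seq(a, by = layer$ph, length.out = oh),
               seq(b, by = layer$pw, length.out = ow), , , drop = FALSE]
      if (is.null(best)) {
        best <- cur; arg <- array(1L, dim(cur))
      } else {
        sel <- cur > best
        best[sel] <- cur[sel]; arg[sel] <- k
      }
    }
  }
  list(out = best, arg = arg)
}

pool_backward <- function(layer, dOut, arg, B) {
  dX <- array(0, c(layer$in_dim, B))
  oh <- layer$out_dim[1]; ow <- layer$out_dim[2]
  k <- 0L
  for (b in seq_len(layer$pw)) {
    for (a in seq_len(layer$ph)) {
      k <- k + 1L
      sel <- arg == k
      if (!any(sel)) next
      ii <- seq(a, by = layer$ph, length.out = oh)
      jj <- seq(b, by = layer$pw, length.out = ow)
      tmp <- dX[ii, jj, , , drop = FALSE]
      tmp[sel] <- dOut[sel]
      dX[ii, jj, , ] <- tmp
    }
  }
  dX
}

# Full forward pass. X: (h, w, c, B) array. Returns caches for backprop when
# train = TRUE (dropout masks drawn from the active RNG stream).
cnn_forward <- function(model, X, train = FALSE, dropout = 0.5) {
  caches <- list()
  A <- X
  B <- dim(X)[4]
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      cf <- conv_forward(l, A)
      mask <- cf$out > 0
      A <- cf$out * mask
      caches[[li]] <- list(GM = cf$GM, relu = mask)
    } else if (l$type == "pool") {
      pf <- pool_forward(l, A)
      A <- pf$out
      caches[[li]] <- list(arg = pf$arg)
    } else {
      if (!is.matrix(A)) {
        A <- matrix(A, ncol = B)  # flatten (h,w,c) column-major
      }
      drop_mask <- NULL
      if (train && dropout > 0) {
        drop_mask <- matrix((stats::runif(length(A)) >= dropout) / (1 - dropout),
                            nrow(A), ncol(A))
        A <- A * drop_mask
      }
      Z <- l$W %*% A + l$b
      relu <- NULL
      if (identical(l$activation, "relu")) {
        relu <- Z > 0
        Zout <- Z * relu
      } else {
        Zout <- Z
      }
      caches[[li]] <- list(A = A, drop_mask = drop_mask, relu = relu)
      A <- Zout
    }
  }
  # softmax over classes (columns are samples)
  Zs <- sweep(A, 2, apply(A, 2, max), `-`)
  E <- exp(Zs)
  probs <- sweep(E, 2, colSums(E), `/`)
  list(probs = probs, logits = A, caches = caches)
}

cnn_backward <- function(model, X, fw, labels) {
  B <- dim(X)[4]
  Y <- matrix(0, model$spec$classes, B)
  Y[cbind(labels, seq_len(B))] <- 1
  dA <- (fw$probs - Y) / B
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (l$type == "fc") {
      if (!is.null(cache$relu)) dA <- dA * cache$relu
      grads[[li]] <- list(dW = tcrossprod(dA, cache$A), db = rowSums(dA))
      dA <- crossprod(l$W, dA)
      if (!is.null(cache$drop_mask)) dA <- dA * cache$drop_mask
    } else if (l$type == "pool") {
      if (is.matrix(dA)) dim(dA) <- c(l$out_dim, B)
      dA <- pool_backward(l, dA, cache$arg, B)
    } else {
      if (is.matrix(dA)) dim(dA) <- c(l$oh, l$ow, l$maps, B)
      dA <- dA * cache$relu
      cb <- conv_backward(l, dA, cache$GM, B)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dX
    }
  }
  grads
}

#' Training regime
#'
#' Defaults follow the reference regime: 50 epochs of mini-batches of 100,
#' Adam at learning rate 0.001, cross-entropy loss, dropout probability 0.5
#' before each fully connected layer, orthogonal initialization (applied at
#' [build_cnn()] time).
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size; a smaller final batch is used, not
#'   dropped.
#' @param learning_rate Adam step size.
#' @param dropout Drop probability before each fully connected layer.
#' @param seed Integer seed governing shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return A list of class `train_spec`.
#' @export
train_spec <- function(epochs = 50, batch_size = 100, learning_rate = 0.001,
                       dropout = 0.5, seed = 1, verbose = FALSE) {
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, dropout = dropout,
                 seed = seed, verbose = verbose),
            class = "train_spec")
}

#' Train a model by Adam on cross-entropy
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param x Input array `(height, width, channels, n)` of AE-GDIs.
#' @param labels Integer class labels in `1..classes`.
#' @param tspec A [train_spec()].
#' @return The trained `cnn_model`, with per-epoch mean losses appended to
#'   `$history`. With `epochs = 0` the model is returned unchanged.
#' @export
train_cnn <- function(model, x, labels, tspec = train_spec()) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as_gdi_array(x, model$spec)
  n <- dim(x)[4]
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels >= 1),
            all(labels <= model$spec$classes))
  missing_cls <- setdiff(seq_len(model$spec$classes), unique(labels))
  if (length(missing_cls)) {
    warning("classes absent from training data: ",
            paste(missing_cls, collapse = ", "))
  }
  if (tspec$epochs == 0) return(model)

  # Adam state per trainable layer
  opt <- lapply(model$layers, function(l) {
    if (l$type == "pool") NULL else
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  lr <- tspec$learning_rate

  with_seed(tspec$seed, {
    for (ep in seq_len(tspec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (off in seq(1L, n, by = tspec$batch_size)) {
        idx <- ord[off:min(off + tspec$batch_size - 1L, n)]
        Xb <- x[, , , idx, drop = FALSE]
        yb <- labels[idx]
        fw <- cnn_forward(model, Xb, train = TRUE, dropout = tspec$dropout)
        p <- fw$probs[cbind(yb, seq_along(idx))]
        loss <- -mean(log(pmax(p, 1e-300)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d)",
                       ep, off), call. = FALSE)
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1L
        grads <- cnn_backward(model, Xb, fw, yb)
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        for (li in seq_along(model$layers)) {
          if (is.null(grads[[li]])) next
          g <- grads[[li]]; o <- opt[[li]]
          o$mW <- beta1 * o$mW + (1 - beta1) * g$dW
          o$vW <- beta2 * o$vW + (1 - beta2) * g$dW^2
          o$mb <- beta1 * o$mb + (1 - beta1) * g$db
          o$vb <- beta2 * o$vb + (1 - beta2) * g$db^2
          model$layers[[li]]$W <- model$layers[[li]]$W -
            lr * (o$mW / bc1) / (sqrt(o$vW / bc2) + eps)
          model$layers[[li]]$b <- model$layers[[li]]$b -
            lr * (o$mb / bc1) / (sqrt(o$vb / bc2) + eps)
          opt[[li]] <- o
        }
      }
      model$history <- c(model$history, ep_loss / nb)
      if (tspec$verbose) {
        message(sprintf("epoch %d/%d loss %.4f", ep, tspec$epochs,
                        ep_loss / nb))
      }
    }
  })
  model
}

# Coerce a batch (array, single aegdi, or list of aegdi) to (h, w, c, n),
# checking against the model spec.
as_gdi_array <- function(x, spec) {
  if (is.list(x) && !is.array(x)) {
    stopifnot(length(x) >= 1)
    d <- dim(x[[1]])
    arr <- array(0, c(d[1], d[2], if (length(d) >= 3) d[3] else 1L, length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    x <- arr
  }
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[1] != spec$input_height || d[2] != spec$input_width ||
      d[3] != spec$channels) {
    stop(sprintf("input is %dx%dx%d but the model expects %dx%dx%d",
                 d[1], d[2], d[3], spec$input_height, spec$input_width,
                 spec$channels), call. = FALSE)
  }
  x
}

#' Class probabilities for a batch of AE-GDIs
#'
#' Forward pass with dropout disabled. Every output row is non-negative and
#' sums to 1.
#'
#' @param object A trained `cnn_model`.
#' @param x Input array `(height, width, channels, n)`, a single image, or a
#'   list of images.
#' @param ... Unused.
#' @return An `n x classes` matrix of class probabilities.
#' @export
predict.cnn_model <- function(object, x, ...) {
  x <- as_gdi_array(x, object$spec)
  fw <- cnn_forward(object, x, train = FALSE)
  t(fw$probs)
}

#' Fuse per-cycle predictions into one decision
#'
#' The label for a probe spanning several consecutive gait cycles is the
#' argmax of the mean probability vector over its AE-GDIs (ties go to the
#' lowest class index); `method = "vote"` uses a majority vote over
#' per-cycle argmaxes instead.
#'
#' @param probabilities An `n x classes` matrix (or list of probability
#'   vectors), one row per consecutive cycle.
#' @param method `"mean"` (default) or `"vote"`.
#' @return Winning class index.
#' @export
aggregate_cycles <- function(probabilities, method = c("mean", "vote")) {
  method <- match.arg(method)
  if (is.list(probabilities)) probabilities <- do.call(rbind, probabilities)
  if (is.null(dim(probabilities))) probabilities <- rbind(probabilities)
  if (nrow(probabilities) == 0) stop("no probability vectors", call. = FALSE)
  if (method == "mean") {
    which.max(colMeans(probabilities))
  } else {
    votes <- tabulate(apply(probabilities, 1, which.max),
                      nbins = ncol(probabilities))
    which.max(votes)
  }
}

#' Persist a trained model
#'
#' Weights and architecture as RDS plus a JSON sidecar (`<path>.json`)
#' recording the specification and parameter count.
#'
#' @param model A `cnn_model`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec), n_params = model$n_params,
               epochs_trained = length(model$history))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model written by [save_cnn()]
#' @param path Path to the RDS file.
#' @return The `cnn_model`.
#' @export
load_cnn <- function(path) readRDS(path)
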