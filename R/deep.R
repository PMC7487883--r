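# Convolutional deep features.
#
# GapNet-PL-style architecture implemented as a real forward-pass network
# in R: 8 convolutional layers, 5 pooling layers (4 max pools + global
# average pooling), 3 fully-connected head layers, SELU activations
# throughout (no ReLU, no batch normalization), with global-average-pool
# taps after three depths concatenated into the 256-unit penultimate
# layer. The six ImageNet-era backbone names are served by compact
# seeded convolutional encoders with the contractual 1000-dim
# penultimate output; externally trained weights can be plugged in
# through `weights = "file"`.

BACKBONE_ORDER <- c("googlenet", "resnet18", "resnet50", "resnet101",
                    "inception_v3", "densenet201", "gapnet_pl")

BACKBONE_DIMS <- c(googlenet = 1000L, resnet18 = 1000L, resnet50 = 1000L,
                   resnet101 = 1000L, inception_v3 = 1000L,
                   densenet201 = 1000L, gapnet_pl = 256L)

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

#' Backbone specification
#'
#' @param name one of `googlenet`, `resnet18`, `resnet50`, `resnet101`,
#'   `inception_v3`, `densenet201`, `gapnet_pl`.
#' @param weights `"random"` (seeded), `"file"` (RDS list written by
#'   [save_backbone()]), or `"pretrained"` (errors with instructions:
#'   trained weights must be supplied as a file in offline use).
#' @param weights_file path used when `weights = "file"`.
#' @param input_side nominal input side (224; 299 for inception_v3,
#'   which is fed resized 224 patches). The forward pass itself accepts
#'   any side: global average pooling removes spatial dependence.
#' @param seed weight-initialization seed.
#' @return A `BackboneSpec`; `feature_dim` is 256 for `gapnet_pl`, 1000
#'   otherwise.
#' @export
backbone_spec <- function(name, weights = c("random", "file", "pretrained"),
                          weights_file = NULL, input_side = NULL, seed = 1L) {
  name <- match.arg(name, BACKBONE_ORDER)
  weights <- match.arg(weights)
  if (is.null(input_side)) input_side <- if (name == "inception_v3") 299L else 224L
  structure(list(name = name, weights = weights, weights_file = weights_file,
                 input_side = as.integer(input_side),
                 feature_dim = BACKBONE_DIMS[[name]], seed = as.integer(seed)),
            class = "BackboneSpec")
}

# LeCun-normal initial weights (the SELU-consistent initialization).
init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(1 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}
init_fc <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, 0, sqrt(1 / din)), din, dout),
       b = numeric(dout))
}

# 3x3 same-padding convolution of an H x W x C array by im2col.
conv2d <- function(x, w) {
  d <- dim(x); h <- d[1]; wd <- d[2]; cin <- d[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  xp <- array(0, dim = c(h + 2 * ph, wd + 2 * pw, cin))
  xp[ph + seq_len(h), pw + seq_len(wd), ] <- x
  cols <- matrix(0, h * wd, kh * kw * cin)
  k <- 0
  for (ci in seq_len(cin)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    k <- k + 1
    cols[, k] <- xp[(i - 1) + seq_len(h), (j - 1) + seq_len(wd), ci]
  }
  wm <- matrix(w, kh * kw * cin, cout)   # (i, j, cin) fastest -> matches cols
  array(cols %*% wm, dim = c(h, wd, cout))
}

# 2x2 stride-2 max pooling (odd trailing row/col dropped).
maxpool2 <- function(x) {
  d <- dim(x); h <- d[1] %/% 2; w <- d[2] %/% 2
  x <- x[seq_len(2 * h), seq_len(2 * w), , drop = FALSE]
  a <- pmax(x[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE],
            x[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE])
  b <- pmax(x[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE],
            x[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE])
  pmax(a, b)
}

gap_pool <- function(x) apply(x, 3, mean)

#' Build the GapNet-style network
#'
#' Convolution widths 32, 32, 64, 64, 128, 128, 256, 256 (3x3, same
#' padding); max pools after conv 2/4/6/8; global-average-pool taps
#' after conv 4, 6 and 8 concatenated (64 + 128 + 256 = 448) and
#' projected by the first fully-connected layer to the 256-unit
#' penultimate representation; two further fully-connected layers end in
#' `n_classes` outputs. SELU follows every learned layer except the
#' output; the network contains no ReLU and no batch normalization.
#'
#' @param n_classes output classes (>= 2).
#' @param seed weight-initialization seed.
#' @return A `GapNet` model object; `model$layers` lists layer types for
#'   architecture audits (8 conv, 5 pool, 3 fc).
#' @export
build_gapnet <- function(n_classes = 3L, seed = 1L) {
  stopifnot(n_classes >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  widths <- c(32, 32, 64, 64, 128, 128, 256, 256)
  cin <- c(3, widths[-8])
  conv <- lapply(seq_len(8), function(i) init_conv(3, 3, cin[i], widths[i]))
  fc <- list(init_fc(448, 256), init_fc(256, 128), init_fc(128, n_classes))
  layers <- c(paste0("conv", 1:8),
              paste0("pool", 1:4), "global_avg_pool",
              paste0("fc", 1:3))
  types <- c(rep("conv", 8), rep("pool", 5), rep("fc", 3))
  structure(list(kind = "gapnet", conv = conv, fc = fc,
                 n_classes = as.integer(n_classes),
                 layers = data.frame(name = layers, type = types,
                                     stringsAsFactors = FALSE),
                 activation = "selu"),
            class = "GapNet")
}

# Forward pass; returns list(penultimate = 256-vector, logits).
gapnet_forward <- function(model, x, with_head = TRUE) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  taps <- list()
  for (i in seq_len(8)) {
    x <- selu(conv2d(x, model$conv[[i]]))
    if (i %% 2 == 0) {
      if (min(dim(x)[1:2]) >= 2) x <- maxpool2(x)
      if (i >= 4) taps[[length(taps) + 1]] <- gap_pool(x)
    }
  }
  z <- unlist(taps)                       # 64 + 128 + 256 = 448
  h1 <- selu(drop(z %*% model$fc[[1]]$W) + model$fc[[1]]$b)   # penultimate, 256
  out <- list(penultimate = h1)
  if (with_head) {
    h2 <- selu(drop(h1 %*% model$fc[[2]]$W) + model$fc[[2]]$b)
    out$logits <- drop(h2 %*% model$fc[[3]]$W) + model$fc[[3]]$b
  }
  out
}

# Compact convolutional encoder behind the six ImageNet-era backbone
# names: strided 3x3 SELU convolutions to a GAP vector, then one
# fully-connected layer to the 1000-dim penultimate output. Depth/width
# schedule varies with the family name; weights are seeded from
# (name, seed) so each backbone yields distinct, reproducible features.
ENCODER_SCHEDULES <- list(
  googlenet    = c(16, 32, 64),
  resnet18     = c(16, 32, 64, 64),
  resnet50     = c(24, 48, 96, 96),
  resnet101    = c(24, 48, 96, 128),
  inception_v3 = c(16, 32, 64, 96),
  densenet201  = c(16, 40, 80, 120)
)

build_encoder <- function(name, seed, n_classes = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + sum(utf8ToInt(name)))
  widths <- ENCODER_SCHEDULES[[name]]
  cin <- c(3, widths[-length(widths)])
  conv <- lapply(seq_along(widths), function(i) init_conv(3, 3, cin[i], widths[i]))
  fc_feat <- init_fc(widths[length(widths)], 1000L)
  fc_out <- init_fc(1000L, n_classes)
  structure(list(kind = "encoder", name = name, conv = conv,
                 fc_feat = fc_feat, fc_out = fc_out,
                 n_classes = as.integer(n_classes)),
            class = "DeepEncoder")
}

encoder_forward <- function(model, x, with_head = TRUE) {
  for (w in model$conv) {
    x <- selu(conv2d(x, w))
    if (min(dim(x)[1:2]) >= 2) x <- maxpool2(x)
  }
  z <- gap_pool(x)
  h <- selu(drop(z %*% model$fc_feat$W) + model$fc_feat$b)   # penultimate, 1000
  out <- list(penultimate = h)
  if (with_head)
    out$logits <- drop(h %*% model$fc_out$W) + model$fc_out$b
  out
}

#' Construct a backbone model from its specification
#'
#' @param spec a [backbone_spec()].
#' @param n_classes classification head width.
#' @return A `GapNet` or `DeepEncoder` model object.
#' @export
build_backbone <- function(spec, n_classes = 3L) {
  stopifnot(inherits(spec, "BackboneSpec"))
  if (spec$weights == "pretrained")
    stop("no trained weights are bundled; export them with save_backbone() ",
         "and load with weights = 'file' for offline use")
  model <- if (spec$name == "gapnet_pl") build_gapnet(n_classes, spec$seed)
           else build_encoder(spec$name, spec$seed, n_classes)
  if (spec$weights == "file") {
    if (is.null(spec$weights_file) || !file.exists(spec$weights_file))
      stop("weights_file not found: ", spec$weights_file)
    saved <- readRDS(spec$weights_file)
    for (nm in intersect(names(saved), names(model))) model[[nm]] <- saved[[nm]]
  }
  model
}

#' Save backbone weights to a file
#'
#' @param model a backbone model object.
#' @param path output RDS path.
#' @return `path`, invisibly.
#' @export
save_backbone <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

# Single-channel window -> 3-channel network input, scaled to [0, 1].
window_to_input <- function(win, side = NULL) {
  m <- win / max(max(win), 1e-8)
  if (!is.null(side) && any(dim(m) != side))
    m <- as.matrix(EBImage::resize(m, w = side, h = side))
  array(rep(m, 3), dim = c(dim(m), 3))
}

#' Penultimate-layer deep features for a patch set
#'
#' Runs every patch's protein window (replicated to three channels)
#' through the backbone and returns per-patch penultimate features plus
#' their mean as the image-level vector.
#'
#' @param patches a `PatchSet`.
#' @param backbone a `BackboneSpec` or a built model object.
#' @param resize_to optional side length to bilinearly resize windows to
#'   before the forward pass; by default windows are fed at native size
#'   (global average pooling makes the feature length side-invariant).
#' @return list: `features` (n_patches x feature_dim matrix, columns
#'   named `deep.<name>.fNNN`), `image_vector` (column means).
#' @export
extract_deep <- function(patches, backbone, resize_to = NULL) {
  stopifnot(inherits(patches, "PatchSet"))
  model <- if (inherits(backbone, "BackboneSpec")) build_backbone(backbone) else backbone
  name <- if (model$kind == "gapnet") "gapnet_pl" else model$name
  fwd <- if (model$kind == "gapnet") gapnet_forward else encoder_forward
  M <- t(vapply(patches$windows, function(wn) {
    fwd(model, window_to_input(wn$protein, resize_to), with_head = FALSE)$penultimate
  }, numeric(BACKBONE_DIMS[[name]])))
  colnames(M) <- sprintf("deep.%s.f%04d", name, seq_len(ncol(M)))
  list(features = M, image_vector = colMeans(M))
}

#' Fine-tune a backbone's classification head
#'
#' Replaces the final layer with an `n_classes`-way output and trains
#' the fully-connected head by momentum SGD on softmax cross-entropy
#' (the convolutional stack stays frozen and acts as the feature
#' extractor; its activations are cached once per patch). For the
#' GapNet model all three head layers train; for the encoders the new
#' output layer trains on the 1000-dim penultimate features.
#'
#' @param model a built backbone model.
#' @param patches list of protein windows (matrices) or a `PatchSet`.
#' @param labels per-patch class labels.
#' @param epochs training epochs (>= 1).
#' @param seed shuffling seed.
#' @param lr learning rate (default 1e-3).
#' @param batch minibatch size (default 32).
#' @param momentum SGD momentum (default 0.9).
#' @return list: `model` (with trained head), `loss_trace` (mean
#'   cross-entropy per epoch, including the pre-training epoch 0),
#'   `train_accuracy`.
#' @export
fine_tune <- function(model, patches, labels, epochs = 10L, seed = 1L,
                      lr = 1e-3, batch = 32L, momentum = 0.9) {
  if (inherits(patches, "PatchSet"))
    patches <- lapply(patches$windows, `[[`, "protein")
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("fine-tuning needs at least 2 classes")
  stopifnot(epochs >= 1, length(patches) == length(y))
  n_classes <- nlevels(y)
  yi <- as.integer(y)

  if (model$kind == "gapnet") {
    feats <- t(vapply(patches, function(p) {
      x <- window_to_input(p)
      taps <- list()
      for (i in seq_len(8)) {
        x <- selu(conv2d(x, model$conv[[i]]))
        if (i %% 2 == 0) {
          if (min(dim(x)[1:2]) >= 2) x <- maxpool2(x)
          if (i >= 4) taps[[length(taps) + 1]] <- gap_pool(x)
        }
      }
      unlist(taps)
    }, numeric(448)))
    dims <- c(448, 256, 128, n_classes)
    W <- list(model$fc[[1]]$W, model$fc[[2]]$W,
              init_fc(128, n_classes)$W)      # replaced output layer
    b <- list(model$fc[[1]]$b, model$fc[[2]]$b, numeric(n_classes))
  } else {
    feats <- t(vapply(patches, function(p) {
      x <- window_to_input(p)
      for (w in model$conv) {
        x <- selu(conv2d(x, w))
        if (min(dim(x)[1:2]) >= 2) x <- maxpool2(x)
      }
      gap_pool(x)
    }, numeric(nrow(model$fc_feat$W))))
    dims <- c(ncol(feats), 1000, n_classes)
    W <- list(model$fc_feat$W, init_fc(1000, n_classes)$W)
    b <- list(model$fc_feat$b, numeric(n_classes))
  }
  L <- length(W)

  forward_head <- function(X) {
    act <- list(X); pre <- list()
    for (l in seq_len(L)) {
      z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
      pre[[l]] <- z
      act[[l + 1]] <- if (l < L) selu(z) else z
    }
    list(act = act, pre = pre, logits = act[[L + 1]])
  }
  ce_loss <- function(logits) {
    lm <- logits - apply(logits, 1, max)
    p <- exp(lm) / rowSums(exp(lm))
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), yi)], 1e-12)))
  }

  set.seed(seed)
  vW <- lapply(W, function(w) w * 0); vb <- lapply(b, function(x) x * 0)
  loss_trace <- ce_loss(forward_head(feats)$logits)   # epoch 0
  n <- nrow(feats)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      fw <- forward_head(feats[idx, , drop = FALSE])
      lm <- fw$logits - apply(fw$logits, 1, max)
      p <- exp(lm) / rowSums(exp(lm))
      delta <- p
      delta[cbind(seq_along(idx), yi[idx])] <-
        delta[cbind(seq_along(idx), yi[idx])] - 1
      delta <- delta / length(idx)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * selu_grad(fw$pre[[l - 1]])
        vW[[l]] <- momentum * vW[[l]] - lr * gW
        vb[[l]] <- momentum * vb[[l]] - lr * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    loss_trace <- c(loss_trace, ce_loss(forward_head(feats)$logits))
  }
  if (model$kind == "gapnet") {
    model$fc <- list(list(W = W[[1]], b = b[[1]]),
                     list(W = W[[2]], b = b[[2]]),
                     list(W = W[[3]], b = b[[3]]))
    model$n_classes <- n_classes
  } else {
    model$fc_feat <- list(W = W[[1]], b = b[[1]])
    model$fc_out <- list(W = W[[2]], b = b[[2]])
    model$n_classes <- n_classes
  }
  pred <- max.col(forward_head(feats)$logits)
  list(model = model, loss_trace = loss_trace,
       train_accuracy = mean(pred == yi), classes = levels(y))
}

#' Concatenate engineered and deep blocks into the combined vector
#'
#' Fixed block order: engineered (848), then googlenet, resnet18,
#' resnet50, resnet101, inception_v3, densenet201 (1000 each), then
#' gapnet_pl (256) — 7104 columns in total. A missing or wrongly sized
#' block raises an error naming it.
#'
#' @param engineered named numeric vector of length 848.
#' @param deep named list of the seven backbone vectors.
#' @return Named numeric vector of length 7104.
#' @export
combine_features <- function(engineered, deep) {
  if (length(engineered) != 848L)
    stop("block 'engineered' must have length 848, got ", length(engineered))
  out <- engineered
  for (nm in BACKBONE_ORDER) {
    if (is.null(deep[[nm]]))
      stop("missing deep feature block '", nm, "'")
    v <- deep[[nm]]
    if (length(v) != BACKBONE_DIMS[[nm]])
      stop("block '", nm, "' must have length ", BACKBONE_DIMS[[nm]],
           ", got ", length(v))
    if (is.null(names(v))) names(v) <- sprintf("deep.%s.f%04d", nm, seq_along(v))
    out <- c(out, v)
  }
  stopifnot(length(out) == 7104L)
  out
}
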