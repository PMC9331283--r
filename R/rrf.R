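#' Frozen convolutional backbone specification
#'
#' A pluggable, frozen feature encoder for the fluency images. The default
#' is a compact seeded random convolutional encoder: images are
#' nearest-neighbour downsampled to \code{pool_side}, convolved with
#' \code{n_filters} fixed random \code{kernel x kernel x 3} filters, passed
#' through a ReLU and globally average-pooled; per-channel global means are
#' appended. The encoder's weights are drawn once from \code{seed} at
#' construction and never updated — only the classification head is ever
#' trained. A deeper pretrained residual backbone can be substituted by
#' supplying a custom \code{encode} function with the same contract.
#'
#' @param name Identifier (default \code{"tiny-random"}).
#' @param input_side Expected image side in pixels (default 224).
#' @param n_filters Number of random filters (default 8).
#' @param kernel Filter side (default 5).
#' @param pool_side Downsampled side before convolution (default 32).
#' @param seed Integer seed for the frozen weights (default 2022).
#' @param encode Optional custom encoder \code{function(image) -> numeric}
#'   overriding the built-in one (it must be deterministic and frozen).
#' @return An \code{rrf_backbone} object.
#' @export
backbone_spec <- function(name = "tiny-random", input_side = 224,
                          n_filters = 8, kernel = 5, pool_side = 32,
                          seed = 2022, encode = NULL) {
  weights <- NULL
  if (is.null(encode)) {
    rng <- local({ set.seed(seed); array(stats::rnorm(kernel * kernel * 3 * n_filters),
                                         dim = c(kernel, kernel, 3L, n_filters)) })
    weights <- rng / sqrt(kernel * kernel * 3)
  }
  structure(list(name = name, input_side = input_side, n_filters = n_filters,
                 kernel = kernel, pool_side = pool_side, seed = seed,
                 frozen = TRUE, weights = weights, encode = encode),
            class = "rrf_backbone")
}

#' Encode images with a frozen backbone
#'
#' @param backbone An \code{rrf_backbone}.
#' @param images A list of \code{fluency_image}s (or H x W x 3 arrays in
#'   [0, 255]).
#' @return Numeric feature matrix, one row per image.
#' @export
backbone_features <- function(backbone, images) {
  if (inherits(images, "fluency_image") ||
      (is.array(images) && length(dim(images)) == 3L)) images <- list(images)
  feats <- lapply(images, function(img) {
    img <- unclass(img) / 255
    if (!is.null(backbone$encode)) return(as.numeric(backbone$encode(img)))
    small <- array(0, dim = c(backbone$pool_side, backbone$pool_side, 3L))
    for (ch in 1:3) small[, , ch] <- resize_nn(img[, , ch], backbone$pool_side)
    k <- backbone$kernel
    out_side <- backbone$pool_side - k + 1L
    pooled <- numeric(backbone$n_filters)
    # valid convolution per filter, ReLU, global average pool
    for (f in seq_len(backbone$n_filters)) {
      acc <- matrix(0, out_side, out_side)
      for (ch in 1:3) {
        w <- backbone$weights[, , ch, f]
        for (i in seq_len(k)) for (j in seq_len(k)) {
          acc <- acc + w[i, j] * small[i:(i + out_side - 1L),
                                       j:(j + out_side - 1L), ch]
        }
      }
      pooled[f] <- mean(pmax(acc, 0))
    }
    c(pooled, apply(small, 3, mean))
  })
  do.call(rbind, feats)
}

#' Head training configuration
#'
#' Mini-batch stochastic gradient descent settings for the binary
#' classification head: batch size 10, 140 epochs, learning rate 1e-4.
#'
#' @param batch_size Mini-batch size (default 10).
#' @param epochs Training epochs (default 140).
#' @param learning_rate SGD step size (default 1e-4).
#' @param seed Integer seed for shuffling (default 1).
#' @return A \code{train_config} list.
#' @export
train_config <- function(batch_size = 10, epochs = 140, learning_rate = 1e-4,
                         seed = 1) {
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0)
    stop("train_config: batch_size, epochs, learning_rate must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the binary classification head on frozen-backbone features
#'
#' Only the final fully-connected layer (a 2-logit linear map with bias) is
#' trained; the convolutional encoder stays frozen. Features are
#' standardized with statistics of the training images only; optimisation is
#' plain seeded mini-batch SGD on the softmax cross-entropy.
#'
#' @param images List of training images (or a precomputed feature matrix
#'   via \code{features}).
#' @param labels Binary labels (0/1, or a 2-level factor); both classes must
#'   be present.
#' @param backbone An \code{rrf_backbone}.
#' @param cfg A \code{train_config}.
#' @param features Optional precomputed \code{backbone_features()} matrix
#'   for \code{images} (the frozen encoder makes precomputation safe).
#' @return An \code{rrf_head} with weights, feature standardization, and a
#'   per-epoch \code{history} data frame (accuracy, loss).
#' @export
train_head <- function(images, labels, backbone, cfg = train_config(),
                       features = NULL) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L)
    stop("train_head: both classes must be present in the labels")
  x <- if (is.null(features)) backbone_features(backbone, images) else as.matrix(features)
  if (nrow(x) != length(y)) stop("train_head: features/labels length mismatch")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  n <- nrow(xs); p <- ncol(xs)
  w <- matrix(0, p, 2L); b <- numeric(2L)
  hot <- cbind(1 - y, y)
  history <- data.frame(epoch = seq_len(cfg$epochs), accuracy = NA_real_,
                        loss = NA_real_)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (s in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(n, s + cfg$batch_size - 1L)]
      xb <- xs[idx, , drop = FALSE]
      pb <- softmax_rows(xb %*% w + rep(b, each = length(idx)))
      g <- (pb - hot[idx, , drop = FALSE]) / length(idx)
      w <- w - cfg$learning_rate * crossprod(xb, g)
      b <- b - cfg$learning_rate * colSums(g)
    }
    pr <- softmax_rows(xs %*% w + rep(b, each = n))
    history$accuracy[ep] <- mean((pr[, 2L] > 0.5) == (y == 1L))
    history$loss[ep] <- -mean(log(pmax(pr[cbind(seq_len(n), y + 1L)], 1e-12)))
  }
  structure(list(weights = w, bias = b, mu = mu, sd = sdv,
                 backbone_name = backbone$name, history = history,
                 trained = TRUE),
            class = "rrf_head")
}

#' Head logits for images
#'
#' @param head A trained \code{rrf_head}.
#' @param backbone The \code{rrf_backbone} used in training.
#' @param images List of images, or \code{features} a precomputed matrix.
#' @param features Optional precomputed feature matrix.
#' @return \code{n x 2} matrix of pre-softmax logits (class order 0, 1).
#' @export
head_logits <- function(head, backbone, images = NULL, features = NULL) {
  if (!inherits(head, "rrf_head") || !isTRUE(head$trained))
    stop("head_logits: model is not a trained rrf_head")
  x <- if (is.null(features)) backbone_features(backbone, images) else as.matrix(features)
  xs <- sweep(sweep(x, 2, head$mu), 2, head$sd, `/`)
  xs %*% head$weights + rep(head$bias, each = nrow(xs))
}

#' Reading-fluency-related feature vector (RRF)
#'
#' Concatenates the two pre-softmax outputs of the time-domain-map head with
#' the two of the spectrogram head, in that fixed order, giving the
#' 4-element RRF vector for one subject segment.
#'
#' @param map_img Time-domain map \code{fluency_image}.
#' @param spec_img Spectrogram \code{fluency_image}.
#' @param map_head,spec_head Trained \code{rrf_head}s for the two image
#'   kinds.
#' @param backbone The shared \code{rrf_backbone}.
#' @return Named numeric vector \code{c(rrf1, rrf2, rrf3, rrf4)}.
#' @export
extract_rrf <- function(map_img, spec_img, map_head, spec_head, backbone) {
  v <- c(head_logits(map_head, backbone, list(map_img))[1L, ],
         head_logits(spec_head, backbone, list(spec_img))[1L, ])
  if (length(v) != 4L || any(!is.finite(v)))
    stop("extract_rrf: expected 4 finite values")
  names(v) <- paste0("rrf", 1:4)
  v
}

#' Checksum of the frozen backbone parameters
#'
#' Convenience for asserting that training never touches the encoder.
#' @param backbone An \code{rrf_backbone}.
#' @return A single numeric checksum.
#' @export
backbone_checksum <- function(backbone) {
  if (is.null(backbone$weights)) return(0)
  sum(backbone$weights * seq_along(backbone$weights))
}
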