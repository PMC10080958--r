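#' Blink classifier specification
#'
#' Architecture and training recipe of the eyes-open/eyes-closed image
#' classifier: 36 x 36 single-channel input; three 3x3 convolutional
#' layers with 16, 32 and 64 filters, each followed by batch
#' normalization and rectification, with 2x2 max pooling after the first
#' two layers (36 -> 18 -> 9); a final fully connected 2-way softmax.
#' Training uses stochastic gradient descent with batch size 128 and data
#' augmentation (random rotation within -45..45 degrees, translation of
#' -1..1 px in both axes, random mirroring over the vertical axis). The
#' reference recipe runs 500 epochs; the desk-scale default here is 50,
#' which already saturates on the synthetic image sets.
#'
#' @param input_px input side length (images are resized to this).
#' @param filters filter counts of the three conv layers.
#' @param batch_size SGD batch size.
#' @param epochs training epochs.
#' @param learning_rate SGD learning rate (no schedule).
#' @param augment logical, apply the augmentation above.
#' @return A `blink_classifier_spec` list.
#' @export
blink_classifier_spec <- function(input_px = 36L, filters = c(16L, 32L, 64L),
                                  batch_size = 128L, epochs = 50L,
                                  learning_rate = 0.01, augment = TRUE) {
  stopifnot(input_px %% 4 == 0, length(filters) == 3)
  spec <- list(input_px = as.integer(input_px), filters = as.integer(filters),
               batch_size = as.integer(batch_size), epochs = as.integer(epochs),
               learning_rate = learning_rate, augment = isTRUE(augment))
  class(spec) <- "blink_classifier_spec"
  spec
}

#' Train the blink (eyes open/closed) classifier
#'
#' Trains the network of [blink_classifier_spec()] on labelled eye images.
#' Per-epoch validation accuracy is logged and the parameters of the
#' best-validation epoch are returned. When no separate validation set is
#' given, a stratified 30% split of the input is held out.
#'
#' @param images array `(h, w, n)` of 8-bit grayscale eye images (0..255 or
#'   `[0,1]`); any size, resized to the spec's input.
#' @param labels factor/character/integer labels with two classes; class
#'   `"closed"` (or the second level) is the blink class.
#' @param spec a [blink_classifier_spec()].
#' @param seed RNG seed; training is reproducible given the seed.
#' @param val_images,val_labels optional explicit validation set.
#' @return A `blink_classifier`: the trained network, `classes`, and a
#'   `history` data.frame (epoch, train_loss, val_accuracy).
#' @export
train_blink_classifier <- function(images, labels, spec = blink_classifier_spec(),
                                   seed = 1, val_images = NULL,
                                   val_labels = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training set must contain both classes")
  if (length(classes) > 2) stop("expected exactly two classes")
  x <- prep_eye_images(images, spec$input_px)
  y <- match(labels, classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(val_images)) {
    hold <- unlist(lapply(split(seq_along(y), y), function(ii)
      sample(ii, max(1, round(0.3 * length(ii))))))
    xv <- x[, , hold, drop = FALSE]; yv <- y[hold]
    x <- x[, , -hold, drop = FALSE]; y <- y[-hold]
  } else {
    xv <- prep_eye_images(val_images, spec$input_px)
    yv <- match(as.character(val_labels), classes)
  }
  n <- dim(x)[3]
  net <- cnn_init(spec$input_px, spec$filters)
  best <- list(acc = -1, net = net, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_accuracy = numeric(0))
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (i0 in seq(1, n, by = spec$batch_size)) {
      ii <- ord[i0:min(i0 + spec$batch_size - 1L, n)]
      if (length(ii) < 2) next   # batch norm needs >= 2 images
      xb <- x[, , ii, drop = FALSE]
      if (spec$augment) xb <- augment_batch(xb)
      yb <- matrix(0, length(ii), 2); yb[cbind(seq_along(ii), y[ii])] <- 1
      lg <- cnn_loss_grad(net, xb, yb)
      net <- cnn_sgd_step(lg$net, lg$grads, spec$learning_rate)
      losses <- c(losses, lg$loss)
    }
    pv <- cnn_predict_probs(net, xv)
    acc <- mean(max.col(pv) == yv)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, net = net, epoch = ep)
  }
  out <- list(net = best$net, classes = classes, spec = spec,
              best_epoch = best$epoch, val_accuracy = best$acc,
              history = hist)
  class(out) <- "blink_classifier"
  out
}

# resize to input_px, scale to [0, 1]
prep_eye_images <- function(images, input_px) {
  if (is.raw(images)) {
    d <- dim(images)
    v <- as.integer(images) / 255
    dim(v) <- d
    images <- v
  }
  d <- dim(images)
  if (length(d) != 3) stop("expected an (h, w, n) image array")
  if (max(images, na.rm = TRUE) > 1) images <- images / 255
  if (d[1] == input_px && d[2] == input_px) return(images)
  out <- array(0, c(input_px, input_px, d[3]))
  for (i in seq_len(d[3]))
    out[, , i] <- resize_gray(images[, , i], input_px, input_px)
  out
}

# bilinear grayscale resize
resize_gray <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  yi <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  xi <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- pmin(pmax(floor(yi), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xi), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y1, x0, drop = FALSE]
  cc <- m[y0, x1, drop = FALSE]; dd <- m[y1, x1, drop = FALSE]
  top <- a * (1 - fy) + b * fy
  bot <- cc * (1 - fy) + dd * fy
  sweep(top, 2, 1 - fx, "*") + sweep(bot, 2, fx, "*")
}

augment_batch <- function(x) {
  d <- dim(x); n <- d[3]; px <- d[1]
  ang <- stats::runif(n, -45, 45) * pi / 180
  tx <- sample(-1:1, n, replace = TRUE)
  ty <- sample(-1:1, n, replace = TRUE)
  mir <- stats::runif(n) < 0.5
  ctr <- (px + 1) / 2
  gi <- matrix(rep(seq_len(px), px), px)        # row index grid
  gj <- t(gi)
  out <- x
  for (i in seq_len(n)) {
    ca <- cos(ang[i]); sa <- sin(ang[i])
    yr <- gi - ctr; xr <- gj - ctr
    src_i <- round(ctr + ca * yr - sa * xr) + ty[i]
    src_j <- round(ctr + sa * yr + ca * xr) + tx[i]
    src_i <- pmin(pmax(src_i, 1), px)
    src_j <- pmin(pmax(src_j, 1), px)
    img <- x[, , i]
    if (mir[i]) img <- img[, px:1]
    out[, , i] <- img[cbind(as.vector(src_i), as.vector(src_j))]
  }
  out
}

#' Classify eye frames as open or closed
#'
#' Deterministic inference of a trained [train_blink_classifier()] model on
#' a stack of eye frames (resized with a warning if their size differs from
#' the network input).
#'
#' @param classifier a `blink_classifier`.
#' @param eye_frames raw or numeric array `(h, w, n)`.
#' @return Data.frame with `frame`, `label`, and per-class probabilities
#'   (columns `p_<class>`, summing to 1).
#' @export
classify_eye_frames <- function(classifier, eye_frames) {
  d <- dim(eye_frames)
  px <- classifier$spec$input_px
  if (!is.raw(eye_frames) && is.null(d)) stop("expected an image array")
  if (d[1] != px || d[2] != px)
    warning(sprintf("resizing %dx%d eye frames to %dx%d", d[1], d[2], px, px))
  x <- prep_eye_images(eye_frames, px)
  probs <- cnn_predict_probs(classifier$net, x)
  lab <- classifier$classes[max.col(probs, ties.method = "first")]
  out <- data.frame(frame = seq_len(dim(x)[3]), label = lab)
  out[[paste0("p_", classifier$classes[1])]] <- probs[, 1]
  out[[paste0("p_", classifier$classes[2])]] <- probs[, 2]
  out
}

#' Blink events and rates from per-frame labels
#'
#' A blink is a maximal run of consecutive closed-eye frames; its duration
#' is the run length times the frame period (20 ms at 50 Hz). Runs
#' separated by a single open frame are not merged. The blink rate is the
#' number of blinks per 15-second window (per-minute values are also
#' reported: 4x the window counts).
#'
#' @param labels per-frame labels (`"closed"` marks closed) or a logical
#'   vector of closed flags.
#' @param rate_hz frame rate of the label stream.
#' @param window_s rate window length (s).
#' @return A `blink_events` list: `events` data.frame (`start_s`,
#'   `duration_s`, `first_frame`, `n_frames`), `rate` data.frame
#'   (`window_start_s`, `n_blinks`, `per_minute`), `rate_units` note.
#' @export
blinks_from_labels <- function(labels, rate_hz = 50, window_s = 15) {
  closed <- if (is.logical(labels)) labels else labels == "closed"
  n <- length(closed)
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  events <- data.frame(
    start_s = (starts[runs] - 1) / rate_hz,
    duration_s = r$lengths[runs] / rate_hz,
    first_frame = starts[runs],
    n_frames = r$lengths[runs])
  total_s <- n / rate_hz
  w0 <- (seq_len(max(1, ceiling(total_s / window_s - 1e-9))) - 1) * window_s
  n_blinks <- vapply(w0, function(t0)
    sum(events$start_s >= t0 & events$start_s < t0 + window_s), numeric(1))
  rate <- data.frame(window_start_s = w0, n_blinks = n_blinks,
                     per_minute = n_blinks * 60 / window_s)
  out <- list(events = events, rate = rate,
              rate_units = "n_blinks per 15 s window; per_minute = 4x")
  class(out) <- "blink_events"
  out
}
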