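test_that("conv-net gradients match finite differences", {
  set.seed(30)
  px <- 8L
  net <- retstim:::cnn_init(px, c(2L, 3L, 4L))
  x <- array(runif(px * px * 4), c(px, px, 4))
  y <- matrix(0, 4, 2); y[cbind(1:4, c(1, 2, 2, 1))] <- 1
  lg <- retstim:::cnn_loss_grad(net, x, y)
  num_grad <- function(set, get) {
    eps <- 1e-5
    n1 <- set(net, get(net) + eps)
    n2 <- set(net, get(net) - eps)
    (retstim:::cnn_loss_grad(n1, x, y)$loss -
       retstim:::cnn_loss_grad(n2, x, y)$loss) / (2 * eps)
  }
  checks <- c(
    num_grad(function(n, v) { n$conv1$W[[5]][1, 2] <- v; n },
             function(n) n$conv1$W[[5]][1, 2]) - lg$grads$conv1$dW[[5]][1, 2],
    num_grad(function(n, v) { n$conv2$W[[1]][2, 3] <- v; n },
             function(n) n$conv2$W[[1]][2, 3]) - lg$grads$conv2$dW[[1]][2, 3],
    num_grad(function(n, v) { n$conv3$gamma[2] <- v; n },
             function(n) n$conv3$gamma[2]) - lg$grads$conv3$dgamma[2],
    num_grad(function(n, v) { n$conv1$beta[1] <- v; n },
             function(n) n$conv1$beta[1]) - lg$grads$conv1$dbeta[1],
    num_grad(function(n, v) { n$fc$W[10, 1] <- v; n },
             function(n) n$fc$W[10, 1]) - lg$grads$fc$W[10, 1])
  expect_lt(max(abs(checks)), 1e-7)
})

test_that("synthetic eye images are deterministic with distinct classes", {
  a <- render_synthetic_eye_images(20, 20, seed = 31)
  b <- render_synthetic_eye_images(20, 20, seed = 31)
  expect_identical(a, b)
  open_mean <- apply(a$images[, , a$labels == "open"], c(1, 2), mean)
  closed_mean <- apply(a$images[, , a$labels == "closed"], c(1, 2), mean)
  expect_gt(mean(abs(open_mean - closed_mean)), 10)
  # the reference class imbalance is expressible directly
  mix <- render_synthetic_eye_images(839, 161, seed = 32)
  expect_equal(sum(mix$labels == "closed"), 161)
  expect_equal(sum(mix$labels == "open"), 839)
})

test_that("training is reproducible and memorizes a small set", {
  set <- render_synthetic_eye_images(80, 80, seed = 33)
  spec <- blink_classifier_spec(epochs = 10)
  m1 <- train_blink_classifier(set$images, set$labels, spec, seed = 34)
  m2 <- train_blink_classifier(set$images, set$labels, spec, seed = 34)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  # training images re-classified correctly with probability > 0.5
  pred <- classify_eye_frames(m1, set$images)
  expect_gt(mean(pred$label == set$labels), 0.9)
  probs <- as.matrix(pred[, c("p_closed", "p_open")])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_error(train_blink_classifier(set$images,
                                      rep("open", length(set$labels))),
               "both classes")
})

test_that("inference is deterministic and resizes with a warning", {
  set <- render_synthetic_eye_images(30, 30, seed = 35)
  model <- train_blink_classifier(set$images, set$labels,
                                  blink_classifier_spec(epochs = 3),
                                  seed = 36)
  one <- set$images[, , c(1, 1, 1)]
  pred <- classify_eye_frames(model, one)
  expect_length(unique(pred$label), 1)
  expect_equal(pred[1, -1], pred[2, -1], ignore_attr = TRUE)
  big <- render_synthetic_eye_images(3, 3, px = 48, seed = 37)
  expect_warning(classify_eye_frames(model, big$images), "resizing")
})

test_that("blink events and rates follow the run-length definition", {
  lab <- c(rep("open", 5), rep("closed", 3), rep("open", 2))
  ev <- blinks_from_labels(lab, rate_hz = 50)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$duration_s, 0.06)
  expect_equal(ev$events$start_s, 0.1)

  expect_equal(nrow(blinks_from_labels(rep("open", 100))$events), 0)

  # 4 blinks uniformly in 60 s -> one per 15 s window, 4 per minute
  closed <- rep(FALSE, 3000)
  closed[c(200, 900, 1700, 2500)] <- TRUE
  ev2 <- blinks_from_labels(closed, rate_hz = 50, window_s = 15)
  expect_equal(ev2$rate$n_blinks, rep(1, 4))
  expect_equal(ev2$rate$per_minute, rep(4, 4))

  # single-open-frame separations are not merged
  lab3 <- c("closed", "closed", "open", "closed")
  expect_equal(nrow(blinks_from_labels(lab3)$events), 2)

  # blink count invariant to padding with open frames
  base <- c(rep(FALSE, 10), rep(TRUE, 4), rep(FALSE, 10))
  padded <- c(rep(FALSE, 37), base, rep(FALSE, 21))
  expect_equal(nrow(blinks_from_labels(padded)$events),
               nrow(blinks_from_labels(base)$events))
})

test_that("synthetic blink rate is recovered within Poisson error", {
  sim <- tiny_walking()    # 30 blinks/min configured, 20 s session
  truth_blinks <- sum(rle(sim$truth$blink_mask)$values)
  lambda <- 30 / 60 * 20
  expect_lt(abs(truth_blinks - lambda), 3.5 * sqrt(lambda))
  # and the label-based counter agrees with the mask
  ev <- blinks_from_labels(sim$truth$blink_mask, rate_hz = 50)
  expect_equal(nrow(ev$events), truth_blinks)
})
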