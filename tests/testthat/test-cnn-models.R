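test_that("parameter counting follows the conv/dense/batch-norm conventions", {
  conv_only <- cecleanr:::new_model_spec(
    list(cecleanr:::layer_conv(3, 32, 3)), input_shape = c(8L, 8L, 3L))
  expect_equal(count_parameters(conv_only), 9L * 3L * 32L + 32L) # 896

  bn_only <- cecleanr:::new_model_spec(
    list(cecleanr:::layer_bn(128)), input_shape = 128L)
  expect_equal(count_parameters(bn_only), 512L) # 4 per channel

  # head alone on a flattened input of length L
  L <- 2048L
  head_spec <- cecleanr:::new_model_spec(
    list(cecleanr:::layer_dense(L, 128L), cecleanr:::layer_act(),
         cecleanr:::layer_bn(128L), cecleanr:::layer_dense(128L, 2L),
         cecleanr:::layer_softmax()),
    input_shape = L)
  expect_equal(count_parameters(head_spec), L * 128L + 128L + 512L + 258L)
})

test_that("the proposed architecture reproduces its published parameter total", {
  spec <- build_proposed_cnn()
  expect_identical(count_parameters(spec), 1708610L)
  # exactly 4 stride-2 layers: the 64x64 input ends 4x4 before the head
  strides <- vapply(spec$layers,
                    function(l) identical(l$kind, "conv") && l$stride == 2L,
                    TRUE)
  expect_equal(sum(strides), 4L)
  shapes <- model_spec_shapes(spec)
  last_conv <- max(which(vapply(spec$layers, function(l)
    identical(l$kind, "conv"), TRUE)))
  expect_equal(shapes[[last_conv]][1:2], c(4, 4))
  # no pooling, no dropout
  expect_false(any(vapply(spec$layers, function(l)
    l$kind == "max_pool", TRUE)))
  # reduced widths shrink the model but keep the downsampling structure
  small <- build_proposed_cnn(0.25)
  expect_lt(count_parameters(small), count_parameters(spec) / 5)
  expect_equal(sum(vapply(small$layers, function(l)
    identical(l$kind, "conv") && l$stride == 2L, TRUE)), 4L)
})

test_that("the VGG-16 comparator reproduces its published parameter total", {
  spec <- build_vgg16_classifier()
  expect_identical(count_parameters(spec), 14977730L)
  # standard conv base alone: 13 convolutions, 14,714,688 parameters
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  expect_equal(sum(kinds == "conv"), 13L)
  base <- cecleanr:::new_model_spec(
    spec$layers[seq_len(max(which(kinds == "max_pool")))])
  expect_identical(count_parameters(base), 14714688L)
  expect_identical(count_parameters(spec) - count_parameters(base), 263042L)
  # base feeds the head a 2x2x512 feature map
  shapes <- model_spec_shapes(spec)
  expect_equal(shapes[[max(which(kinds == "max_pool"))]], c(2, 2, 512))
})

test_that("counted parameters equal the instantiated parameter storage", {
  for (spec in list(build_proposed_cnn(0.1), build_vgg16_classifier())) {
    model <- init_model(spec, seed = 1)
    stored <- sum(vapply(model$params, function(p)
      if (is.null(p)) 0L else length(unlist(p)), 0L))
    expect_equal(stored, count_parameters(spec))
  }
})

test_that("inconsistent layer shapes are rejected", {
  expect_error(cecleanr:::new_model_spec(
    list(cecleanr:::layer_conv(4, 8, 3)), input_shape = c(8L, 8L, 3L)),
    "expects 4 channels")
  expect_error(cecleanr:::new_model_spec(
    list(cecleanr:::layer_flatten(), cecleanr:::layer_dense(100L, 2L)),
    input_shape = c(8L, 8L, 3L)),
    "expects 100 inputs")
})

test_that("forward pass yields probabilities summing to one", {
  spec <- build_proposed_cnn(0.1)
  model <- init_model(spec, seed = 3)
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  probs <- nn_predict(model, x)
  expect_equal(dim(probs), c(4L, 2L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("analytic gradients match finite differences", {
  L <- cecleanr:::layer_conv; B <- cecleanr:::layer_bn
  A <- cecleanr:::layer_act; FL <- cecleanr:::layer_flatten
  D <- cecleanr:::layer_dense; S <- cecleanr:::layer_softmax
  layers <- list(L(3, 4, 3, 1), B(4), A(), L(4, 5, 3, 2), B(5), A(),
                 FL(), D(4 * 4 * 5, 7), A(), B(7), D(7, 2), S())
  spec <- cecleanr:::new_model_spec(layers, input_shape = c(8L, 8L, 3L))
  model <- init_model(spec, seed = 11)
  set.seed(5)
  x <- array(runif(8 * 8 * 3 * 12), c(8, 8, 3, 12))
  y <- sample(1:2, 12, TRUE)
  loss_fn <- function(m)
    cecleanr:::xent_loss_grad(cecleanr:::nn_forward(m, x, TRUE)$out, y)$loss
  fw <- cecleanr:::nn_forward(model, x, TRUE)
  grads <- cecleanr:::nn_backward(model, fw$caches,
                                  cecleanr:::xent_loss_grad(fw$out, y)$dy)
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    if (is.null(p)) next
    for (f in intersect(names(p), c("w", "b", "gamma", "beta"))) {
      for (j in sample(length(p[[f]]), min(4, length(p[[f]])))) {
        m2 <- model; m2$params[[i]][[f]][j] <- m2$params[[i]][[f]][j] + 1e-6
        m3 <- model; m3$params[[i]][[f]][j] <- m3$params[[i]][[f]][j] - 1e-6
        num <- (loss_fn(m2) - loss_fn(m3)) / 2e-6
        ana <- grads[[i]][[f]][j]
        if (abs(num) + abs(ana) > 1e-8) # skip exact-zero gradients
          expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("training separates a linearly separable colour toy in 3 epochs", {
  set.seed(1)
  n <- 80
  mk <- function(channel) {
    x <- array(0.05 * runif(64 * 64 * 3 * n), c(64, 64, 3, n))
    x[, , channel, ] <- x[, , channel, ] + 0.8
    x
  }
  x <- array(0, c(64, 64, 3, 2 * n))
  x[, , , seq_len(n)] <- mk(1)              # reds = clean
  x[, , , n + seq_len(n)] <- mk(2)          # greens = dirty
  y <- rep(c("clean", "dirty"), each = n)
  ord <- sample(2 * n)
  sp <- train_val_split(ord, 0.8, seed = 2)
  r <- train_model(build_proposed_cnn(0.1),
                   x[, , , sp$train, drop = FALSE], y[sp$train],
                   x[, , , sp$val, drop = FALSE], y[sp$val],
                   hyper_params(max_epochs = 3, seed = 4))
  expect_equal(r$best_val_accuracy, 1.0)
  # history bookkeeping: bounded length, best epoch is the running maximum
  expect_lte(nrow(r$history), 3L)
  expect_equal(max(r$history$val_accuracy), r$best_val_accuracy)
  expect_equal(r$history$val_accuracy[r$best_epoch], r$best_val_accuracy)
})

test_that("training rejects degenerate inputs", {
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  expect_error(train_model(build_proposed_cnn(0.1), x, rep("clean", 4),
                           x, rep("clean", 4)),
               "both classes")
})

test_that("two-stage VGG training freezes the base in stage one", {
  set.seed(2)
  n <- 2
  x <- array(runif(64 * 64 * 3 * (2 * n)), c(64, 64, 3, 2 * n))
  y <- rep(c("clean", "dirty"), n)
  spec <- build_vgg16_classifier()
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  base_idx <- seq_len(max(which(kinds == "max_pool")))
  init <- init_model(spec, seed = 1)

  hp <- hyper_params(optimizer = "sgd", batch_size = 4L, seed = 1)
  hp1 <- hp; hp1$max_epochs <- 1L; hp1$patience <- 1L
  # stage 1 only: base parameters stay bit-identical to their init
  s1 <- cecleanr:::run_training(init, x, cecleanr:::encode_labels(y),
                                x, cecleanr:::encode_labels(y),
                                hp1,
                                trainable_idx =
                                  setdiff(seq_along(spec$layers), base_idx),
                                optimizer_name = "sgd", verbose = FALSE)
  for (i in base_idx)
    expect_identical(s1$model$params[[i]], init$params[[i]])
  # head changed
  head_i <- max(which(kinds == "dense"))
  expect_false(identical(s1$model$params[[head_i]], init$params[[head_i]]))

  # full two-stage run changes base parameters in stage 2 and warns about
  # the random base initialisation
  expect_warning(
    r <- train_vgg_two_stage(x, y, x, y, hp = hp,
                             epochs_stage1 = 1L, epochs_stage2 = 1L),
    "random init")
  first_conv <- min(which(kinds == "conv"))
  expect_false(identical(r$model$params[[first_conv]]$w,
                         init$params[[first_conv]]$w))
})

test_that("classification metrics match their defining formulas", {
  m <- classification_metrics(tp = 45, tn = 40, fp = 10, fn = 5)
  expect_equal(m$accuracy, 85.00)
  expect_equal(m$sensitivity, 90.00)
  expect_equal(m$specificity, 80.00)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)

  perfect <- classification_metrics(50, 50, 0, 0)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  # all-one-class predictions on balanced data: MCC guard returns 0
  degenerate <- classification_metrics(50, 0, 50, 0)
  expect_equal(degenerate$mcc, 0)

  # random label/prediction pairs against the brute-force oracle
  set.seed(9)
  for (i in 1:25) {
    truth <- sample(1:2, 40, TRUE)
    pred <- sample(1:2, 40, TRUE)
    m <- classification_metrics(tp = sum(truth == 2 & pred == 2),
                                tn = sum(truth == 1 & pred == 1),
                                fp = sum(truth == 1 & pred == 2),
                                fn = sum(truth == 2 & pred == 1))
    o <- brute_force_metrics(truth, pred)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$mcc, o$mcc)
  }
})

test_that("model weights round-trip through the JSON checkpoint", {
  spec <- build_proposed_cnn(0.05)
  model <- init_model(spec, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_model_weights(model, path)
  back <- load_model_weights(path)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_equal(nn_predict(back, x), nn_predict(model, x), tolerance = 1e-12)
})
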