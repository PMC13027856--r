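test_that("focal loss reduces to cross-entropy and matches hand values", {
  set.seed(91)
  # gamma = 0, alpha = 1 equals cross-entropy on many random draws
  for (i in 1:200) {
    lg <- matrix(rnorm(10), 5, 2)
    y <- sample(1:2, 5, replace = TRUE)
    fl <- focal_loss(lg, y, alpha_t = 1, gamma = 0)
    ce <- cross_entropy_loss(lg, y)
    expect_equal(fl$value, ce$value, tolerance = 1e-12)
  }
  # p_t = 1 gives zero loss
  sure <- matrix(c(-50, 50), 1, 2)
  expect_lt(focal_loss(sure, 2L)$value, 1e-12)
  # p_t = 0.5, alpha 0.25, gamma 2 -> 0.25 * 0.25 * ln 2
  even <- matrix(c(0, 0), 1, 2)
  expect_equal(focal_loss(even, 1L, 0.25, 2)$value, 0.25 * 0.25 * log(2),
               tolerance = 1e-9)
  expect_lt(abs(0.25 * 0.25 * log(2) - 0.043321), 1e-6)
  # non-negative and monotone decreasing in p_t
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p) {
    lg1 <- matrix(c(0, log(p / (1 - p))), 1, 2)
    focal_loss(lg1, 2L, 0.25, 2)$value
  }, 0)
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))
  # analytic gradient agrees with numeric differentiation
  lg <- matrix(rnorm(6), 3, 2)
  y <- c(1, 2, 1)
  fl <- focal_loss(lg, y, 0.25, 2)
  ng <- num_grad(function(z) focal_loss(z, y, 0.25, 2)$value, lg)
  expect_lt(max(abs(fl$grad - ng)), 1e-7)
})

test_that("Mixup produces convex combinations of inputs and labels", {
  x <- list(array(1, dim = c(2, 2)), array(3, dim = c(2, 2)))
  y <- rbind(c(1, 0), c(0, 1))
  m1 <- mixup(x, y, lambda = 1, perm = c(2, 1))
  expect_equal(m1$x, x); expect_equal(m1$y, y)
  m5 <- mixup(x, y, lambda = 0.5, perm = c(2, 1))
  expect_true(all(m5$x[[1]] == 2))
  expect_equal(m5$y[1, ], c(0.5, 0.5))
  expect_true(all(abs(rowSums(m5$y) - 1) < 1e-12))
  # batch of one is the identity
  one <- mixup(x[1], y[1, , drop = FALSE], lambda = 0.3)
  expect_equal(one$x, x[1])
})

test_that("metrics follow the confusion-count definitions and flag degeneracies", {
  perfect <- compute_metrics(tp = 1, fp = 0, fn = 0, tn = 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  m <- compute_metrics(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 0.666667, tolerance = 1e-6)
  deg <- compute_metrics(tp = 0, fp = 0, fn = 2, tn = 3)
  expect_true(is.nan(deg$precision))
  expect_true(deg$undefined["precision"])
  # from labels
  ml <- compute_metrics(pred = c("ASD", "NC", "ASD"),
                        truth = c("ASD", "NC", "NC"))
  expect_equal(ml$tp, 1); expect_equal(ml$fp, 1); expect_equal(ml$tn, 1)
})

test_that("AUC equals the Mann-Whitney pair statistic", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  mix <- roc_auc(c(0.9, 0.4, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mix$auc, 0.75)
  set.seed(92)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    got <- roc_auc(scores, labels)$auc
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(scores), labels)$auc, got, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("our AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  scores <- rnorm(50)
  labels <- sample(c(0, 1), 50, replace = TRUE)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("the Grad-CAM rule localises a quadrant-sum linear model", {
  set.seed(94)
  # activations concentrated in one quadrant; logit = sum over that quadrant
  act <- array(0, dim = c(8, 8, 8, 4))
  act[1:4, 1:4, 1:4, ] <- abs(rnorm(4 * 4 * 4 * 4))
  grads <- array(0, dim = dim(act))
  grads[1:4, 1:4, 1:4, ] <- 1  # d logit / d activation
  cam <- grad_cam_map(act, grads)
  expect_true(all(cam >= 0))
  expect_equal(dim(cam), c(8, 8, 8))
  expect_gte(sum(cam[1:4, 1:4, 1:4]) / sum(cam), 0.8)
  up <- grad_cam_map(act, grads, out_dim = c(16, 16, 16))
  expect_equal(dim(up), c(16, 16, 16))
  expect_true(all(up >= 0))
})

test_that("training is seeded, leak-guarded and loss-decreasing on separable data", {
  spec <- phantom_spec(n_asd = 8, n_control = 8, shape = c(16, 16, 16),
                       effect_size = 2, noise_sd = 0.1, seed = 95)
  ds <- phantom_smri_dataset(spec, n_slices = 8, out_size = 16)
  cfg <- tiny_smri_cfg()
  tc <- train_config(loss = "focal", lr = 1e-3, epochs = 10, batch_size = 8,
                     seed = 95)
  m <- mvb_fit(ds$x, ds$y, "smri", smri_cfg = cfg, config = tc,
               subject_ids = ds$subject_ids)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(m$history$loss[10], m$history$loss[1])
  # identical seed reproduces the loss trajectory exactly
  m2 <- mvb_fit(ds$x, ds$y, "smri", smri_cfg = cfg, config = tc,
                subject_ids = ds$subject_ids)
  expect_identical(m$history$loss, m2$history$loss)
  # subject leakage across train and validation refuses to train
  expect_error(
    mvb_fit(ds$x, ds$y, "smri", smri_cfg = cfg, config = tc,
            subject_ids = ds$subject_ids,
            val = list(x = ds$x[1], y = ds$y[1],
                       subject_ids = ds$subject_ids[1])),
    "leakage")
})

test_that("evaluation aggregates slice probabilities to subject calls", {
  # hand-constructed probabilities through the mean rule
  prob <- c(0.9, 0.9, 0.1)
  expect_equal(mean(prob), 0.633, tolerance = 1e-3)
  spec <- phantom_spec(n_asd = 3, n_control = 3, shape = c(16, 16, 16),
                       effect_size = 2, seed = 96)
  ds <- phantom_smri_dataset(spec, n_slices = 8, out_size = 16)
  cfg <- tiny_smri_cfg()
  tc <- train_config(lr = 1e-3, epochs = 5, batch_size = 6, seed = 96)
  m <- mvb_fit(ds$x, ds$y, "smri", smri_cfg = cfg, config = tc)
  # duplicate each subject's input to mimic multiple samples per subject
  x2 <- c(ds$x, ds$x); y2 <- c(ds$y, ds$y)
  sid2 <- c(ds$subject_ids, ds$subject_ids)
  slice_rep <- evaluate_model(m, x2, y2, sid2, aggregation = "slice")
  subj_rep <- evaluate_model(m, x2, y2, sid2, aggregation = "subject")
  expect_equal(slice_rep$tp + slice_rep$fp + slice_rep$fn + slice_rep$tn, 12)
  expect_equal(subj_rep$tp + subj_rep$fp + subj_rep$fn + subj_rep$tn, 6)
  # single subject, all samples correct -> subject-level accuracy 1
  one <- evaluate_model(m, ds$x[1], ds$y[1], ds$subject_ids[1],
                        aggregation = "subject")
  expect_true(one$accuracy %in% c(0, 1))
  expect_error(evaluate_model(m, list(), character(0)), "empty")
})

test_that("fitted models expose the standard S3 surface", {
  spec <- phantom_spec(n_asd = 3, n_control = 3, shape = c(16, 16, 16),
                       effect_size = 2, seed = 97)
  ds <- phantom_smri_dataset(spec, n_slices = 8, out_size = 16)
  m <- mvb_fit(ds$x, ds$y, "smri", smri_cfg = tiny_smri_cfg(),
               config = train_config(lr = 1e-3, epochs = 2, batch_size = 6,
                                     seed = 97))
  expect_s3_class(m, "mvb_model")
  expect_output(print(m), "mvb_model")
  expect_output(summary(m), "parameters")
  p <- predict(m, ds$x)
  expect_length(p, 6)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(m, ds$x, type = "class")
  expect_true(all(cls %in% c("ASD", "NC")))
  lg <- predict(m, ds$x, type = "logit")
  expect_equal(dim(lg), c(6, 2))
  cam <- grad_cam(m, ds$x[[1]], target = "ASD", plane = 2)
  expect_equal(dim(cam), dim(ds$x[[1]]$mvt)[2:4])
  expect_true(all(cam >= 0))
  expect_error(grad_cam(m, ds$x[[1]], block = 99), "not on the")
  pdf(NULL); plot(m); dev.off()
})
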