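tiny_cfg <- function(max_epochs = 200L, ...)
  mlp_config(hidden_units = 2L, activations = "tanh",
             max_epochs = max_epochs, ...)

test_that("the 70/30 split is a reproducible unstratified partition", {
  labels <- rep(c("malignant", "benign"), c(295, 175))
  sp <- split_cohort(labels, 0.70, seed = 3)
  expect_length(sp$train, 329)
  expect_length(sp$test, 141)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_cohort(labels, 0.70, seed = 3))
  expect_error(split_cohort(c("malignant", "benign"), 0.7, 1), "2 lesions")
})

test_that("linearly separable data trains to a perfect training AUC", {
  set.seed(7)
  x <- matrix(c(rnorm(30, 2), rnorm(30, -2)), ncol = 1)
  lab <- rep(c("malignant", "benign"), each = 30)
  m <- train_mlp(x, lab, tiny_cfg(seed = 11))
  p <- predict_pseudo_probability(m, x)
  expect_equal(roc_curve(p, lab)$auc, 1.0)
})

test_that("SCG solves XOR with at least one of five seeded restarts", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  lab <- c("benign", "malignant", "malignant", "benign")
  ce <- sapply(1:5, function(s) {
    m <- train_mlp(x, lab, mlp_config(hidden_units = 3L,
                                      activations = "tanh",
                                      max_epochs = 1000L,
                                      validation_fraction = 0.25, seed = s))
    p <- predict_pseudo_probability(m, x)
    y <- as.integer(lab == "malignant")
    -mean(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  })
  expect_lt(min(ce), 0.05)
})

test_that("permuted labels give chance-level held-out performance", {
  # held-out set of 140 keeps the null AUC sd near 0.06, so the
  # [0.35, 0.65] band is a wide (>2 sigma) chance-level region
  set.seed(101)
  n <- 200
  x <- matrix(rnorm(2 * n), ncol = 2)
  lab0 <- rep(c("malignant", "benign"), each = n / 2)
  aucs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    lab <- sample(lab0)
    tr <- sample.int(n, 60)
    m <- train_mlp(x[tr, ], lab[tr], tiny_cfg(max_epochs = 100L, seed = s))
    p <- predict_pseudo_probability(m, x[-tr, ])
    oracle_auc_pairs(p, lab[-tr])
  }, numeric(1))
  expect_gte(mean(aucs >= 0.35 & aucs <= 0.65), 0.90)
})

test_that("the forward pass matches a hand computation and is symmetric", {
  # hand-set 2:2:2 tanh network
  w <- list(W1 = matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2, byrow = TRUE),
            b1 = c(0.1, -0.2),
            W2 = matrix(c(1.0, -0.5, -1.0, 0.5), 2, 2, byrow = TRUE),
            b2 = c(0.05, -0.05))
  model <- list(weights = w, activation = "tanh")
  x <- c(0.7, -1.2)
  a1 <- tanh(w$W1 %*% x + w$b1)
  z2 <- w$W2 %*% a1 + w$b2
  byhand <- exp(z2[2]) / sum(exp(z2))
  expect_equal(predict_pseudo_probability(model, x), as.numeric(byhand),
               tolerance = 1e-12)
  # zero weights -> exactly 0.5; identical inputs -> identical outputs
  w0 <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
             W2 = matrix(0, 2, 2), b2 = c(0, 0))
  expect_equal(predict_pseudo_probability(list(weights = w0,
                                               activation = "logistic"),
                                          c(3, -4)), 0.5)
  two <- predict_pseudo_probability(model, rbind(x, x))
  expect_identical(two[1], two[2])
  # class pseudo-probabilities sum to one
  P <- breastdce:::mlp_forward_raw(w, rbind(x, 2 * x), "tanh")$P
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
})

test_that("SCG training error is monotone over accepted steps", {
  set.seed(5)
  x <- matrix(rnorm(80), ncol = 2)
  lab <- ifelse(x[, 1] + x[, 2] + 0.5 * rnorm(40) > 0, "malignant", "benign")
  m <- train_mlp(x, lab, tiny_cfg(seed = 2))
  expect_true(all(diff(m$history) <= 1e-9))
  expect_lte(m$epochs, 200)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_mlp(x, rep("benign", 10), tiny_cfg()), "both classes")
  x[1] <- NA
  expect_error(train_mlp(x, rep(c("benign", "malignant"), 5), tiny_cfg()),
               "non-finite")
  m <- train_mlp(matrix(rnorm(20), ncol = 2),
                 rep(c("benign", "malignant"), 5), tiny_cfg(seed = 4))
  expect_error(predict_pseudo_probability(m, c(1, 2, 3)), "dimension")
})
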