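#' MLP training configuration
#'
#' Hyperparameters of the multilayer-perceptron classifier and its scaled
#' conjugate gradient (SCG) optimizer. Defaults follow the described
#' training protocol: one hidden layer with 1-50 units, hyperbolic tangent
#' or sigmoid activation chosen automatically, batch-mode SCG with initial
#' lambda 5e-7 and initial sigma 5e-5, and epoch count stopped by the
#' minimum relative change in training error (1e-4) or in training error
#' ratio (1e-3).
#'
#' @param hidden_units candidate hidden-unit counts searched (subset of
#'   1..50).
#' @param activations candidate activations: `"tanh"`, `"logistic"`.
#' @param initial_lambda,initial_sigma SCG scalars (Moller's lambda_1 and
#'   sigma).
#' @param stop_rel_error_change minimum relative change in training error.
#' @param stop_rel_error_ratio_change minimum relative change in training
#'   error ratio (error scaled by the initial error).
#' @param max_epochs hard iteration ceiling guaranteeing termination.
#' @param validation_fraction internal held-out fraction of the training
#'   data used to pick the architecture.
#' @param seed RNG seed for weight initialization and the internal split.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_units = c(1:6, 8L, 10L, 12L, 16L, 20L, 25L,
                                        30L, 40L, 50L),
                       activations = c("tanh", "logistic"),
                       initial_lambda = 5e-7, initial_sigma = 5e-5,
                       stop_rel_error_change = 1e-4,
                       stop_rel_error_ratio_change = 1e-3,
                       max_epochs = 1000L,
                       validation_fraction = 0.2,
                       seed = 1L) {
  stopifnot(all(hidden_units >= 1L & hidden_units <= 50L),
            all(activations %in% c("tanh", "logistic")),
            initial_lambda > 0, initial_sigma > 0,
            stop_rel_error_change > 0, stop_rel_error_ratio_change > 0,
            max_epochs >= 1)
  structure(as.list(environment()), class = "mlp_config")
}

# ---- network primitives -------------------------------------------------

act_fun <- function(z, activation)
  if (activation == "tanh") tanh(z) else 1 / (1 + exp(-z))

act_deriv <- function(a, activation)
  if (activation == "tanh") 1 - a^2 else a * (1 - a)

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

flatten_weights <- function(w) c(w$W1, w$b1, w$W2, w$b2)

unflatten_weights <- function(v, d, h) {
  i <- 0
  W1 <- matrix(v[i + seq_len(h * d)], h, d); i <- i + h * d
  b1 <- v[i + seq_len(h)]; i <- i + h
  W2 <- matrix(v[i + seq_len(2 * h)], 2, h); i <- i + 2 * h
  b2 <- v[i + seq_len(2)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward_raw <- function(w, X, activation) {
  A1 <- act_fun(sweep(X %*% t(w$W1), 2, w$b1, "+"), activation)
  P <- softmax2(sweep(A1 %*% t(w$W2), 2, w$b2, "+"))
  list(A1 = A1, P = P)
}

# Total cross-entropy and its gradient (batch).
mlp_loss_grad <- function(v, X, Y, d, h, activation, grad = TRUE) {
  w <- unflatten_weights(v, d, h)
  fw <- mlp_forward_raw(w, X, activation)
  E <- -sum(Y * log(pmax(fw$P, 1e-300)))
  if (!grad) return(list(E = E))
  dZ2 <- fw$P - Y
  gW2 <- t(dZ2) %*% fw$A1
  gb2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% w$W2) * act_deriv(fw$A1, activation)
  gW1 <- t(dZ1) %*% X
  gb1 <- colSums(dZ1)
  list(E = E, g = c(gW1, gb1, gW2, gb2))
}

# ---- scaled conjugate gradient (Moller 1993) ---------------------------

scg_optimize <- function(v, fn_grad, sigma0, lambda0,
                         rel_err_tol, rel_ratio_tol, max_epochs) {
  eg <- fn_grad(v)
  E <- eg$E; r <- -eg$g; p <- r
  E0 <- max(E, .Machine$double.eps)
  lambda <- lambda0; lambda_bar <- 0
  success <- TRUE
  n <- length(v)
  history <- numeric(0)
  small_count <- 0
  delta <- 1
  for (k in seq_len(max_epochs)) {
    p2 <- sum(p * p)
    if (p2 < 1e-300) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      eg2 <- fn_grad(v + sigma * p)
      s <- (eg2$g - (-r)) / sigma
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {                 # make the Hessian estimate pd
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    Enew <- fn_grad(v + alpha * p)$E
    Delta <- 2 * delta_k * (E - Enew) / mu^2
    if (is.finite(Delta) && Delta >= 0) {   # accepted step
      v <- v + alpha * p
      egn <- fn_grad(v)
      r_new <- -egn$g
      lambda_bar <- 0
      success <- TRUE
      if (k %% n == 0) p <- r_new
      else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      rel_change <- (E - egn$E) / max(E, .Machine$double.eps)
      ratio_change <- (E - egn$E) / E0
      E <- egn$E; r <- r_new
      history <- c(history, E)
      if (Delta >= 0.75) lambda <- lambda / 4
      if (abs(rel_change) < rel_err_tol || abs(ratio_change) < rel_ratio_tol)
        small_count <- small_count + 1
      else small_count <- 0
      if (small_count >= 3) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25)
      lambda <- lambda + delta_k * (1 - max(Delta, 0)) / p2
    if (!is.finite(lambda) || lambda > 1e100) break
    if (sqrt(sum(r * r)) < 1e-10) break
  }
  list(v = v, E = E, history = history, epochs = length(history))
}

# Train one fixed architecture; inputs already standardized.
scg_train <- function(X, Y, n_hidden, activation, config) {
  d <- ncol(X)
  npar <- n_hidden * d + n_hidden + 2 * n_hidden + 2
  v0 <- stats::runif(npar, -0.5, 0.5)
  fg <- function(v) mlp_loss_grad(v, X, Y, d, n_hidden, activation)
  opt <- scg_optimize(v0, fg, config$initial_sigma, config$initial_lambda,
                      config$stop_rel_error_change,
                      config$stop_rel_error_ratio_change,
                      config$max_epochs)
  list(weights = unflatten_weights(opt$v, d, n_hidden),
       n_hidden = n_hidden, activation = activation,
       final_error = opt$E, history = opt$history, epochs = opt$epochs)
}

#' Random lesion-level train/test split
#'
#' Simple (unstratified) random split at the lesion level, reproducible
#' under the seed.
#'
#' @param labels per-lesion class labels (`"benign"`/`"malignant"`).
#' @param train_fraction fraction assigned to training (default 0.70).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_fraction = 0.70, seed = 1L) {
  n <- length(labels)
  if (min(table(labels)) < 2L)
    stop("need at least 2 lesions per class to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, round(train_fraction * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Train the MLP classifier with architecture search
#'
#' Searches hidden-unit counts and the two activation functions using an
#' internal 80/20 validation split of the training data (cross-entropy
#' criterion, ties broken toward the smaller network), then retrains the
#' winning architecture on the full training set with batch scaled
#' conjugate gradient.
#'
#' @param scores numeric matrix, lesions x components (PCA scores).
#' @param labels `"benign"`/`"malignant"` per lesion.
#' @param config an [mlp_config()].
#' @return object of class `mlp_model`: weights, architecture, input
#'   standardization, training history and the architecture-search table.
#' @export
train_mlp <- function(scores, labels, config = mlp_config()) {
  X <- as.matrix(scores)
  if (any(!is.finite(X))) stop("non-finite inputs")
  y <- as.integer(labels == "malignant")
  if (length(unique(y)) < 2) stop("need both classes to train")
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- cbind(benign = 1 - y, malignant = y)

  set.seed(as.integer(config$seed))
  n <- nrow(Xs)
  val <- sample.int(n, max(1L, round(config$validation_fraction * n)))
  if (length(unique(y[-val])) < 2) val <- which(y == y[1])[1]  # degenerate tiny data
  search <- expand.grid(activation = config$activations,
                        n_hidden = sort(config$hidden_units),
                        stringsAsFactors = FALSE)
  search <- search[order(search$n_hidden, search$activation), ]
  search$val_ce <- NA_real_
  fits <- vector("list", nrow(search))
  for (i in seq_len(nrow(search))) {
    fit <- scg_train(Xs[-val, , drop = FALSE], Y[-val, , drop = FALSE],
                     search$n_hidden[i], search$activation[i], config)
    p <- mlp_forward_raw(fit$weights, Xs[val, , drop = FALSE],
                         fit$activation)$P
    search$val_ce[i] <- -mean(Y[val, ] * log(pmax(p, 1e-300))) * 2
    fits[[i]] <- fit
  }
  best <- which.min(search$val_ce)   # first minimum = smallest network
  final <- scg_train(Xs, Y, search$n_hidden[best], search$activation[best],
                     config)
  structure(list(weights = final$weights,
                 n_hidden = final$n_hidden,
                 activation = final$activation,
                 center = ctr, scale = scl,
                 n_inputs = ncol(X),
                 history = final$history,
                 epochs = final$epochs,
                 final_error = final$final_error,
                 search = search[, c("n_hidden", "activation", "val_ce")],
                 config = config),
            class = "mlp_model")
}

#' Predicted pseudo-probability of malignancy
#'
#' Softmax output of the malignant class; deterministic given the model
#' weights.
#'
#' @param model an `mlp_model` (or a bare list with `weights` and
#'   `activation` for hand-constructed networks).
#' @param scores matrix lesions x components, or a single score vector.
#' @return numeric vector of pseudo-probabilities in [0, 1].
#' @export
predict_pseudo_probability <- function(model, scores) {
  X <- if (is.null(dim(scores))) t(as.matrix(scores)) else as.matrix(scores)
  if (!is.null(model$n_inputs) && ncol(X) != model$n_inputs)
    stop("score dimension mismatch: expected ", model$n_inputs)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- mlp_forward_raw(model$weights, X, model$activation)$P
  unname(p[, 2])
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP %d:%d:2 (%s), %d SCG epochs, final cross-entropy %.4g\n",
              x$n_inputs, x$n_hidden, x$activation, x$epochs,
              x$final_error))
  invisible(x)
}

#' Serialize an MLP model to JSON
#' @param model an `mlp_model`.
#' @param path file path.
#' @export
write_mlp_json <- function(model, path) {
  jsonlite::write_json(
    list(n_inputs = model$n_inputs, n_hidden = model$n_hidden,
         activation = model$activation,
         W1 = model$weights$W1, b1 = model$weights$b1,
         W2 = model$weights$W2, b2 = model$weights$b2,
         center = model$center, scale = model$scale,
         epochs = model$epochs, final_error = model$final_error),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
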