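#' MLP architecture presets
#'
#' Two fixed two-hidden-layer perceptron architectures for one-hot encoded
#' signatures, each with a rectifier after every hidden layer, dropout
#' active only during training, and a single linear output unit:
#' * `"Lib"`: 32 units (dropout 20%) then 4 units (dropout 10%);
#' * `"Ala"`: 8 units (dropout 0%) then 2 units (dropout 30%).
#'
#' @param name `"Lib"` or `"Ala"`.
#' @return A list with `name`, `units` (length 2), `dropout` (length 2).
#' @export
architecture_spec <- function(name = c("Lib", "Ala")) {
  name <- match.arg(name)
  if (name == "Lib") {
    list(name = "Lib", units = c(32L, 4L), dropout = c(0.20, 0.10))
  } else {
    list(name = "Ala", units = c(8L, 2L), dropout = c(0.00, 0.30))
  }
}

#' Hyper-parameter settings for ensemble training
#'
#' @param batch_size Minibatch size (search grid: 2, 4, 8, 16, 32, 64).
#' @param epochs Training epochs (grid: 10, 20, 30, 40, 50).
#' @param learning_rate Optimizer learning rate
#'   (grid: 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 3e-2).
#' @param architecture `"Lib"` or `"Ala"`.
#' @param sample_weighting `"no-weight"` (all examples weight 1) or
#'   `"with-weight"` (weight = log2 of the summed read count).
#' @param base_seed Seed of ensemble member 1; members use
#'   `base_seed + 0:(n_members-1)`.
#' @return A list of class `hp` with the above fields.
#' @export
hyperparams <- function(batch_size = 32L, epochs = 30L, learning_rate = 5e-3,
                        architecture = "Lib",
                        sample_weighting = c("with-weight", "no-weight"),
                        base_seed = 1L) {
  sample_weighting <- match.arg(sample_weighting)
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate,
         architecture = match.arg(architecture, c("Lib", "Ala")),
         sample_weighting = sample_weighting,
         base_seed = as.integer(base_seed)),
    class = "hp"
  )
}

#' The full hyper-parameter search grid
#'
#' Cross product of the declared search ranges. The full grid has
#' 6 x 5 x 6 x 2 x 2 = 720 combinations; any axis can be restricted.
#'
#' @param batch_size,epochs,learning_rate,architecture,sample_weighting
#'   Vectors of candidate values (defaults: the full search ranges).
#' @return A tibble with one row per combination.
#' @export
hp_grid <- function(batch_size = c(2L, 4L, 8L, 16L, 32L, 64L),
                    epochs = c(10L, 20L, 30L, 40L, 50L),
                    learning_rate = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 3e-2),
                    architecture = c("Lib", "Ala"),
                    sample_weighting = c("no-weight", "with-weight")) {
  tidyr::expand_grid(
    batch_size = batch_size, epochs = epochs,
    learning_rate = learning_rate, architecture = architecture,
    sample_weighting = sample_weighting
  )
}

#' Split training examples by read depth
#'
#' Sorts examples by `weight_raw` (total read count) descending — ties
#' broken by ascending signature, so the split is deterministic — and
#' assigns the deepest 10% to the test set, the next 10% to the validation
#' set, and the remainder to training. Deep-read variants carry the most
#' reliable labels, which is why they anchor evaluation.
#'
#' @param examples Training table from [build_training_table()] (needs
#'   `signature` and `weight_raw`).
#' @return The same tibble with a `split` factor column
#'   (`train`/`val`/`test`), in depth order.
#' @export
split_by_depth <- function(examples) {
  n <- nrow(examples)
  if (n < 10L) stop("TOO_FEW_EXAMPLES: need at least 10 examples to split",
                    call. = FALSE)
  n_test <- floor(0.10 * n)
  n_val <- floor(0.10 * n)
  examples |>
    dplyr::arrange(dplyr::desc(.data$weight_raw), .data$signature) |>
    dplyr::mutate(split = factor(
      rep(c("test", "val", "train"), c(n_test, n_val, n - n_test - n_val)),
      levels = c("train", "val", "test")
    ))
}

#' Per-example training weights
#'
#' `"with-weight"`: log2 of the raw read-count sum, prioritising variants
#' with larger statistical samples (a variant seen once in each gate gets
#' log2(2) = 1; one seen once in total gets 0 and no training influence).
#' `"no-weight"`: all ones.
#'
#' @param weight_raw Positive integer read-count sums.
#' @param sample_weighting `"with-weight"` or `"no-weight"`.
#' @return Numeric weights.
#' @export
sample_weight <- function(weight_raw,
                          sample_weighting = c("with-weight", "no-weight")) {
  sample_weighting <- match.arg(sample_weighting)
  if (any(weight_raw <= 0)) stop("`weight_raw` must be positive",
                                 call. = FALSE)
  if (sample_weighting == "no-weight") rep(1, length(weight_raw))
  else log2(weight_raw)
}

mlp_init <- function(n_in, arch) {
  h1 <- arch$units[1]; h2 <- arch$units[2]
  # He-scaled gaussian init; draws come from the member seed set by callers
  list(
    W1 = matrix(stats::rnorm(n_in * h1, sd = sqrt(2 / n_in)), n_in, h1),
    b1 = rep(0, h1),
    W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
    b2 = rep(0, h2),
    W3 = matrix(stats::rnorm(h2, sd = sqrt(2 / h2)), h2, 1),
    b3 = 0
  )
}

mlp_forward <- function(params, X) {
  A1 <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  A2 <- pmax(sweep(A1 %*% params$W2, 2, params$b2, "+"), 0)
  drop(A2 %*% params$W3 + params$b3)
}

# One Adam step over a list of gradients; state updated by reference-style
# return. Standard moment estimates with bias correction.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train one MLP ensemble member
#'
#' Minimises weighted mean-squared error on one-hot encoded signatures with
#' minibatch Adam for exactly `epochs` epochs. All stochasticity — weight
#' initialisation, epoch shuffling, dropout masks — derives from `seed`, so
#' training is deterministic given (data, hyper-parameters, seed).
#'
#' @param train Training tibble (`signature`, `label`, `weight_raw`).
#' @param scheme A [reference_scheme()].
#' @param hp A [hyperparams()] object.
#' @param seed Integer member seed.
#' @return A list of class `mlp_member`: layer weights, the architecture,
#'   the seed, and the final full-train weighted MSE (`final_loss`).
#' @export
train_member <- function(train, scheme, hp, seed) {
  stopifnot(nrow(train) >= 1L)
  arch <- architecture_spec(hp$architecture)
  X <- encode_signatures(train$signature, scheme)
  y <- train$label
  w <- sample_weight(train$weight_raw, hp$sample_weighting)
  n <- nrow(X)
  bs <- min(hp$batch_size, n)
  d1 <- arch$dropout[1]; d2 <- arch$dropout[2]

  set.seed(seed)
  params <- mlp_init(ncol(X), arch)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  t <- 0L
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      wb <- w[idx]
      sw <- sum(wb)
      if (sw <= 0) next  # all-zero-weight minibatch contributes nothing
      B <- length(idx)

      Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
      A1 <- pmax(Z1, 0)
      if (d1 > 0) {
        M1 <- matrix(stats::rbinom(B * ncol(A1), 1L, 1 - d1) / (1 - d1),
                     B, ncol(A1))
        A1 <- A1 * M1
      }
      Z2 <- sweep(A1 %*% params$W2, 2, params$b2, "+")
      A2 <- pmax(Z2, 0)
      if (d2 > 0) {
        M2 <- matrix(stats::rbinom(B * ncol(A2), 1L, 1 - d2) / (1 - d2),
                     B, ncol(A2))
        A2 <- A2 * M2
      }
      yhat <- drop(A2 %*% params$W3 + params$b3)
      err <- yhat - yb
      if (!all(is.finite(err))) {
        stop("training diverged (non-finite loss) with hp: arch=",
             hp$architecture, " lr=", hp$learning_rate,
             " batch=", hp$batch_size, call. = FALSE)
      }
      # weighted-mean squared error over the minibatch
      dy <- matrix(2 * wb * err / sw, ncol = 1)

      gW3 <- crossprod(A2, dy)
      gb3 <- sum(dy)
      dA2 <- dy %*% t(params$W3)
      if (d2 > 0) dA2 <- dA2 * M2
      dZ2 <- dA2 * (Z2 > 0)
      gW2 <- crossprod(A1, dZ2)
      gb2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(params$W2)
      if (d1 > 0) dA1 <- dA1 * M1
      dZ1 <- dA1 * (Z1 > 0)
      gW1 <- crossprod(Xb, dZ1)
      gb1 <- colSums(dZ1)

      t <- t + 1L
      upd <- adam_step(params,
                       list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                            W3 = gW3, b3 = gb3),
                       state, hp$learning_rate, t)
      params <- upd$params
      state <- upd$state
    }
  }
  pred <- mlp_forward(params, X)
  wt <- if (sum(w) > 0) w / sum(w) else rep(1 / n, n)
  structure(
    list(params = params, arch = arch, seed = seed,
         final_loss = sum(wt * (pred - y)^2)),
    class = "mlp_member"
  )
}

#' Train an ensemble of MLP regressors
#'
#' Trains `n_members` members (default 10) with seeds
#' `hp$base_seed + 0:(n_members-1)`, each with its own random
#' initialisation, shuffling, and dropout masks. The ensemble prediction is
#' the arithmetic mean of member outputs.
#'
#' @param train Training tibble (`signature`, `label`, `weight_raw`).
#' @param scheme A [reference_scheme()].
#' @param hp A [hyperparams()] object.
#' @param n_members Ensemble size (default 10).
#' @return An object of class `mlp_ensemble`.
#' @export
train_ensemble <- function(train, scheme, hp, n_members = 10L) {
  seeds <- hp$base_seed + seq_len(n_members) - 1L
  members <- lapply(seeds, function(s) train_member(train, scheme, hp, s))
  structure(
    list(members = members, hp = hp, scheme = scheme, seeds = seeds,
         n_train = nrow(train)),
    class = "mlp_ensemble"
  )
}

#' Predict log2 enrichment ratios
#'
#' Mean of the member predictions; dropout is disabled at prediction time.
#'
#' @param object An `mlp_ensemble`.
#' @param signatures Character vector of signatures (may be empty).
#' @param members If `TRUE`, return the per-member prediction matrix
#'   (rows = signatures) instead of the mean.
#' @param ... Unused.
#' @return Numeric vector of predictions (or a matrix with `members = TRUE`).
#' @export
predict.mlp_ensemble <- function(object, signatures, members = FALSE, ...) {
  if (length(signatures) == 0L) {
    return(if (members) matrix(0, 0, length(object$members)) else numeric(0))
  }
  X <- encode_signatures(signatures, object$scheme)
  preds <- vapply(object$members, function(m) mlp_forward(m$params, X),
                  numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X))
  if (members) preds else rowMeans(preds)
}

#' Number of trainable scalars in a member or ensemble
#'
#' @param model An `mlp_member` or `mlp_ensemble`.
#' @return Integer count of weights plus biases (per member).
#' @export
count_params <- function(model) {
  if (inherits(model, "mlp_ensemble")) model <- model$members[[1]]
  sum(vapply(model$params, length, integer(1)))
}

#' Pearson correlation between predicted and observed values
#'
#' Direct implementation of the product-moment formula
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    stop("ZERO_VARIANCE: constant vector has no defined correlation",
         call. = FALSE)
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Grid search over hyper-parameter combinations
#'
#' The depth split is computed once and reused for every combination. Each
#' combination trains a fresh ensemble on the training fold and is scored
#' by Pearson correlation on the validation fold; the winner (ties: first
#' in grid order) is rescored exactly once on the held-out test fold.
#'
#' @param examples Training table from [build_training_table()].
#' @param scheme A [reference_scheme()].
#' @param grid Tibble of combinations, as from [hp_grid()].
#' @param n_members Ensemble size per combination (default 10).
#' @param base_seed Base seed shared by all combinations.
#' @return A list with `best_hp` ([hyperparams()]), `model` (the winning
#'   `mlp_ensemble`), `leaderboard` (grid + `val_pearson`, sorted), and
#'   `test_pearson`.
#' @export
grid_search <- function(examples, scheme, grid = hp_grid(), n_members = 10L,
                        base_seed = 1L) {
  split <- split_by_depth(examples)
  train <- dplyr::filter(split, .data$split == "train")
  val <- dplyr::filter(split, .data$split == "val")
  test <- dplyr::filter(split, .data$split == "test")

  best <- NULL
  val_scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- hyperparams(
      batch_size = grid$batch_size[i], epochs = grid$epochs[i],
      learning_rate = grid$learning_rate[i],
      architecture = grid$architecture[i],
      sample_weighting = grid$sample_weighting[i], base_seed = base_seed
    )
    fit <- tryCatch(train_ensemble(train, scheme, hp, n_members),
                    error = function(e) NULL)
    if (is.null(fit)) next
    r <- tryCatch(pearson_r(predict(fit, val$signature), val$label),
                  error = function(e) NA_real_)
    val_scores[i] <- r
    if (!is.na(r) && (is.null(best) || r > best$val_pearson)) {
      best <- list(hp = hp, model = fit, val_pearson = r)
    }
  }
  if (is.null(best)) stop("all hyper-parameter combinations failed",
                          call. = FALSE)
  leaderboard <- dplyr::mutate(grid, val_pearson = val_scores) |>
    dplyr::arrange(dplyr::desc(.data$val_pearson))
  test_r <- pearson_r(predict(best$model, test$signature), test$label)
  list(best_hp = best$hp, model = best$model, leaderboard = leaderboard,
       val_pearson = best$val_pearson, test_pearson = test_r)
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  cat("<mlp_ensemble>", length(x$members), "members,",
      x$hp$architecture, "architecture,", count_params(x),
      "parameters each\n")
  cat("  trained on", x$n_train, "examples; seeds",
      x$seeds[1], "..", x$seeds[length(x$seeds)], "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-member summary of an ensemble
#'
#' @param x An `mlp_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per member: `member`, `seed`, `final_loss`,
#'   `n_params`.
#' @method tidy mlp_ensemble
#' @export
tidy.mlp_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    seed = x$seeds,
    final_loss = vapply(x$members, function(m) m$final_loss, numeric(1)),
    n_params = vapply(x$members, count_params, numeric(1))
  )
}

#' One-row summary of an ensemble fit
#'
#' @param x An `mlp_ensemble`.
#' @param ... Unused.
#' @return One-row tibble of hyper-parameters and fit metadata.
#' @method glance mlp_ensemble
#' @export
glance.mlp_ensemble <- function(x, ...) {
  tibble::tibble(
    architecture = x$hp$architecture,
    batch_size = x$hp$batch_size,
    epochs = x$hp$epochs,
    learning_rate = x$hp$learning_rate,
    sample_weighting = x$hp$sample_weighting,
    n_members = length(x$members),
    n_train = x$n_train,
    mean_final_loss = mean(vapply(x$members, function(m) m$final_loss,
                                  numeric(1)))
  )
}
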