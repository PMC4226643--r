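# One-hidden-layer sigmoid multilayer perceptron trained from scratch by
# online backpropagation (stochastic gradient descent on squared error).
# "Generations" counts individual pattern presentations, not epochs.

#' Logistic sigmoid activation
#'
#' \eqn{f(x) = 1 / (1 + e^{-x})}; saturates smoothly, never NaN.
#'
#' @param x Numeric.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

#' Training configuration for the perceptron
#'
#' @param learning_rate Gradient step size, in (0, 1].
#' @param generations Total pattern presentations (>= 1). Patterns are
#'   drawn cyclically, reshuffled each pass, from the seeded RNG.
#' @param hidden Hidden-neuron count h (one hidden layer).
#' @param seed RNG seed for weight initialization and presentation order.
#' @param momentum Momentum coefficient; default 0 (plain gradient descent).
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, generations = 50000L,
                         hidden = 60L, seed = 1L, momentum = 0) {
  stopifnot(learning_rate > 0, learning_rate <= 1,
            generations >= 1, hidden >= 1, momentum >= 0)
  structure(list(learning_rate = learning_rate,
                 generations = as.integer(generations),
                 hidden = as.integer(hidden),
                 seed = as.integer(seed),
                 momentum = momentum),
            class = "train_config")
}

# Forward pass + analytic gradients of the per-pattern squared error
# E = 0.5 * sum((o - t)^2) for one pattern. Exposed internally for the
# finite-difference gradient check.
mlp_forward <- function(x, Wh, bh, Wo, bo) {
  ah <- sigmoid(drop(crossprod(Wh, x)) + bh)
  o <- sigmoid(drop(crossprod(Wo, ah)) + bo)
  list(ah = ah, o = o)
}

mlp_gradients <- function(x, target, Wh, bh, Wo, bo) {
  fw <- mlp_forward(x, Wh, bh, Wo, bo)
  err <- fw$o - target
  delta_o <- err * fw$o * (1 - fw$o)
  delta_h <- drop(Wo %*% delta_o) * fw$ah * (1 - fw$ah)
  list(dWh = outer(x, delta_h), dbh = delta_h,
       dWo = outer(fw$ah, delta_o), dbo = delta_o,
       loss = 0.5 * sum(err^2))
}

#' Train the sigmoid multilayer perceptron
#'
#' Features are z-score standardized by the training-set mean and standard
#' deviation (the scaler is stored in the model and re-applied at
#' prediction time); species targets are one-hot encoded. Weights and
#' biases start uniform(-0.5, 0.5) from the seed and are updated by
#' online stochastic gradient descent on the squared error, one pattern
#' presentation per generation.
#'
#' @param table Feature table `data.frame` (15 feature columns +
#'   `species`), e.g. from [extract_features_dir()].
#' @param config A [train_config()].
#' @return Object of class `mlp_model`: weights `Wh` (15 x h), `bh`,
#'   `Wo` (h x m), `bo`, `label_map` (species names in output order),
#'   `scaler` (`mean`, `sd` per feature), `config`, and `loss_trace`
#'   (mean per-pattern loss per pass over the data).
#' @export
mlp_train <- function(table, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(table[, feature_names()])
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(rowSums(X)))[1]
    stop("non-finite feature in row ", bad)
  }
  labels <- as.character(table$species)
  species <- sort(unique(labels))
  m <- length(species)
  if (m < 2) stop("need at least 2 species to train")
  if (any(tabulate(factor(labels, levels = species)) < 2))
    stop("need at least 2 samples per species")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- unname(sweep(sweep(X, 2, mu), 2, sdev, "/"))
  Tm <- matrix(0, nrow(X), m)
  Tm[cbind(seq_len(nrow(X)), match(labels, species))] <- 1
  n_in <- ncol(X); h <- config$hidden
  set.seed(config$seed)
  Wh <- matrix(stats::runif(n_in * h, -0.5, 0.5), n_in, h)
  bh <- stats::runif(h, -0.5, 0.5)
  Wo <- matrix(stats::runif(h * m, -0.5, 0.5), h, m)
  bo <- stats::runif(m, -0.5, 0.5)
  vWh <- Wh * 0; vbh <- bh * 0; vWo <- Wo * 0; vbo <- bo * 0
  lr <- config$learning_rate; mom <- config$momentum
  n <- nrow(X)
  order_idx <- integer(0)
  loss_trace <- numeric(0)
  acc_loss <- 0; acc_n <- 0L
  for (g in seq_len(config$generations)) {
    if (length(order_idx) == 0L) {
      if (acc_n > 0L) {
        loss_trace <- c(loss_trace, acc_loss / acc_n)
        acc_loss <- 0; acc_n <- 0L
      }
      order_idx <- sample.int(n)
    }
    i <- order_idx[1L]; order_idx <- order_idx[-1L]
    gr <- mlp_gradients(Xs[i, ], Tm[i, ], Wh, bh, Wo, bo)
    if (mom > 0) {
      vWh <- mom * vWh - lr * gr$dWh; Wh <- Wh + vWh
      vbh <- mom * vbh - lr * gr$dbh; bh <- bh + vbh
      vWo <- mom * vWo - lr * gr$dWo; Wo <- Wo + vWo
      vbo <- mom * vbo - lr * gr$dbo; bo <- bo + vbo
    } else {
      Wh <- Wh - lr * gr$dWh; bh <- bh - lr * gr$dbh
      Wo <- Wo - lr * gr$dWo; bo <- bo - lr * gr$dbo
    }
    acc_loss <- acc_loss + gr$loss; acc_n <- acc_n + 1L
  }
  if (acc_n > 0L) loss_trace <- c(loss_trace, acc_loss / acc_n)
  structure(list(Wh = Wh, bh = bh, Wo = Wo, bo = bo,
                 label_map = species,
                 scaler = list(mean = mu, sd = sdev),
                 config = config, loss_trace = loss_trace),
            class = "mlp_model")
}

#' Predict the species of a feature vector
#'
#' The winning species is the argmax of the raw sigmoid outputs (ties
#' broken by lowest output index). The thresholded binary output vector
#' (step at 0.5) is also reported; when no output clears 0.5 the argmax
#' class is still returned with `confident = FALSE`.
#'
#' @param model An `mlp_model`.
#' @param fv Numeric feature vector of length 15, or a feature table /
#'   matrix with 15 feature columns (one prediction per row).
#' @return For a single vector: list `species, raw_outputs,
#'   binary_outputs, confident`. For multiple rows: character vector of
#'   species.
#' @export
mlp_predict <- function(model, fv) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.data.frame(fv)) fv <- as.matrix(fv[, feature_names()])
  if (is.matrix(fv)) {
    if (ncol(fv) != nrow(model$Wh))
      stop("feature dimension mismatch: model expects ", nrow(model$Wh))
    return(vapply(seq_len(nrow(fv)),
                  function(i) mlp_predict(model, fv[i, ])$species,
                  character(1)))
  }
  if (length(fv) != nrow(model$Wh))
    stop("feature dimension mismatch: model expects ", nrow(model$Wh))
  if (any(!is.finite(fv))) stop("non-finite feature value")
  xs <- (fv - model$scaler$mean) / model$scaler$sd
  o <- mlp_forward(xs, model$Wh, model$bh, model$Wo, model$bo)$o
  k <- which.max(o)
  list(species = model$label_map[k],
       raw_outputs = stats::setNames(o, model$label_map),
       binary_outputs = stats::setNames(as.integer(o >= 0.5),
                                        model$label_map),
       confident = any(o >= 0.5))
}

#' Save / load an MLP model
#'
#' The model is serialized as a single documented JSON container holding
#' the weights, scaler, label map, training configuration and a format
#' version field.
#'
#' @param model An `mlp_model`.
#' @param path File path (conventionally `.json`).
#' @return `write_mlp_model`: `path` invisibly; `read_mlp_model`: the
#'   `mlp_model`.
#' @export
write_mlp_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(format = "taxofeat-mlp", version = 1L,
              Wh = model$Wh, bh = model$bh, Wo = model$Wo, bo = model$bo,
              label_map = model$label_map,
              scaler_mean = model$scaler$mean, scaler_sd = model$scaler$sd,
              config = unclass(model$config),
              loss_trace = model$loss_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "taxofeat-mlp")
    stop("not a taxofeat MLP model file: ", path)
  cfg <- do.call(train_config, obj$config[c("learning_rate", "generations",
                                            "hidden", "seed", "momentum")])
  fn <- feature_names()
  Wh <- as.matrix(obj$Wh); Wo <- as.matrix(obj$Wo)
  if (nrow(Wh) != length(fn) || nrow(Wo) != cfg$hidden)
    stop("corrupt model file: weight dimensions do not match config")
  structure(list(Wh = Wh,
                 bh = as.numeric(obj$bh),
                 Wo = Wo,
                 bo = as.numeric(obj$bo),
                 label_map = as.character(obj$label_map),
                 scaler = list(mean = stats::setNames(
                                 as.numeric(obj$scaler_mean), fn),
                               sd = stats::setNames(
                                 as.numeric(obj$scaler_sd), fn)),
                 config = cfg,
                 loss_trace = as.numeric(obj$loss_trace)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("mlp_model: 15 -", ncol(x$Wh), "-", ncol(x$Wo),
      "sigmoid network;", length(x$label_map), "species; lr",
      x$config$learning_rate, ";", x$config$generations, "generations\n")
  invisible(x)
}
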