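# Split-based evaluation protocol: stratified train/test splits at several
# training fractions, success rates with confusion matrices, and a
# hidden-neuron sweep.

#' Stratified train/test split of a feature table
#'
#' The split is performed independently within each species at the stated
#' training fraction; rounding leaves at least one test sample (and one
#' training sample) per species. The two parts are disjoint and exhaustive.
#'
#' @param table Feature table (15 feature columns + `species`).
#' @param train_fraction Training proportion, in (0, 1).
#' @param seed RNG seed; same seed gives the identical split.
#' @return List with `train` and `test` feature tables.
#' @export
stratified_split <- function(table, train_fraction, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.character(table$species)
  set.seed(seed)
  train_idx <- integer(0)
  for (sp in sort(unique(labels))) {
    rows <- which(labels == sp)
    n <- length(rows)
    if (n < 2) stop("species '", sp, "' has fewer than 2 samples")
    n_train <- round(train_fraction * n)
    n_train <- max(1L, min(n - 1L, n_train))
    train_idx <- c(train_idx, sample(rows, n_train))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), ,
                    drop = FALSE])
}

#' Success rate of a model on a test table
#'
#' 100 x (correct argmax predictions) / (test size), with the species
#' confusion matrix (rows = true species, columns = predicted).
#'
#' @param model An `mlp_model`.
#' @param test Feature table of test specimens.
#' @return List with `rate` (percentage), `confusion` (count matrix),
#'   `n` (test size).
#' @export
success_rate <- function(model, test) {
  if (nrow(test) == 0) stop("empty test set")
  truth <- as.character(test$species)
  pred <- mlp_predict(model, test)
  lv <- sort(unique(c(truth, model$label_map)))
  confusion <- table(factor(truth, levels = lv),
                     factor(pred, levels = lv))
  list(rate = 100 * mean(pred == truth),
       confusion = unclass(confusion),
       n = nrow(test))
}

#' Evaluate the classifier over train/test split fractions
#'
#' For each training fraction the table is stratified-split, a model is
#' trained and scored on the held-out part; every reported rate is the
#' mean over `repeats` seeded repetitions (split seed and training seed
#' both varied; seeds are logged in the report).
#'
#' @param table Feature table.
#' @param fractions Training fractions; default the 60/70/80/90% protocol.
#' @param config Base [train_config()]; its seed anchors the repeat seeds.
#' @param repeats Seeded repetitions per fraction; default 3.
#' @return Object of class `eval_report`: `data.frame` with columns
#'   `train_fraction`, `rate` (mean %), `rates` (per-repeat, as a list
#'   column), plus attributes `seeds` and `confusion` (summed over
#'   repeats, last fraction).
#' @export
evaluate_splits <- function(table, fractions = c(0.6, 0.7, 0.8, 0.9),
                            config = train_config(), repeats = 3L) {
  seeds <- config$seed + seq_len(repeats) - 1L
  rows <- list()
  confusions <- list()
  for (f in fractions) {
    rates <- numeric(repeats)
    conf <- NULL
    for (r in seq_len(repeats)) {
      sp <- stratified_split(table, f, seed = seeds[r])
      cfg <- config; cfg$seed <- seeds[r]
      model <- mlp_train(sp$train, cfg)
      sc <- success_rate(model, sp$test)
      rates[r] <- sc$rate
      conf <- if (is.null(conf)) sc$confusion else conf + sc$confusion
    }
    rows[[length(rows) + 1L]] <-
      data.frame(train_fraction = f, rate = mean(rates))
    rows[[length(rows)]]$rates <- I(list(rates))
    confusions[[as.character(f)]] <- conf
  }
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  attr(out, "confusion") <- confusions
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Split evaluation (mean success rate over",
      length(attr(x, "seeds")), "seeded repeats):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %2.0f/%2.0f : %6.2f %%\n",
                100 * x$train_fraction[i], 100 * (1 - x$train_fraction[i]),
                x$rate[i]))
  invisible(x)
}

#' Sweep the hidden-neuron count
#'
#' Trains one model per hidden-layer size under the same seed policy and
#' records the mean test success rate, optionally writing a CSV and a PNG
#' plot of rate against neuron count.
#'
#' @param table Feature table.
#' @param h_values Hidden-neuron counts to try.
#' @param config Base [train_config()].
#' @param train_fraction Split fraction; default 0.8.
#' @param repeats Seeded repeats per h; default 1.
#' @param csv,plot Optional output file paths.
#' @return `data.frame` with columns `hidden`, `rate`, `error` (NA or the
#'   training error message for that h; the sweep continues past failures).
#' @export
neuron_sweep <- function(table, h_values, config = train_config(),
                         train_fraction = 0.8, repeats = 1L,
                         csv = NULL, plot = NULL) {
  stopifnot(length(h_values) >= 1)
  res <- data.frame(hidden = as.integer(h_values), rate = NA_real_,
                    error = NA_character_)
  for (i in seq_along(h_values)) {
    rates <- numeric(0)
    err <- NA_character_
    for (r in seq_len(repeats)) {
      seed <- config$seed + r - 1L
      out <- tryCatch({
        sp <- stratified_split(table, train_fraction, seed = seed)
        cfg <- config; cfg$hidden <- as.integer(h_values[i]); cfg$seed <- seed
        success_rate(mlp_train(sp$train, cfg), sp$test)$rate
      }, error = function(e) conditionMessage(e))
      if (is.character(out)) err <- out else rates <- c(rates, out)
    }
    if (length(rates) > 0) res$rate[i] <- mean(rates)
    res$error[i] <- err
  }
  if (!is.null(csv)) utils::write.csv(res, csv, row.names = FALSE)
  if (!is.null(plot)) {
    grDevices::png(plot, width = 640, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    ok <- !is.na(res$rate)
    graphics::plot(res$hidden[ok], res$rate[ok], type = "b", pch = 19,
                   xlab = "hidden neurons", ylab = "success rate (%)",
                   main = "Success rate vs hidden-layer size")
  }
  res
}
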