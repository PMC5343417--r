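#' Specimen records: the unit of statistics and classification
#'
#' @param id character vector of specimen ids.
#' @param gender factor/character `"F"`/`"M"`.
#' @param side factor/character `"L"`/`"R"`.
#' @param coefficients numeric matrix (one row per specimen) of shape-model
#'   coefficients, or `NULL`.
#' @param morphometrics data.frame of per-plane morphometrics in the layout
#'   of [specimen_morphometrics()], or `NULL`.
#' @return an object of class `specimen_records`.
#' @export
specimen_records <- function(id, gender, side, coefficients = NULL,
                             morphometrics = NULL) {
  n <- length(id)
  stopifnot(length(gender) == n, length(side) == n)
  if (!is.null(coefficients)) {
    coefficients <- as.matrix(coefficients)
    stopifnot(nrow(coefficients) == n)
  }
  structure(list(id = as.character(id),
                 gender = factor(gender, levels = c("F", "M")),
                 side = factor(side, levels = c("L", "R")),
                 coefficients = coefficients,
                 morphometrics = morphometrics),
            class = "specimen_records")
}

#' @export
print.specimen_records <- function(x, ...) {
  cat(sprintf("specimen_records: %d specimens (%s)\n", length(x$id),
              paste(sprintf("%s=%d", names(table(paste0(x$gender, x$side))),
                            table(paste0(x$gender, x$side))), collapse = ", ")))
  if (!is.null(x$coefficients))
    cat(sprintf("  %d shape coefficients per specimen\n", ncol(x$coefficients)))
  invisible(x)
}

# feature matrix for classification
record_features <- function(records, features = c("coefficients",
                                                  "morphometrics")) {
  features <- match.arg(features)
  if (features == "coefficients") {
    if (is.null(records$coefficients)) stop("records carry no coefficients")
    x <- records$coefficients
  } else {
    if (is.null(records$morphometrics)) stop("records carry no morphometrics")
    mm <- records$morphometrics
    wide <- stats::reshape(
      mm[, c("id", "plane", "width", "depth", "perimeter", "area")],
      idvar = "id", timevar = "plane", direction = "wide")
    x <- as.matrix(wide[match(records$id, wide$id), -1, drop = FALSE])
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Leave-one-out random-forest classification
#'
#' For every iteration a complete leave-one-out sweep is run: each specimen
#' is predicted by a random forest (default 50 trees) trained on all other
#' specimens, and the sweep's fraction of correct predictions is one
#' accuracy value.  Iterations differ only in the forest's internal
#' randomness (LOOCV itself has no sampling freedom), which makes a
#' median over iterations meaningful.  Deterministic under `seed`.
#'
#' @param records a [specimen_records()] object.
#' @param label `"side"` or `"gender"`.
#' @param n_trees trees per forest.
#' @param n_iterations number of repeated LOOCV sweeps.
#' @param seed integer seed.
#' @param features classify from shape-model `"coefficients"` (default) or
#'   per-plane `"morphometrics"`.
#' @return an [accuracy_summary()].
#' @export
loocv_random_forest <- function(records, label = c("side", "gender"),
                                n_trees = 50L, n_iterations = 100L,
                                seed = 1L,
                                features = c("coefficients", "morphometrics")) {
  label <- match.arg(label)
  y <- droplevels(records[[label]])
  if (nlevels(y) < 2L) stop("need at least two classes to classify")
  if (min(table(y)) < 2L) stop("need at least 2 specimens per class")
  x <- record_features(records, features)
  n <- length(y)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  acc <- numeric(n_iterations)
  conf <- table(truth = y, predicted = y) * 0L
  prob_correct <- matrix(NA_real_, n_iterations, n)
  for (it in seq_len(n_iterations)) {
    set.seed(as.integer(seed) + it - 1L)
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    for (i in seq_len(n)) {
      fit <- randomForest::randomForest(x[-i, , drop = FALSE], y[-i],
                                        ntree = n_trees)
      pred[i] <- stats::predict(fit, x[i, , drop = FALSE])
      pr <- stats::predict(fit, x[i, , drop = FALSE], type = "prob")
      prob_correct[it, i] <- pr[1, as.character(y[i])]
    }
    acc[it] <- mean(pred == y)
    conf <- conf + table(truth = y, predicted = pred)
  }
  accuracy_summary(acc, conf, seed = seed, label = label,
                   prob_correct = prob_correct)
}

#' Step-wise side-then-gender classification
#'
#' Per held-out specimen, the side is predicted first by a side classifier
#' trained on the remaining specimens; the gender is then predicted by a
#' gender classifier trained on the remaining specimens of the *predicted*
#' side.  A combined prediction is successful only if both labels are
#' correct.
#'
#' @inheritParams loocv_random_forest
#' @return an [accuracy_summary()] of the combined accuracy.
#' @export
stepwise_side_then_gender <- function(records, n_trees = 50L,
                                      n_iterations = 100L, seed = 1L,
                                      features = c("coefficients",
                                                   "morphometrics")) {
  y_side <- records$side
  y_gen <- records$gender
  if (nlevels(droplevels(y_side)) < 2L || nlevels(droplevels(y_gen)) < 2L)
    stop("need both sides and both genders represented")
  x <- record_features(records, features)
  n <- length(y_side)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  acc <- numeric(n_iterations)
  lv <- c("FL", "FR", "ML", "MR")
  truth_comb <- factor(paste0(y_gen, y_side), levels = lv)
  conf <- table(truth = truth_comb, predicted = truth_comb) * 0L
  for (it in seq_len(n_iterations)) {
    set.seed(as.integer(seed) + it - 1L)
    ok <- logical(n)
    pred_comb <- factor(rep(NA_character_, n), levels = lv)
    for (i in seq_len(n)) {
      fit_s <- randomForest::randomForest(x[-i, , drop = FALSE], y_side[-i],
                                          ntree = n_trees)
      ps <- as.character(stats::predict(fit_s, x[i, , drop = FALSE]))
      stratum <- setdiff(which(y_side == ps), i)
      yg <- droplevels(y_gen[stratum])
      if (nlevels(yg) < 2L)
        stop(sprintf(
          "predicted-side stratum '%s' contains a single gender class", ps))
      fit_g <- randomForest::randomForest(x[stratum, , drop = FALSE],
                                          y_gen[stratum], ntree = n_trees)
      pg <- as.character(stats::predict(fit_g, x[i, , drop = FALSE]))
      ok[i] <- (ps == as.character(y_side[i])) && (pg == as.character(y_gen[i]))
      pred_comb[i] <- paste0(pg, ps)
    }
    acc[it] <- mean(ok)
    conf <- conf + table(truth = truth_comb, predicted = pred_comb)
  }
  accuracy_summary(acc, conf, seed = seed, label = "side+gender")
}

#' Accuracy summary of repeated LOOCV sweeps
#'
#' @param per_iteration numeric vector of per-iteration accuracy fractions.
#' @param confusion confusion table summed over iterations.
#' @param seed seed used.
#' @param label what was classified.
#' @param prob_correct optional iteration x specimen matrix of the
#'   predicted probability of the true class (secondary reading of
#'   "classification probability").
#' @return an object of class `accuracy_summary` with the median accuracy
#'   in `$median`.
#' @export
accuracy_summary <- function(per_iteration, confusion = NULL, seed = NA,
                             label = "", prob_correct = NULL) {
  stopifnot(all(per_iteration >= 0 & per_iteration <= 1))
  structure(list(per_iteration = per_iteration,
                 median = stats::median(per_iteration),
                 confusion = confusion,
                 n_iterations = length(per_iteration),
                 seed = seed, label = label,
                 prob_correct = prob_correct),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf(
    "LOOCV %s: median accuracy %.1f%% over %d iterations (range %.1f-%.1f%%)\n",
    x$label, 100 * x$median, x$n_iterations, 100 * min(x$per_iteration),
    100 * max(x$per_iteration)))
  if (!is.null(x$confusion)) {
    cat("confusion (summed over iterations):\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Export a classification result as JSON + CSV
#'
#' @param summary an [accuracy_summary()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, the summary.
#' @export
write_accuracy <- function(summary, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(label = summary$label, median = summary$median,
           n_iterations = summary$n_iterations, seed = summary$seed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(iteration = seq_along(summary$per_iteration),
                                accuracy = summary$per_iteration),
                     csv_path, row.names = FALSE)
  }
  invisible(summary)
}
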