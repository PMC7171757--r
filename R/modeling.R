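#' Tune random survival forest hyperparameters
#'
#' Grid search with k-fold cross-validation on the training set. Folds are
#' stratified by the event indicator; if a fold ends up with no event (only
#' possible with very few events), the folds are redrawn with a fresh child
#' seed and the refold is counted. The winner is the grid point with the
#' highest mean out-of-fold Harrell C-index; the full score table is kept
#' for audit.
#'
#' @param table feature table restricted to the model's features.
#' @param outcomes single-endpoint outcome table.
#' @param grid data frame with columns `mtry`, `min_node_size` (and
#'   optionally `num_trees`); default grid spans mtry in
#'   {sqrt(p), p/3, p} and node sizes {3, 6, 15}.
#' @param n_folds number of CV folds (>= 2).
#' @param num_trees trees per forest during tuning.
#' @param seed integer seed.
#' @return list with `best` (one-row data frame), `scores` (grid with mean
#'   CV C-index) and `n_refolds`.
#' @export
tune_rsf <- function(table, outcomes, grid = NULL, n_folds = 5L,
                     num_trees = 500L, seed = 1L) {
  prep <- align_outcomes(table, outcomes)
  p <- ncol(prep$x)
  if (is.null(grid))
    grid <- expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), p))),
      min_node_size = c(3L, 6L, 15L))
  stopifnot(nrow(grid) >= 1L, n_folds >= 2L)
  seeds <- child_seeds(seed, c(paste0("fold_", 1:50), "forest"))
  folds <- NULL
  n_refolds <- 0L
  for (attempt in 1:50) {
    set.seed(seeds[[paste0("fold_", attempt)]])
    folds <- stratified_folds(prep$event, n_folds)
    ok <- all(vapply(seq_len(n_folds), function(f)
      sum(prep$event[folds != f]) > 0 && sum(prep$event[folds == f]) >= 0,
      TRUE))
    if (ok) break
    n_refolds <- n_refolds + 1L
  }
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cs <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      model <- fit_rsf(table[tr, , drop = FALSE],
                       subset_outcomes(outcomes, table$patient_id[tr]),
                       hyperparameters = list(
                         mtry = grid$mtry[g],
                         min_node_size = grid$min_node_size[g],
                         num_trees = grid$num_trees[g] %||% num_trees),
                       seed = seeds[["forest"]])
      risk <- predict_risk(model, table[!tr, , drop = FALSE])
      cs[f] <- harrell_cindex(risk, prep$time[!tr], prep$event[!tr])
    }
    scores[g] <- mean(cs, na.rm = TRUE)
  }
  best <- which.max(scores)
  list(best = grid[best, , drop = FALSE],
       scores = cbind(grid, cv_cindex = scores),
       n_refolds = n_refolds)
}

stratified_folds <- function(event, n_folds) {
  folds <- integer(length(event))
  for (v in unique(event)) {
    idx <- which(event == v)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

subset_outcomes <- function(outcomes, ids) {
  outcomes[outcomes$patient_id %in% ids, , drop = FALSE]
}

#' Fit a random survival forest risk model
#'
#' Grows a forest of survival trees with log-rank splitting (ranger) and
#' predicts a scalar risk per patient as the ensemble mortality: the sum
#' over the unique training event times of the ensemble cumulative hazard.
#' Higher risk means predicted worse outcome. Missing feature values are
#' median-imputed with training-set medians, which the model stores and
#' reuses at prediction time.
#'
#' @inheritParams tune_rsf
#' @param hyperparameters list with `mtry`, `min_node_size`, `num_trees`.
#' @param endpoint endpoint label carried in the model.
#' @param seed integer seed for forest randomness.
#' @return A `risk_model`.
#' @export
fit_rsf <- function(table, outcomes,
                    hyperparameters = list(mtry = NULL, min_node_size = 3L,
                                           num_trees = 1000L),
                    endpoint = outcomes$endpoint[1] %||% "OS", seed = 1L) {
  prep <- align_outcomes(table, outcomes)
  if (sum(prep$event) == 0)
    stop("cannot fit a survival forest with no events")
  feat <- setdiff(names(table), "patient_id")
  medians <- vapply(table[feat], function(x) median(x, na.rm = TRUE), 0)
  df <- impute_with(table[feat], medians)
  df$..time <- prep$time
  df$..event <- prep$event
  rf <- ranger::ranger(
    survival::Surv(..time, ..event) ~ ., data = df,
    num.trees = hyperparameters$num_trees %||% 1000L,
    mtry = hyperparameters$mtry %||% max(1L, floor(sqrt(length(feat)))),
    min.node.size = hyperparameters$min_node_size %||% 3L,
    splitrule = "logrank",
    seed = seed, num.threads = 1L)
  structure(list(forest = rf, features = feat, medians = medians,
                 hyperparameters = hyperparameters, endpoint = endpoint,
                 seed = seed),
            class = "risk_model")
}

impute_with <- function(df, medians) {
  for (f in names(df)) {
    miss <- is.na(df[[f]])
    if (any(miss)) df[[f]][miss] <- medians[[f]]
  }
  df
}

#' @rdname fit_rsf
#' @param model a `risk_model`.
#' @return `predict_risk()`: named numeric vector of ensemble-mortality
#'   risks (one per row of `table`).
#' @export
predict_risk <- function(model, table) {
  stopifnot(inherits(model, "risk_model"))
  missing_feat <- setdiff(model$features, names(table))
  if (length(missing_feat))
    stop("model feature(s) absent from table: ",
         paste(missing_feat, collapse = ", "))
  df <- impute_with(table[model$features], model$medians)
  pred <- stats::predict(model$forest, data = df, num.threads = 1L)
  risk <- rowSums(pred$chf)
  names(risk) <- table$patient_id %||% NULL
  risk
}
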