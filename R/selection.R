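#' Rank features by one penalized Cox fit
#'
#' Fits a penalized proportional-hazards model (glmnet) with the penalty
#' strength chosen by internal cross-validation of the partial likelihood,
#' and orders features by decreasing absolute coefficient. Inputs are
#' standardized column-wise before fitting so coefficient magnitudes are
#' comparable. For lasso and elastic-net (mixing parameter 0.5), features
#' with zero coefficients rank below all non-zero ones, ordered
#' lexicographically among themselves.
#'
#' @param table feature table (numeric columns plus `patient_id`).
#' @param outcomes outcome table with `patient_id`, `time_months`, `event`
#'   (a single endpoint).
#' @param penalty one of `"ridge"`, `"lasso"`, `"elastic_net"`.
#' @param nfolds internal CV folds for the penalty strength.
#' @param nlambda length of the penalty-strength grid.
#' @return Character vector of feature names, best first.
#' @export
rank_once <- function(table, outcomes,
                      penalty = c("ridge", "lasso", "elastic_net"),
                      nfolds = 5L, nlambda = 50L) {
  penalty <- match.arg(penalty)
  alpha <- switch(penalty, ridge = 0, lasso = 1, elastic_net = 0.5)
  prep <- align_outcomes(table, outcomes)
  x <- scale(prep$x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  y <- survival::Surv(prep$time, prep$event)
  fit <- tryCatch(
    glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha, nfolds = nfolds,
                      nlambda = nlambda),
    error = function(e)
      stop("penalized Cox fit failed (penalty = ", penalty, "): ",
           conditionMessage(e)))
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  nm <- colnames(x)
  nonzero <- beta != 0
  ranked <- c(nm[nonzero][order(-abs(beta[nonzero]), nm[nonzero])],
              sort(nm[!nonzero]))
  ranked
}

# match a single-endpoint outcome table to feature-table rows by patient_id
align_outcomes <- function(table, outcomes) {
  stopifnot(all(c("patient_id", "time_months", "event") %in% names(outcomes)))
  idx <- match(table$patient_id, outcomes$patient_id)
  if (anyNA(idx))
    stop("outcomes missing for patient(s): ",
         paste(table$patient_id[is.na(idx)], collapse = ", "))
  feat <- setdiff(names(table), "patient_id")
  list(x = as.matrix(table[, feat, drop = FALSE]),
       time = outcomes$time_months[idx],
       event = outcomes$event[idx])
}

#' Bootstrap-aggregated feature ranking
#'
#' Repeats penalized-Cox ranking on `n_boot` bootstrap resamples of the
#' training table (sampled with replacement at the training size; resamples
#' without any event are redrawn and logged). Each resample contributes one
#' top-`top_k` list per penalty; all collected lists are aggregated by the
#' simple ensemble method: a feature's score is its mean rank across lists,
#' where a feature absent from a list is assigned rank `top_k + 1`. The
#' consensus ordering is by ascending mean rank, ties broken
#' lexicographically.
#'
#' @inheritParams rank_once
#' @param n_boot number of bootstrap resamples (default 100).
#' @param top_k list length retained per fit (default 10).
#' @param penalties penalties pooled into the aggregation.
#' @param seed integer seed for the resampling stream.
#' @return A `ranked_features` object: data frame (`feature`, `mean_rank`,
#'   `selection_freq`) ordered by consensus rank, with provenance attached.
#' @export
bootstrap_select <- function(table, outcomes, n_boot = 100L, top_k = 10L,
                             penalties = c("ridge", "lasso", "elastic_net"),
                             seed = 1L) {
  stopifnot(n_boot >= 1L)
  feat <- sort(setdiff(names(table), "patient_id"))
  if (top_k > length(feat))
    stop("'top_k' exceeds the number of features")
  n <- nrow(table)
  prep <- align_outcomes(table, outcomes)
  if (sum(prep$event) == 0) stop("no events in the training outcomes")
  seeds <- child_seeds(seed, c("resample", paste0("fit_", seq_len(n_boot))))
  set.seed(seeds[["resample"]])
  lists <- list()
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(prep$event[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    boot_tab <- table[idx, , drop = FALSE]
    boot_tab$patient_id <- sprintf("B%05d", seq_len(n))
    boot_out <- data.frame(patient_id = boot_tab$patient_id,
                           time_months = prep$time[idx],
                           event = prep$event[idx])
    set.seed(seeds[[paste0("fit_", b)]])
    for (pen in penalties)
      lists[[length(lists) + 1L]] <-
        head(rank_once(boot_tab, boot_out, pen), top_k)
  }
  scores <- vapply(feat, function(f) {
    mean(vapply(lists, function(l) {
      r <- match(f, l)
      if (is.na(r)) top_k + 1 else r
    }, 0))
  }, 0)
  freq <- vapply(feat, function(f)
    mean(vapply(lists, function(l) f %in% l, TRUE)), 0)
  ord <- order(scores, feat)
  out <- data.frame(feature = feat[ord], mean_rank = scores[ord],
                    selection_freq = freq[ord], row.names = NULL)
  structure(out, class = c("ranked_features", "data.frame"),
            provenance = list(n_boot = n_boot, top_k = top_k,
                              penalties = penalties, seed = seed,
                              n_redrawn = n_redrawn))
}

#' @rdname bootstrap_select
#' @param ranked a `ranked_features` object (or any data frame with a
#'   `feature` column ordered best-first).
#' @param k number of top features to keep.
#' @return `take_top()`: character vector of the `k` best-ranked features.
#' @export
take_top <- function(ranked, k) {
  if (k < 1L) stop("'k' must be >= 1")
  if (k > nrow(ranked)) stop("'k' exceeds the number of ranked features")
  ranked$feature[seq_len(k)]
}
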