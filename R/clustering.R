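#' Spearman correlation matrix of a feature table
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between all
#' feature columns. Columns that are constant (after dropping missing
#' values) have undefined rank correlation and must be removed first;
#' [prepare_feature_matrix()] applies the standard preparation: drop
#' features missing in more than `max_missing` of patients, median-impute
#' the remainder, drop constant columns.
#'
#' @param table feature table (data frame with `patient_id` plus feature
#'   columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "patient_id"), drop = FALSE])
  if (nrow(m) < 3L) stop("need at least 3 patients for rank correlations")
  cst <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE) == 0 ||
                 all(is.na(x)))
  if (any(cst))
    stop("constant feature column(s): ",
         paste(colnames(m)[cst], collapse = ", "))
  cor(m, method = "spearman", use = "pairwise.complete.obs")
}

#' @rdname spearman_matrix
#' @param max_missing features missing in more than this fraction of
#'   patients are dropped.
#' @param medians optional named medians to impute with (training-set
#'   medians when preparing a validation table); computed from `table` when
#'   `NULL`.
#' @return `prepare_feature_matrix()`: list with the cleaned `table`, the
#'   `medians` used and the names of `dropped` columns.
#' @export
prepare_feature_matrix <- function(table, max_missing = 0.2, medians = NULL) {
  feat <- setdiff(names(table), "patient_id")
  frac_na <- vapply(table[feat], function(x) mean(is.na(x)), 0)
  drop_na <- feat[frac_na > max_missing]
  feat <- setdiff(feat, drop_na)
  if (is.null(medians))
    medians <- vapply(table[feat], function(x) median(x, na.rm = TRUE), 0)
  for (f in feat) {
    miss <- is.na(table[[f]])
    if (any(miss)) table[[f]][miss] <- medians[[f]]
  }
  cst <- feat[vapply(table[feat], function(x) var(x) == 0, TRUE)]
  keep <- setdiff(feat, cst)
  list(table = table[, c("patient_id", keep), drop = FALSE],
       medians = medians[keep], dropped = c(drop_na, cst))
}

#' Cluster highly correlated features
#'
#' Agglomerative clustering with distance `1 - |SC|` and average linkage;
#' the tree is cut at height `1 - threshold`, so features whose cluster-wise
#' average absolute Spearman correlation exceeds the threshold end up
#' together. The absolute value is used because negatively correlated
#' features belong to the same cluster (they are sign-inverted before
#' averaging). For each cluster an anchor is chosen (the member with the
#' highest mean |SC| to the other members, ties lexicographic) and each
#' member gets the sign of its correlation with the anchor; members nearly
#' uncorrelated with the anchor (|SC| < 0.1) are flagged with a warning and
#' assigned +1. Feature names are processed in lexicographic order, making
#' the clustering deterministic given the matrix.
#'
#' @param mat Spearman correlation matrix from [spearman_matrix()].
#' @param threshold absolute-correlation threshold (default 0.90).
#' @return A `cluster_map`: list of clusters (members, signs, anchor) plus
#'   the threshold.
#' @export
cluster_features <- function(mat, threshold = 0.90) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  ord <- order(colnames(mat))
  mat <- mat[ord, ord]
  nm <- colnames(mat)
  if (nrow(mat) == 1L) {
    grp <- setNames(1L, nm)
  } else {
    d <- stats::as.dist(1 - abs(mat))
    hc <- hclust(d, method = "average")
    grp <- cutree(hc, h = 1 - threshold)
  }
  clusters <- lapply(sort(unique(grp)), function(g) {
    members <- sort(nm[grp == g])
    if (length(members) == 1L)
      return(list(members = members, signs = setNames(1, members),
                  anchor = members))
    sub <- mat[members, members, drop = FALSE]
    mean_abs <- (rowSums(abs(sub)) - 1) / (length(members) - 1)
    anchor <- members[order(-mean_abs, members)][1]
    signs <- sign(sub[, anchor])
    weak <- abs(sub[, anchor]) < 0.1
    if (any(weak & members != anchor)) {
      warning("sign ambiguity for member(s) ",
              paste(members[weak & members != anchor], collapse = ", "),
              " (|SC| to anchor < 0.1); using sign +1")
      signs[weak] <- 1
    }
    signs[signs == 0] <- 1
    list(members = members, signs = signs, anchor = anchor)
  })
  structure(list(clusters = clusters, threshold = threshold, scaling = NULL),
            class = "cluster_map")
}

#' Replace feature clusters by their averaged representative
#'
#' Each multi-member cluster is replaced by one representative column, named
#' after its anchor: members are z-scored (zero mean, unit variance),
#' sign-aligned with the anchor (negatively correlated members multiplied by
#' -1) and averaged. Singleton clusters pass through on their original
#' scale. The member means and standard deviations are taken from the table
#' the map was first applied to (the training split) and reused when the map
#' is applied again, so a validation table is reduced with frozen training
#' statistics.
#'
#' @param table feature table whose columns the map covers.
#' @param cmap a [cluster_features()] map.
#' @return List with the reduced `table` and the updated `cmap` (carrying
#'   the scaling statistics).
#' @export
reduce_table <- function(table, cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  feat <- setdiff(names(table), "patient_id")
  members_all <- sort(unlist(lapply(cmap$clusters, `[[`, "members")))
  if (!setequal(members_all, feat))
    stop("cluster map does not cover the table's feature columns")
  if (is.null(cmap$scaling)) {
    scale_members <- unlist(lapply(cmap$clusters, function(cl)
      if (length(cl$members) > 1L) cl$members else character(0)))
    cmap$scaling <- list(
      center = vapply(table[scale_members], mean, 0),
      scale = vapply(table[scale_members], sd, 0))
    cmap$scaling$scale[cmap$scaling$scale == 0] <- 1
  }
  cols <- lapply(cmap$clusters, function(cl) {
    if (length(cl$members) == 1L)
      return(setNames(list(table[[cl$members]]), cl$members))
    z <- vapply(cl$members, function(f)
      cl$signs[[f]] * (table[[f]] - cmap$scaling$center[[f]]) /
        cmap$scaling$scale[[f]], numeric(nrow(table)))
    setNames(list(rowMeans(z)), cl$anchor)
  })
  cols <- unlist(cols, recursive = FALSE)
  out <- data.frame(patient_id = table$patient_id, cols,
                    check.names = FALSE, row.names = NULL)
  list(table = out, cmap = cmap)
}

#' Iterate the cluster-and-average reduction to a fixed point
#'
#' One cluster-and-average pass groups the original features correctly, but
#' the averaged representatives are new variables and an occasional pair of
#' them can still exceed the correlation threshold. `reduce_until_stable()`
#' therefore repeats the pass on its own output until no off-diagonal
#' |Spearman| exceeds the threshold (usually 1-2 passes), which makes the
#' post-reduction audit hold by construction. The ordered list of maps (with
#' their frozen scaling statistics) is returned so the identical composed
#' reduction can be applied to a validation table via `apply_reduction()`.
#'
#' @inheritParams reduce_table
#' @param threshold absolute Spearman threshold.
#' @param max_iter safety bound on the number of passes.
#' @return list with the reduced `table` and the list of `maps` applied.
#' @export
reduce_until_stable <- function(table, threshold = 0.90, max_iter = 10L) {
  maps <- list()
  for (it in seq_len(max_iter)) {
    if (ncol(table) <= 2L) break
    m <- spearman_matrix(table)
    off <- abs(m); diag(off) <- 0
    if (max(off) <= threshold) break
    cmap <- cluster_features(m, threshold)
    red <- reduce_table(table, cmap)
    table <- red$table
    maps[[length(maps) + 1L]] <- red$cmap
  }
  list(table = table, maps = maps)
}

#' @rdname reduce_until_stable
#' @param maps list of frozen cluster maps from `reduce_until_stable()`.
#' @export
apply_reduction <- function(table, maps) {
  for (cmap in maps) table <- reduce_table(table, cmap)$table
  table
}

#' @rdname reduce_table
#' @param path JSON path for serializing a cluster map.
#' @export
write_cluster_map <- function(cmap, path) {
  jsonlite::write_json(
    list(threshold = cmap$threshold,
         clusters = lapply(cmap$clusters, function(cl)
           list(members = cl$members, signs = as.numeric(cl$signs),
                anchor = cl$anchor))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
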