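# Spearman matrix, hierarchical clustering at |SC| > 0.90, reduction.

test_that("spearman matrix is rank-based, symmetric, tie-aware", {
  set.seed(10)
  x <- rnorm(30)
  tab <- data.frame(patient_id = as.character(1:30),
                    a = x, b = exp(x), c = -x, d = rnorm(30),
                    check.names = FALSE)
  m <- spearman_matrix(tab)
  expect_equal(m["a", "b"], 1)                  # monotone transform
  expect_equal(m["a", "c"], -1)                 # negation
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))

  # 5-point hand computation: ranks of y = (1,2,3,5,4) against x = 1..5
  # rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 6*2/120 = 0.9
  tab5 <- data.frame(patient_id = as.character(1:5),
                     x = 1:5, y = c(1, 2, 3, 5, 4), check.names = FALSE)
  expect_equal(spearman_matrix(tab5)["x", "y"], 0.9)

  expect_error(spearman_matrix(data.frame(patient_id = as.character(1:5),
                                          k = rep(1, 5), z = rnorm(5))),
               "constant")
})

test_that("features above the threshold cluster together; others stay apart", {
  # three mutually |SC| ~ 0.95 features plus two weakly related ones
  set.seed(4)
  n <- 200
  base <- rnorm(n)
  mix <- function(w) w * base + sqrt(1 - w^2) * rnorm(n)
  tab <- data.frame(patient_id = as.character(1:n),
                    f1 = base, f2 = mix(0.985), f3 = -mix(0.985),
                    g1 = rnorm(n), g2 = rnorm(n), check.names = FALSE)
  m <- spearman_matrix(tab)
  cm <- cluster_features(m, 0.90)
  sizes <- sort(vapply(cm$clusters, function(cl) length(cl$members), 0L))
  expect_equal(sizes, c(1L, 1L, 3L))
  trio <- cm$clusters[[which(vapply(cm$clusters, function(cl)
    length(cl$members), 0L) == 3L)]]
  expect_setequal(trio$members, c("f1", "f2", "f3"))
  expect_equal(unname(trio$signs["f3"]), -1)    # anticorrelated member

  # all weak correlations: all singletons
  tab2 <- data.frame(patient_id = as.character(1:n),
                     a = rnorm(n), b = rnorm(n), c = rnorm(n),
                     check.names = FALSE)
  cm2 <- cluster_features(spearman_matrix(tab2), 0.90)
  expect_true(all(vapply(cm2$clusters, function(cl)
    length(cl$members), 0L) == 1L))
})

test_that("reduction inverts negative members and freezes training scaling", {
  set.seed(5)
  n <- 100
  f <- rnorm(n)
  tab <- data.frame(patient_id = as.character(1:n), f = f, g = -f,
                    check.names = FALSE)
  cm <- cluster_features(spearman_matrix(tab), 0.90)
  red <- reduce_table(tab, cm)
  expect_equal(ncol(red$table), 2)              # patient_id + 1 representative
  rep_col <- red$table[[2]]
  expect_equal(abs(cor(rep_col, f, method = "spearman")), 1)

  # two identical features: representative equals their common z-score
  tab2 <- data.frame(patient_id = as.character(1:n), a = f, b = f,
                     check.names = FALSE)
  red2 <- reduce_table(tab2, cluster_features(spearman_matrix(tab2), 0.9))
  expect_equal(red2$table[[2]], (f - mean(f)) / sd(f), tolerance = 1e-12)

  # frozen scaling: applying the fitted map to new data reuses training stats
  new_tab <- data.frame(patient_id = as.character(1:n), a = f + 10, b = f + 10,
                        check.names = FALSE)
  red_new <- reduce_table(new_tab, red2$cmap)
  expect_equal(red_new$table[[2]], (f + 10 - mean(f)) / sd(f),
               tolerance = 1e-12)
})

test_that("iterated reduction reaches the no-high-correlation fixed point", {
  coh <- generate_cohort(small_cohort_spec(45, seed = 13))
  tab <- structure_columns(extract_cohort(coh), "tumor")
  prep <- prepare_feature_matrix(tab)
  red <- reduce_until_stable(prep$table, 0.90)
  expect_lt(ncol(red$table), ncol(prep$table))  # strictly fewer than 86
  m <- abs(spearman_matrix(red$table))
  diag(m) <- 0
  expect_lte(max(m), 0.90)

  # idempotence: a second pass only yields singletons
  again <- reduce_until_stable(red$table, 0.90)
  expect_identical(again$table, red$table)
  expect_length(again$maps, 0)

  # determinism given the table
  red2 <- reduce_until_stable(prep$table, 0.90)
  expect_identical(red$table, red2$table)
})
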