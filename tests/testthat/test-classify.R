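test_that("the N/10 feature budget follows the floor rule", {
  expect_identical(kmax(42 + 38), 8L)
  expect_identical(kmax(42 + 32), 7L)
  expect_identical(kmax(38 + 32), 7L)
  expect_identical(kmax(10), 1L)
  expect_error(kmax(9), "N/10")
})

test_that("T ranking puts an implanted feature first almost always", {
  ## one feature separated by 1.0 SD among 99 pure-noise features, 40
  ## subjects per class: the implanted feature must rank first in at
  ## least 95% of draws
  n_draws <- 100L
  first <- 0L
  in_top5 <- 0L
  set.seed(101)
  for (i in seq_len(n_draws)) {
    y <- rep(c("a", "b"), each = 40)
    X <- matrix(stats::rnorm(80 * 100), 80, 100)
    X[y == "b", 7] <- X[y == "b", 7] + 1.0
    sel <- select_features(X, y, 5)
    if (sel[1] == 7L) first <- first + 1L
    if (7L %in% sel) in_top5 <- in_top5 + 1L
  }
  ## at this signal-to-noise the implanted feature wins the selection set
  ## essentially always and tops the ranking in the clear majority of draws
  expect_gte(in_top5 / n_draws, 0.95)
  expect_gte(first / n_draws, 0.80)
})

test_that("T ranking breaks ties and degeneracies deterministically", {
  X <- matrix(1, 8, 5)       # all features constant: every T undefined
  y <- rep(c("a", "b"), 4)
  sel <- select_features(X, y, 5)
  expect_identical(as.integer(sel), 1:5)
  expect_equal(attr(sel, "n_undefined"), 5L)
  ## K = feature count returns all features in rank order
  set.seed(2)
  X2 <- matrix(stats::rnorm(16 * 3), 16, 3)
  sel2 <- select_features(X2, rep(c("a", "b"), 8), 3)
  expect_setequal(as.integer(sel2), 1:3)
  expect_error(select_features(X2, rep(c("a", "b"), 8), 4), "exceeds")
  expect_error(select_features(X2, rep("a", 16), 1), "classes")
})

test_that("the default grid spans 7 C values by 10 gamma values", {
  g <- svm_grid()
  expect_equal(nrow(g), 70L)
  expect_equal(sort(unique(g$C)), 10^(-1:5))
  expect_equal(sort(unique(g$gamma)), 2^(-5:4))
  expect_error(svm_grid(C_values = c(-1, 1)), "positive")
})

test_that("stratified holdout balances training and covers all subjects", {
  labels <- rep(c("NC", "sd"), c(42, 38))
  plan <- rhst_splits(labels, n_reps = 50L, seed = 3L)
  expect_equal(plan$train_per_class, 19L)
  for (sp in plan$repetitions) {
    expect_equal(length(sp$train), 38L)
    expect_equal(length(sp$test), 42L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
    ## exactly train_per_class per class, even under 2:1-style imbalance
    expect_true(all(table(labels[sp$train]) == 19L))
  }
  tiny <- rhst_splits(rep(c("a", "b"), each = 4), n_reps = 5L, seed = 1L)
  expect_equal(tiny$train_per_class, 2L)
  expect_equal(length(tiny$repetitions[[1]]$test), 4L)
  expect_error(rhst_splits(rep(c("a", "b"), each = 4), train_fraction = 0),
               "train_fraction")
  expect_error(rhst_splits(c("a", "a", "b"), seed = 1), ">= 2")
})

test_that("repetitions are essentially always distinct at study sizes", {
  labels <- rep(c("NC", "md"), c(42, 32))
  plan <- rhst_splits(labels, n_reps = 100L, seed = 9L)
  keys <- vapply(plan$repetitions, function(sp)
    paste(sp$train, collapse = ","), "")
  expect_equal(length(unique(keys)), 100L)
})

test_that("a strong implanted signal yields near-perfect AUC", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 25L, B = 25L),
                        effect_spec = list(list(label = 3L, class = "B",
                                                thinning = 1.2)),
                        subject_sd = 0.1, vertex_sd = 0.2, seed = 14L)
  patches <- make_patches(am$mesh, am$atlas, k = 5L, seed = 1L)
  fm <- patch_means(co, patches)
  splits <- rhst_splits(co$diagnosis, n_reps = 25L, seed = 4L)
  grid <- svm_grid(C_values = c(1, 100), gamma_values = c(0.03125, 0.5))
  ex <- run_experiment(fm, co$diagnosis, grid, splits)
  expect_gte(select_best(ex)$metrics["AUC", "mean"], 0.95)
})

test_that("permuted labels drive the mean AUC to chance", {
  ## a single permutation leaves cohort-level chance structure that all
  ## repetitions share, so calibration is judged across permutations:
  ## the grand mean AUC over several relabelings must sit within 3
  ## standard errors of 0.5
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 25L, B = 25L),
                        effect_spec = list(list(label = 3L, class = "B",
                                                thinning = 1.0)),
                        seed = 15L)
  patches <- make_patches(am$mesh, am$atlas, k = 5L, seed = 1L)
  fm <- patch_means(co, patches)
  set.seed(77)
  perm_means <- vapply(1:8, function(i) {
    y_perm <- sample(co$diagnosis)
    splits <- rhst_splits(y_perm, n_reps = 15L, seed = 5L + i)
    ex <- run_experiment(fm, y_perm, svm_grid(C_values = 1,
                                              gamma_values = 0.125), splits)
    mean(ex$auc[ex$valid, 1])
  }, 0)
  se <- stats::sd(perm_means) / sqrt(length(perm_means))
  expect_lt(abs(mean(perm_means) - 0.5), 3 * se)
})

test_that("a single repetition is bit-reproducible", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 15L, B = 15L), seed = 16L)
  patches <- make_patches(am$mesh, am$atlas, k = 3L, seed = 1L)
  fm <- patch_means(co, patches)
  splits <- rhst_splits(co$diagnosis, n_reps = 3L, seed = 8L)
  grid <- svm_grid(C_values = 1, gamma_values = c(0.125, 1))
  e1 <- run_experiment(fm, co$diagnosis, grid, splits)
  e2 <- run_experiment(fm, co$diagnosis, grid, splits)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$auc, e2$auc)
})

test_that("best-combo selection matches a brute-force recomputation", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 20L, B = 20L),
                        effect_spec = list(list(label = 1L, class = "B",
                                                thinning = 0.5)),
                        seed = 19L)
  patches <- make_patches(am$mesh, am$atlas, k = 4L, seed = 1L)
  fm <- patch_means(co, patches)
  splits <- rhst_splits(co$diagnosis, n_reps = 15L, seed = 2L)
  grid <- svm_grid(C_values = c(0.1, 1, 10), gamma_values = c(0.125, 0.5))
  ex <- run_experiment(fm, co$diagnosis, grid, splits)
  best <- select_best(ex)
  brute <- colMeans(ex$auc[ex$valid, , drop = FALSE], na.rm = TRUE)
  expect_equal(unname(best$metrics["AUC", "mean"]), max(brute),
               tolerance = 1e-12)
  expect_equal(best$combo, which.max(brute))
})

test_that("exact mean-AUC ties resolve to smaller C then smaller gamma", {
  fake <- structure(list(
    grid = data.frame(C = c(10, 0.1, 0.1), gamma = c(0.5, 2, 0.25)),
    auc = matrix(c(0.6, 0.7, 0.7, 0.6, 0.7, 0.7), 2, 3, byrow = TRUE),
    acc = matrix(0.5, 2, 3), spec = matrix(0.5, 2, 3),
    sens = matrix(0.5, 2, 3), valid = c(TRUE, TRUE)),
    class = "rhst_experiment")
  best <- select_best(fake)
  expect_equal(best$C, 0.1)
  expect_equal(best$gamma, 0.25)
})

test_that("mean AUC does not decrease with implanted effect size", {
  am <- fx_atlas_small()
  patches <- make_patches(am$mesh, am$atlas, k = 4L, seed = 1L)
  grid <- svm_grid(C_values = c(1, 10), gamma_values = c(0.0625, 0.25))
  res <- lapply(c(0, 0.2, 0.5, 1.0), function(delta) {
    eff <- if (delta > 0)
      list(list(label = 2L, class = "B", thinning = delta)) else list()
    co <- simulate_cohort(am$mesh, am$atlas, c(A = 20L, B = 20L),
                          effect_spec = eff, seed = 23L)
    fm <- patch_means(co, patches)
    splits <- rhst_splits(co$diagnosis, n_reps = 20L, seed = 3L)
    ex <- run_experiment(fm, co$diagnosis, grid, splits)
    best <- select_best(ex)
    auc <- ex$auc[ex$valid, best$combo]
    c(mean = mean(auc), se = stats::sd(auc) / sqrt(length(auc)))
  })
  for (i in 2:4) {
    expect_gte(res[[i]]["mean"] + res[[i]]["se"] + res[[i - 1]]["se"],
               res[[i - 1]]["mean"])
  }
})
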