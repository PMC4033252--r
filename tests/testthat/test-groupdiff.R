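test_that("vertex-wise T map matches the pooled-variance formula", {
  ## identical groups: T = 0 everywhere
  X <- matrix(stats::rnorm(5 * 20), 5, 20)
  tm0 <- vertexwise_tmap(X, X)
  expect_true(all(tm0$t == 0))
  expect_equal(tm0$df, 8L)

  ## hand-computed oracle: A = {2.0, 2.2, 2.4}, B = {1.0, 1.2, 1.4}
  ## means 2.2, 1.2; pooled s^2 = 0.04; se = sqrt(0.04 * 2/3); T = 6.1237
  A <- matrix(c(2.0, 2.2, 2.4), ncol = 1)
  B <- matrix(c(1.0, 1.2, 1.4), ncol = 1)
  tm <- vertexwise_tmap(A, B)
  expect_equal(tm$t, 6.1237, tolerance = 1e-3 / 6.1237)

  ## antisymmetry
  tswap <- vertexwise_tmap(B, A)
  expect_equal(tswap$t, -tm$t)

  ## agreement with the standard equal-variance two-sample test
  set.seed(31)
  Xa <- matrix(stats::rnorm(12 * 6), 12, 6)
  Xb <- matrix(stats::rnorm(9 * 6, 0.4), 9, 6)
  tmr <- vertexwise_tmap(Xa, Xb)
  for (j in c(1, 4, 6)) {
    tt <- stats::t.test(Xa[, j], Xb[, j], var.equal = TRUE)
    expect_equal(tmr$t[j], unname(tt$statistic), tolerance = 1e-12)
  }

  ## zero pooled variance is marked undefined and counted
  Xc <- cbind(rep(1, 4), stats::rnorm(4))
  Xd <- cbind(rep(1, 4), stats::rnorm(4))
  tmz <- vertexwise_tmap(Xc, Xd)
  expect_true(is.na(tmz$t[1]))
  expect_equal(tmz$n_undefined, 1L)
})

test_that("classifier feature ranking reuses the group-difference T", {
  set.seed(8)
  A <- matrix(stats::rnorm(10 * 15), 10, 15)
  B <- matrix(stats::rnorm(12 * 15, 0.3), 12, 15)
  tm <- vertexwise_tmap(A, B)
  sel <- select_features(rbind(A, B), rep(c("a", "b"), c(10, 12)), 15)
  expect_identical(as.integer(sel), order(-abs(tm$t), seq_along(tm$t)))
})

test_that("permutation cluster correction finds implanted effects", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(NC = 40L, `md-aMCI` = 40L),
                        effect_spec = list(list(label = 4L, class = "md-aMCI",
                                                thinning = 0.8)),
                        subject_sd = 0.1, vertex_sd = 0.2, seed = 21L)
  A <- co$thickness[co$diagnosis == "NC", ]
  B <- co$thickness[co$diagnosis == "md-aMCI", ]
  tm <- vertexwise_tmap(A, B)
  cr <- cluster_correct(tm, am$mesh, A, B, n_perm = 200L, seed = 13L)
  expect_gt(length(cr$significant), 0L)
  ## the top cluster overlaps at least half of the implanted label
  lab_vids <- which(am$atlas$label_of_vertex == 4L)
  top <- cr$clusters[[1]]$vertices
  expect_gte(length(intersect(top, lab_vids)) / length(lab_vids), 0.5)
})

test_that("cluster correction is reproducible and honours alpha = 1", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 15L, B = 15L), seed = 3L)
  X1 <- co$thickness[co$diagnosis == "A", ]
  X2 <- co$thickness[co$diagnosis == "B", ]
  tm <- vertexwise_tmap(X1, X2)
  cr1 <- cluster_correct(tm, am$mesh, X1, X2, cluster_forming_p = 0.05,
                         n_perm = 120L, seed = 5L)
  cr2 <- cluster_correct(tm, am$mesh, X1, X2, cluster_forming_p = 0.05,
                         n_perm = 120L, seed = 5L)
  expect_identical(cr1$null_max_stat, cr2$null_max_stat)
  expect_identical(vapply(cr1$clusters, `[[`, 0, "p_corrected"),
                   vapply(cr2$clusters, `[[`, 0, "p_corrected"))
  ## with alpha = 1 every suprathreshold cluster is reported: the cluster
  ## list covers the full suprathreshold vertex set
  cr3 <- cluster_correct(tm, am$mesh, X1, X2, cluster_forming_p = 0.05,
                         alpha = 1, n_perm = 120L, seed = 5L)
  sup <- which(abs(tm$t) >= cr3$threshold_t)
  expect_setequal(unlist(lapply(cr3$clusters, `[[`, "vertices")), sup)
  ## corrected p sorted ascending
  p <- vapply(cr1$clusters, `[[`, 0, "p_corrected")
  expect_true(!is.unsorted(p))
  expect_error(cluster_correct(tm, am$mesh, X1, X2, n_perm = 50L), "100")
})

test_that("null cluster correction keeps its family-wise error near alpha", {
  ## exchangeable null data: the fraction of experiments reporting any
  ## significant cluster should not exceed alpha by more than 2 binomial SE
  am <- fx_atlas_small()
  mesh <- am$mesh
  nv <- nrow(mesh$vertices)
  n_exp <- 60L
  alpha <- 0.05
  hits <- 0L
  set.seed(17)
  for (i in seq_len(n_exp)) {
    X1 <- matrix(stats::rnorm(12 * nv), 12, nv)
    X2 <- matrix(stats::rnorm(12 * nv), 12, nv)
    tm <- vertexwise_tmap(X1, X2)
    cr <- cluster_correct(tm, mesh, X1, X2, cluster_forming_p = 0.01,
                          alpha = alpha, n_perm = 100L, seed = i)
    if (length(cr$significant) > 0L) hits <- hits + 1L
  }
  se <- sqrt(alpha * (1 - alpha) / n_exp)
  expect_lte(hits / n_exp, alpha + 2 * se)
})

test_that("region histograms summarize per-subject means by group", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 6L, B = 6L),
                        subject_sd = 0, vertex_sd = 0, seed = 1L)
  rh <- region_histograms(co, 1:20)
  expect_true(all(rh$group_mean == 2.5))
  expect_true(all(rh$group_sd == 0))
  ## offset groups with zero noise differ exactly by the offset
  co2 <- simulate_cohort(am$mesh, am$atlas, c(A = 6L, B = 6L),
                         effect_spec = list(list(label = 1L, class = "B",
                                                 thinning = 0.4)),
                         subject_sd = 0, vertex_sd = 0, seed = 1L)
  vids <- which(am$atlas$label_of_vertex == 1L)
  rh2 <- region_histograms(co2, vids)
  expect_equal(unname(rh2$group_mean["A"] - rh2$group_mean["B"]), 0.4)
  ## bin counts conserve the subject count per group
  co3 <- simulate_cohort(am$mesh, am$atlas, c(A = 9L, B = 7L), seed = 2L)
  rh3 <- region_histograms(co3, 5:40)
  expect_equal(vapply(rh3$counts, sum, 0L)[c("A", "B")], c(A = 9L, B = 7L))
  expect_error(region_histograms(co3, integer(0)), "non-empty")
})
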