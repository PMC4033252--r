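test_that("slab phantom geometry is forced by construction", {
  slab <- make_slab_phantom(3, 1, 20)
  ## gray run along z is exactly 3 voxels thick everywhere in-plane
  runs <- apply(slab$grid == 1L, c(1, 2), sum)
  expect_true(all(runs == 3L))
  ## codes ordered inner -> gray -> outside along z
  prof <- slab$grid[1, 1, ]
  expect_equal(unique(rle(prof)$values), c(2L, 1L, 0L))
})

test_that("slab phantom rejects under-resolved separations", {
  expect_error(make_slab_phantom(1, 1, 20), "under-resolved")
  expect_error(make_slab_phantom(2, 1, 20), "under-resolved")
  expect_error(make_slab_phantom(3, 1, 2), "extent")
  ## minimal valid slab: separation = 3 * spacing
  s <- make_slab_phantom(3, 1, 10)
  expect_equal(sum(apply(s$grid == 1L, c(1, 2), sum) != 3L), 0L)
})

test_that("shell phantom matches the analytic radius band", {
  sh <- make_shell_phantom(5, 7, 0.5)
  n <- dim(sh$grid)[1]
  cc <- (seq_len(n) - (n + 1) / 2) * sh$spacing
  r <- sqrt(outer(outer(cc^2, cc^2, "+"), cc^2, "+"))
  expect_true(all((sh$grid == 1L) == (r >= 5 & r < 7)))
  expect_true(all((sh$grid == 2L) == (r < 5)))
  ## gray voxel count approximates the analytic shell volume within 10%
  analytic <- 4 / 3 * pi * (7^3 - 5^3) / 0.5^3
  expect_lt(abs(sum(sh$grid == 1L) - analytic) / analytic, 0.10)
  expect_error(make_shell_phantom(5, 5, 0.5), "r_outer")
  expect_error(make_shell_phantom(5, 6, 0.5), "under-resolved")
})

test_that("atlas mesh yields the requested parcellation", {
  am <- fx_atlas_small()
  expect_equal(length(unique(am$atlas$label_of_vertex)), 12L)
  ## every vertex labeled exactly once (no orphans)
  expect_false(anyNA(am$atlas$label_of_vertex))
  expect_equal(length(am$atlas$label_of_vertex), nrow(am$mesh$vertices))
  ## labels respect hemispheres: labels 1..6 left, 7..12 right
  left <- am$mesh$hemisphere == "left"
  expect_true(all(am$atlas$label_of_vertex[left] <= 6L))
  expect_true(all(am$atlas$label_of_vertex[!left] > 6L))
  ## meshes are closed connected 2-manifolds per hemisphere
  expect_true(validate_mesh(am$mesh))
  ## a full-scale atlas carries 34 labels per hemisphere, 68 total
  full <- fx_atlas_full()
  expect_equal(length(unique(full$atlas$label_of_vertex)), 68L)
  ## single-label hemisphere is legal
  one <- make_atlas_mesh(vertices_per_label = 15L, n_labels = 1L, seed = 1L)
  expect_equal(sort(unique(one$atlas$label_of_vertex)), c(1L, 2L))
})

test_that("atlas labels are spatially contiguous", {
  am <- fx_atlas_small()
  edges <- mesh_edges(am$mesh)
  for (lab in unique(am$atlas$label_of_vertex)) {
    vids <- which(am$atlas$label_of_vertex == lab)
    sel <- edges[edges[, 1] %in% vids & edges[, 2] %in% vids, , drop = FALSE]
    g <- igraph::make_graph(as.vector(t(matrix(match(sel, vids), ncol = 2))),
                            n = length(vids), directed = FALSE)
    expect_equal(igraph::components(g)$no, 1L)
  }
})

test_that("noise-free cohort equals the baseline everywhere", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 3L, B = 3L),
                        subject_sd = 0, vertex_sd = 0, seed = 1L)
  expect_true(all(co$thickness == 2.5))
})

test_that("default group sizes give the 42/38/32 cohort", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, seed = 2L)
  expect_equal(nrow(co$thickness), 112L)
  expect_equal(as.integer(table(co$diagnosis)[c("NC", "sd-aMCI", "md-aMCI")]),
               c(42L, 38L, 32L))
  expect_equal(nrow(co$covariates), 112L)
  ## scanner is assigned near-evenly within each class
  for (g in unique(co$diagnosis)) {
    tab <- table(co$covariates$scanner[co$diagnosis == g])
    expect_lte(abs(diff(as.integer(tab))), 1L)
  }
})

test_that("implanted thinning is recovered as a group-mean difference", {
  ## empirical class-mean difference over the implanted label must sit
  ## within 3 standard errors of the implanted 0.5 mm at n = 200
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(NC = 100L, `md-aMCI` = 100L),
                        effect_spec = list(list(label = 3L, class = "md-aMCI",
                                                thinning = 0.5)),
                        seed = 7L)
  vids <- which(am$atlas$label_of_vertex == 3L)
  per_subj <- rowMeans(co$thickness[, vids])
  a <- per_subj[co$diagnosis == "NC"]
  b <- per_subj[co$diagnosis == "md-aMCI"]
  diff_mean <- mean(a) - mean(b)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_lt(abs(diff_mean - 0.5), 3 * se)
})

test_that("cohort simulation is bit-reproducible under a fixed seed", {
  am <- fx_atlas_small()
  c1 <- simulate_cohort(am$mesh, am$atlas, c(A = 5L, B = 5L), seed = 99L)
  c2 <- simulate_cohort(am$mesh, am$atlas, c(A = 5L, B = 5L), seed = 99L)
  expect_identical(c1$thickness, c2$thickness)
  expect_identical(c1$covariates, c2$covariates)
})

test_that("null cohorts carry no vertex-wise group signal", {
  ## with no implanted effect, vertex-wise two-sample t p-values are
  ## approximately uniform (KS test)
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 25L, B = 25L), seed = 5L)
  tm <- vertexwise_tmap(co$thickness[co$diagnosis == "A", ],
                        co$thickness[co$diagnosis == "B", ])
  p <- 2 * stats::pt(-abs(tm$t), df = tm$df)
  ## neighbouring vertices are correlated by design; thin to every 4th
  ## vertex to temper the dependence before the uniformity check
  ks <- suppressWarnings(stats::ks.test(p[seq(1, length(p), by = 4)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clipping floor never activates at realistic noise scales", {
  am <- fx_atlas_small()
  co <- simulate_cohort(am$mesh, am$atlas, c(A = 30L, B = 30L),
                        effect_spec = list(list(label = 1L, class = "B",
                                                thinning = 0.5)),
                        seed = 11L)
  expect_true(all(co$thickness > 0.05))
})

test_that("cohort validation rejects malformed requests", {
  am <- fx_atlas_small()
  expect_error(simulate_cohort(am$mesh, am$atlas, c(A = 1L, B = 5L), seed = 1),
               ">= 2 subjects")
  expect_error(simulate_cohort(am$mesh, am$atlas, c(A = 5L, B = 5L),
                               effect_spec = list(list(label = 99L, class = "A",
                                                       thinning = 0.1)),
                               seed = 1),
               "unknown label")
  expect_error(simulate_cohort(am$mesh, am$atlas, c(A = 5L, B = 5L),
                               effect_spec = list(list(label = 1L, class = "Z",
                                                       thinning = 0.1)),
                               seed = 1),
               "unknown class")
})
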