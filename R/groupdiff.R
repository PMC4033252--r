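## Shared pooled-variance two-sample T computation. Operates columnwise on
## two subjects x variables matrices; returns the T vector (positive where
## group A exceeds group B) plus degrees of freedom. This single routine
## backs both the vertex-wise group maps and the classifier's feature
## ranking, so the two stages cannot drift apart.
pooled_t <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 subjects", call. = FALSE)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2)
  v2 <- colSums(sweep(B, 2, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- NA_real_
  list(t = t, df = df, n_undefined = sum(se == 0))
}

#' Vertex-wise two-sample T map
#'
#' Pooled-variance two-sample T statistic at every vertex; positive values
#' mean group A is thicker than group B. Vertices with zero pooled variance
#' get an undefined marker (NA) and are counted.
#'
#' @param groupA,groupB Subjects x vertices thickness matrices.
#' @return An object of class \code{tmap} with fields \code{t}, \code{df},
#'   \code{group_sizes} and \code{n_undefined}.
#' @export
vertexwise_tmap <- function(groupA, groupB) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB))
    stop("groups must share the vertex set", call. = FALSE)
  pt <- pooled_t(groupA, groupB)
  structure(list(t = pt$t, df = pt$df,
                 group_sizes = c(nrow(groupA), nrow(groupB)),
                 n_undefined = pt$n_undefined),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("tmap: %d vertices, df = %d (groups %d/%d), |T| max %.2f, %d undefined\n",
              length(x$t), x$df, x$group_sizes[1], x$group_sizes[2],
              max(abs(x$t), na.rm = TRUE), x$n_undefined))
  invisible(x)
}

## edge-connected components of a vertex subset; returns list of vertex-id
## vectors (ids into the full mesh)
vertex_components <- function(vids, edges) {
  if (length(vids) == 0L) return(list())
  if (length(vids) == 1L) return(list(vids))
  sel <- edges[edges[, 1] %in% vids & edges[, 2] %in% vids, , drop = FALSE]
  idx <- matrix(match(sel, vids), ncol = 2)
  g <- igraph::make_graph(as.vector(t(idx)), n = length(vids), directed = FALSE)
  comp <- igraph::components(g)$membership
  split(vids, comp)
}

## suprathreshold cluster masses of a |T| map
cluster_masses <- function(tvals, thr, edges) {
  sup <- which(!is.na(tvals) & abs(tvals) >= thr)
  comps <- vertex_components(sup, edges)
  if (length(comps) == 0L) return(list(masses = numeric(0), comps = comps))
  list(masses = vapply(comps, function(v) sum(abs(tvals[v])), 0), comps = comps)
}

## t statistics for many permuted group assignments at once.
## X: subjects x vertices; assign: n_perm x subjects logical (TRUE = group A)
perm_tmaps <- function(X, assign, n1, n2) {
  X2 <- X^2
  A <- assign * 1
  sumA <- A %*% X; sumA2 <- A %*% X2
  sumT <- matrix(colSums(X), nrow(A), ncol(X), byrow = TRUE)
  sumT2 <- matrix(colSums(X2), nrow(A), ncol(X), byrow = TRUE)
  sumB <- sumT - sumA; sumB2 <- sumT2 - sumA2
  m1 <- sumA / n1; m2 <- sumB / n2
  v1 <- sumA2 - n1 * m1^2
  v2 <- sumB2 - n2 * m2^2
  df <- n1 + n2 - 2
  se <- sqrt(pmax(v1 + v2, 0) / df * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tt[se == 0] <- NA_real_
  tt
}

#' Cluster-level multiple-comparison correction by permutation
#'
#' Thresholds the |T| map at a vertex-level cluster-forming p-value,
#' extracts edge-connected suprathreshold clusters and assigns each a
#' corrected p-value as the fraction of group-label permutations whose
#' maximal cluster mass (sum of |T|) reaches the observed mass. This
#' permutation maximal-statistic procedure provides family-wise error
#' control at the cluster level without smoothness estimation.
#'
#' @param tmap A \code{tmap} from \code{\link{vertexwise_tmap}}.
#' @param mesh The \code{cortical_mesh} defining vertex adjacency.
#' @param groupA,groupB The thickness matrices the map was computed from.
#' @param cluster_forming_p Two-sided vertex-level threshold (default 0.001).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param statistic Cluster summary: \code{"mass"} (default, sum of |T|) or
#'   \code{"extent"} (vertex count).
#' @return An object of class \code{cluster_result}: a list of clusters
#'   (vertex ids, peak T, summary statistic, corrected p), sorted by
#'   corrected p, plus the significant subset at \code{alpha}.
#' @export
cluster_correct <- function(tmap, mesh, groupA, groupB,
                            cluster_forming_p = 0.001, alpha = 0.05,
                            n_perm = 1000L, seed = 1L,
                            statistic = c("mass", "extent")) {
  statistic <- match.arg(statistic)
  if (n_perm < 100L) stop("'n_perm' must be >= 100 for a stable tail", call. = FALSE)
  if (length(tmap$t) != nrow(mesh$vertices))
    stop("tmap length does not match mesh vertex count", call. = FALSE)
  edges <- mesh_edges(mesh)
  thr <- stats::qt(1 - cluster_forming_p / 2, df = tmap$df)
  stat_of <- if (statistic == "mass") {
    function(tv, comps) vapply(comps, function(v) sum(abs(tv[v])), 0)
  } else {
    function(tv, comps) vapply(comps, length, 0L)
  }
  obs <- cluster_masses(tmap$t, thr, edges)
  obs_stat <- stat_of(tmap$t, obs$comps)
  X <- rbind(as.matrix(groupA), as.matrix(groupB))
  n1 <- nrow(groupA); n2 <- nrow(groupB); n <- n1 + n2
  assign <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      a <- logical(n); a[sample.int(n, n1)] <- TRUE; a
    }, logical(n)))
  })
  tt <- perm_tmaps(X, assign, n1, n2)
  max_stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    cm <- cluster_masses(tt[b, ], thr, edges)
    st <- stat_of(tt[b, ], cm$comps)
    max_stat[b] <- if (length(st)) max(st) else 0
  }
  pvals <- vapply(obs_stat, function(s) (1 + sum(max_stat >= s)) / (n_perm + 1), 0)
  ord <- order(pvals)
  clusters <- lapply(ord, function(i) {
    v <- obs$comps[[i]]
    list(vertices = v,
         peak_t = tmap$t[v][which.max(abs(tmap$t[v]))],
         statistic = obs_stat[i],
         p_corrected = pvals[i])
  })
  structure(list(clusters = clusters,
                 significant = clusters[vapply(clusters, function(cl)
                   cl$p_corrected < alpha, TRUE)],
                 alpha = alpha, n_permutations = n_perm,
                 cluster_forming_p = cluster_forming_p,
                 threshold_t = thr, statistic = statistic,
                 null_max_stat = max_stat),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters (|T| >= %.2f), %d significant at alpha = %g [%d permutations]\n",
              length(x$clusters), x$threshold_t, length(x$significant),
              x$alpha, x$n_permutations))
  for (cl in x$clusters[seq_len(min(5, length(x$clusters)))])
    cat(sprintf("  %4d vertices, peak T %6.2f, %s %8.1f, p = %.4f\n",
                length(cl$vertices), cl$peak_t, x$statistic, cl$statistic,
                cl$p_corrected))
  invisible(x)
}

#' Per-group thickness distribution over a region
#'
#' Averages each subject's thickness over a vertex set (e.g. the most
#' significant cluster) and summarizes the per-subject means by diagnosis:
#' group means, SDs and histogram bin counts on shared breaks.
#'
#' @param cohort A \code{cohort_dataset}.
#' @param vertex_set Non-empty integer vector of vertex ids.
#' @param breaks Passed to \code{\link[graphics]{hist}} (default
#'   \code{"Sturges"}).
#' @return List with \code{subject_means} (named by diagnosis),
#'   \code{group_mean}, \code{group_sd}, \code{breaks}, \code{counts}
#'   (per-group bin counts).
#' @export
region_histograms <- function(cohort, vertex_set, breaks = "Sturges") {
  if (length(vertex_set) == 0L) stop("'vertex_set' must be non-empty", call. = FALSE)
  sm <- rowMeans(cohort$thickness[, vertex_set, drop = FALSE])
  h_all <- graphics::hist(sm, breaks = breaks, plot = FALSE)
  groups <- split(sm, cohort$diagnosis)
  counts <- lapply(groups, function(v)
    graphics::hist(v, breaks = h_all$breaks, plot = FALSE)$counts)
  list(subject_means = groups,
       group_mean = vapply(groups, mean, 0),
       group_sd = vapply(groups, stats::sd, 0),
       breaks = h_all$breaks,
       counts = counts)
}
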