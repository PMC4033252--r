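#' Default run configuration
#'
#' The configuration drives every stage of \code{\link{run_all}}. Defaults
#' describe the reference study design: a 34-label-per-hemisphere atlas,
#' groups of 42/38/32 (normal controls, single- and multi-domain amnestic
#' MCI), 10 patches per label (680 features), the full 7 x 10 SVM grid and
#' 250 stratified-holdout repetitions. Implanted effects default to subtle
#' multi-domain thinning, in line with the weak separability such cohorts
#' show.
#'
#' @param seed Integer master seed (mandatory; every stage derives its own
#'   stream from it).
#' @return A list of class \code{run_config}.
#' @export
default_run_config <- function(seed) {
  cfg <- list(
    seed = seed,
    atlas = list(vertices_per_label = 30L, n_labels = 34L, radius = 70),
    cohort = list(group_sizes = c("NC" = 42L, "sd-aMCI" = 38L, "md-aMCI" = 32L),
                  effects = list(
                    list(label = 5L, class = "md-aMCI", thinning = 0.25),
                    list(label = 12L, class = "md-aMCI", thinning = 0.25),
                    list(label = 20L, class = "md-aMCI", thinning = 0.25),
                    list(label = 5L, class = "sd-aMCI", thinning = 0.12)),
                  baseline_mean = 2.5, subject_sd = 0.15, vertex_sd = 0.3,
                  scanner_effect = 0, noise_fwhm = 10),
    phantom = list(slab_separation = 3, slab_spacing = 1, slab_extent = 20,
                   shell_r_inner = 5, shell_r_outer = 7, shell_spacing = 0.5),
    groupdiff = list(pair = c("NC", "md-aMCI"), cluster_forming_p = 0.001,
                     alpha = 0.05, n_perm = 500L),
    features = list(patches_per_label = 10L, residualize_scanner = FALSE),
    classify = list(pairs = list(c("NC", "sd-aMCI"), c("NC", "md-aMCI"),
                                 c("sd-aMCI", "md-aMCI")),
                    n_reps = 250L, train_fraction = 0.5,
                    C_values = 10^(-1:5), gamma_values = 2^(-5:4)),
    evaluate = list(roc_grid_size = 101L))
  class(cfg) <- c("run_config", "list")
  cfg
}

validate_run_config <- function(config) {
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    stop("run config must declare an explicit integer 'seed'", call. = FALSE)
  for (f in c("atlas", "cohort", "features", "classify"))
    if (is.null(config[[f]])) stop("run config lacks section '", f, "'", call. = FALSE)
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Missing sections fall back to \code{\link{default_run_config}} values;
#' the seed must be explicit in the file.
#'
#' @param file Path to a YAML config.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(file) {
  user <- yaml::read_yaml(file)
  if (is.null(user$seed)) stop("config file must declare 'seed'", call. = FALSE)
  cfg <- default_run_config(as.integer(user$seed))
  for (nm in setdiff(names(user), "seed")) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  ## YAML turns named vectors into lists; coerce the ones that matter
  cfg$cohort$group_sizes <- unlist(cfg$cohort$group_sizes)
  cfg
}

checksum_files <- function(paths) {
  ok <- file.exists(paths)
  sums <- rep(NA_character_, length(paths))
  sums[ok] <- unname(tools::md5sum(paths[ok]))
  names(sums) <- basename(paths)
  sums
}

#' Run the complete pipeline
#'
#' Executes simulate -> phantom validation -> group difference -> features
#' -> classification -> evaluation under one master seed, writing every
#' stage output (PLY mesh, TSV tables, JSON summaries, ROC plot) into
#' \code{out_dir} and a manifest with per-file checksums at its root.
#' Deterministic given the config; a stage failure aborts with the stage
#' name while earlier outputs remain on disk.
#'
#' @param config A \code{run_config} (see \code{\link{default_run_config}}).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_all <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outputs <- character(0)
  add_out <- function(path) outputs <<- c(outputs, path)

  ## -- simulate ------------------------------------------------------------
  am <- stage("simulate", {
    say("simulate: atlas %d labels/hemisphere, seed %d",
        config$atlas$n_labels, derive_seed(seed, 10L))
    make_atlas_mesh(config$atlas$vertices_per_label, config$atlas$n_labels,
                    config$atlas$radius, seed = derive_seed(seed, 10L))
  })
  cohort <- stage("simulate", {
    co <- config$cohort
    say("simulate: cohort %s, seed %d",
        paste(sprintf("%s=%d", names(co$group_sizes), co$group_sizes),
              collapse = " "), derive_seed(seed, 11L))
    simulate_cohort(am$mesh, am$atlas, co$group_sizes, co$effects,
                    co$baseline_mean, co$subject_sd, co$vertex_sd,
                    co$scanner_effect, co$noise_fwhm,
                    seed = derive_seed(seed, 11L))
  })
  add_out(write_mesh_ply(am$mesh, file.path(out_dir, "atlas_mesh.ply")))
  add_out(write_labels_tsv(am$atlas, file.path(out_dir, "atlas_labels.tsv")))
  add_out(write_tsv(cbind(subject_id = sprintf("S%03d", seq_len(nrow(cohort$thickness))),
                          diagnosis = cohort$diagnosis, cohort$covariates),
                    file.path(out_dir, "covariates.tsv")))

  ## -- phantom validation suite -------------------------------------------
  ph <- stage("phantom", {
    p <- config$phantom
    slab <- make_slab_phantom(p$slab_separation, p$slab_spacing, p$slab_extent)
    fsl <- solve_laplace(slab)
    zmid <- p$slab_separation / 2
    tr <- trace_streamline(fsl, slab, c(p$slab_extent / 2, p$slab_extent / 2, zmid))
    shell <- make_shell_phantom(p$shell_r_inner, p$shell_r_outer, p$shell_spacing)
    fsh <- solve_laplace(shell)
    pial <- icosphere(2, p$shell_r_outer)
    tm <- compute_thickness(pial, fsh, shell)
    err <- abs(tm$values - (p$shell_r_outer - p$shell_r_inner))
    say("phantom: slab thickness %.4f (true %g); shell max err %.4f mm, %d traces failed",
        tr$thickness, p$slab_separation, max(err, na.rm = TRUE), tm$n_failed)
    list(slab_thickness = tr$thickness,
         slab_true = p$slab_separation,
         shell_median_err = stats::median(err, na.rm = TRUE),
         shell_max_err = max(err, na.rm = TRUE),
         shell_failed = tm$n_failed)
  })

  ## -- group difference ----------------------------------------------------
  gd <- stage("groupdiff", {
    g <- config$groupdiff
    A <- cohort$thickness[cohort$diagnosis == g$pair[1], , drop = FALSE]
    B <- cohort$thickness[cohort$diagnosis == g$pair[2], , drop = FALSE]
    tm <- vertexwise_tmap(A, B)
    cr <- cluster_correct(tm, am$mesh, A, B, g$cluster_forming_p, g$alpha,
                          g$n_perm, seed = derive_seed(seed, 20L))
    say("groupdiff %s vs %s: %d clusters, %d significant at alpha=%g",
        g$pair[1], g$pair[2], length(cr$clusters), length(cr$significant),
        g$alpha)
    list(tmap = tm, clusters = cr, pair = g$pair)
  })
  add_out(write_thickness_tsv(gd$tmap$t, file.path(out_dir, "tmap.tsv")))
  cl_json <- lapply(gd$clusters$clusters, function(cl)
    list(n_vertices = length(cl$vertices), peak_t = cl$peak_t,
         statistic = cl$statistic, p_corrected = cl$p_corrected,
         vertices_0based = cl$vertices - 1L))
  jsonlite::write_json(cl_json, file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  add_out(file.path(out_dir, "clusters.json"))

  ## -- features -------------------------------------------------------------
  feats <- stage("features", {
    fe <- config$features
    patches <- make_patches(am$mesh, am$atlas, fe$patches_per_label,
                            seed = derive_seed(seed, 30L))
    fm <- patch_means(cohort, patches)
    if (isTRUE(fe$residualize_scanner))
      fm <- residualize(fm, cohort$covariates$scanner)
    say("features: %d patches -> %d x %d feature matrix%s",
        patches$n_patches, nrow(fm), ncol(fm),
        if (isTRUE(fe$residualize_scanner)) " (scanner residualized)" else "")
    list(patches = patches, fm = fm)
  })
  add_out(write_patches_tsv(feats$patches, am$atlas,
                            file.path(out_dir, "patches.tsv")))
  add_out(write_features_tsv(feats$fm, file.path(out_dir, "features.tsv")))

  ## -- classify + evaluate --------------------------------------------------
  rows <- list()
  for (pi in seq_along(config$classify$pairs)) {
    pair <- config$classify$pairs[[pi]]
    res <- stage("classify", {
      keep <- cohort$diagnosis %in% pair
      Xp <- feats$fm[keep, , drop = FALSE]
      yp <- factor(cohort$diagnosis[keep], levels = pair)
      splits <- rhst_splits(yp, config$classify$n_reps,
                            config$classify$train_fraction,
                            seed = derive_seed(seed, 40L + pi))
      grid <- svm_grid(config$classify$C_values, config$classify$gamma_values)
      ex <- run_experiment(Xp, yp, grid, splits)
      say("classify %s vs %s: %d reps x %d combos, K=%d, %d flagged",
          pair[1], pair[2], splits$n_reps, nrow(grid), ex$K, ex$n_flagged)
      ex
    })
    row <- stage("evaluate", {
      best <- select_best(res)
      p <- auc_vs_chance(res$auc[res$valid, best$combo])
      av <- vertical_average(experiment_rocs(res, best$combo),
                             config$evaluate$roc_grid_size)
      tag <- paste(pair, collapse = "_vs_")
      write_tsv(data.frame(fpr = av$fpr_grid, mean_tpr = av$mean_tpr,
                           sd_tpr = av$sd_tpr),
                file.path(out_dir, sprintf("roc_%s.tsv", tag)))
      add_out(file.path(out_dir, sprintf("roc_%s.tsv", tag)))
      grDevices::png(file.path(out_dir, sprintf("roc_%s.png", tag)),
                     width = 600, height = 600)
      plot(av)
      grDevices::dev.off()
      m <- best$metrics
      list(pair = paste(pair, collapse = " vs "), K = res$K,
           gamma = best$gamma, C = best$C,
           AUC = round(m["AUC", "mean"], 4), AUC_sd = round(m["AUC", "sd"], 4),
           ACC = round(100 * m["ACC", "mean"], 2),
           SPEC = round(100 * m["SPEC", "mean"], 2),
           SENS = round(100 * m["SENS", "mean"], 2),
           p_vs_chance = as.numeric(p))
    })
    rows[[pi]] <- row
    say("evaluate %s: AUC %.3f ACC %.1f%% (p vs chance %.3g)",
        row$pair, row$AUC, row$ACC, row$p_vs_chance)
  }
  jsonlite::write_json(rows, file.path(out_dir, "classification_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  add_out(file.path(out_dir, "classification_summary.json"))

  ## -- manifest --------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("corthick")),
    seed = seed,
    config_checksum = unname(tools::md5sum(cfg_file)),
    checksums = as.list(checksum_files(outputs)),
    phantom_validation = ph,
    table_rows = rows,
    timestamp = format(Sys.time(), tz = "UTC"),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
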