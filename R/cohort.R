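#' Simulated thickness cohorts
#'
#' A \code{cohort_dataset} holds a subjects x vertices thickness matrix
#' (mm), a diagnosis tag per subject, a covariate table (age, sex, scanner)
#' and, for simulated cohorts, a record of the implanted group effects.
#'
#' @param thickness Subjects x vertices numeric matrix, mm (> 0).
#' @param diagnosis Character/factor of class tags, one per subject.
#' @param covariates Data frame with one row per subject.
#' @param effect_truth Optional list describing implanted effects.
#' @return An object of class \code{cohort_dataset}.
#' @export
cohort_dataset <- function(thickness, diagnosis, covariates,
                           effect_truth = NULL) {
  thickness <- as.matrix(thickness)
  if (any(!is.finite(thickness)) || any(thickness <= 0))
    stop("all thickness values must be finite and > 0", call. = FALSE)
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != nrow(thickness))
    stop("one diagnosis per subject required", call. = FALSE)
  if (nrow(covariates) != nrow(thickness))
    stop("covariate row count must equal subject count", call. = FALSE)
  structure(list(thickness = thickness, diagnosis = diagnosis,
                 covariates = covariates, effect_truth = effect_truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$diagnosis)
  cat(sprintf("cohort_dataset: %d subjects x %d vertices (%s)\n",
              nrow(x$thickness), ncol(x$thickness),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a multi-group cortical-thickness cohort
#'
#' Generates per-subject, per-vertex thickness as
#' \code{baseline + subject offset + smooth vertex noise - implanted
#' thinning + scanner offset}: the subject offset is Normal with SD
#' \code{subject_sd}; vertex noise is Normal with SD \code{vertex_sd} and is
#' smoothed on the mesh with the same diffusion kernel the analysis uses
#' (default 10-mm FWHM) so simulated maps have the spatial smoothness the
#' pipeline assumes; listed anatomical labels are thinned by the stated
#' amount for the stated class; subjects on scanner 2 receive a constant
#' additive offset. Scanners are assigned near-evenly within each class.
#' Values are clipped to a small positive floor (0.05 mm), which is inert
#' whenever \code{baseline_mean} dominates the noise scales.
#'
#' The default group sizes (42 normal controls, 38 single-domain and 32
#' multi-domain amnestic MCI) mirror a typical aging-cohort design.
#'
#' @param mesh A \code{cortical_mesh} (shared by all subjects; vertex
#'   correspondence by construction).
#' @param atlas Matching \code{label_atlas}.
#' @param group_sizes Named integer vector, class -> subject count.
#' @param effect_spec List of implanted effects, each a list with elements
#'   \code{label} (atlas label id), \code{class} (diagnosis tag) and
#'   \code{thinning} (mm, subtracted).
#' @param baseline_mean Mean thickness, mm (default 2.5).
#' @param subject_sd Between-subject SD of the global offset, mm.
#' @param vertex_sd SD of vertex noise before smoothing, mm.
#' @param scanner_effect Additive offset for scanner-2 subjects, mm.
#' @param noise_fwhm FWHM of the spatial smoothing applied to vertex
#'   noise, mm.
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return A \code{cohort_dataset} with \code{effect_truth} recording the
#'   implants.
#' @export
simulate_cohort <- function(mesh, atlas,
                            group_sizes = c("NC" = 42L, "sd-aMCI" = 38L,
                                            "md-aMCI" = 32L),
                            effect_spec = list(),
                            baseline_mean = 2.5, subject_sd = 0.15,
                            vertex_sd = 0.3, scanner_effect = 0,
                            noise_fwhm = 10, seed = 1L) {
  stopifnot_scalar_pos(baseline_mean, "baseline_mean")
  if (subject_sd < 0 || vertex_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("'group_sizes' must be a named vector", call. = FALSE)
  if (any(group_sizes < 2L)) stop("every group needs >= 2 subjects", call. = FALSE)
  n_labels_total <- max(atlas$label_of_vertex)
  for (ef in effect_spec) {
    if (!all(c("label", "class", "thinning") %in% names(ef)))
      stop("each effect needs 'label', 'class', 'thinning'", call. = FALSE)
    if (ef$label < 1L || ef$label > n_labels_total)
      stop("unknown label ", ef$label, " in effect_spec", call. = FALSE)
    if (!ef$class %in% names(group_sizes))
      stop("unknown class '", ef$class, "' in effect_spec", call. = FALSE)
    if (ef$thinning >= baseline_mean)
      stop("thinning magnitudes must be < baseline_mean", call. = FALSE)
  }
  nv <- nrow(mesh$vertices)
  if (length(atlas$label_of_vertex) != nv)
    stop("atlas does not match mesh", call. = FALSE)
  n <- sum(group_sizes)
  diagnosis <- rep(names(group_sizes), group_sizes)
  with_seed(seed, {
    subj_off <- stats::rnorm(n, 0, subject_sd)
    noise <- matrix(stats::rnorm(n * nv, 0, vertex_sd), nrow = nv, ncol = n)
    if (vertex_sd > 0 && noise_fwhm > 0)
      noise <- smooth_on_mesh(noise, mesh, noise_fwhm)
    ## scanner assigned stratified-even within class (randomized remainder)
    scanner <- integer(n)
    for (g in names(group_sizes)) {
      idx <- which(diagnosis == g)
      half <- length(idx) %/% 2L
      s <- c(rep(1L, half), rep(2L, length(idx) - half))
      scanner[idx] <- sample(s)
    }
    age <- round(stats::rnorm(n, 78, 4.5), 1)
    sex <- sample(c("F", "M"), n, replace = TRUE)
  })
  thick <- matrix(baseline_mean, nrow = n, ncol = nv)
  thick <- thick + subj_off + t(noise)
  for (ef in effect_spec) {
    rows <- which(diagnosis == ef$class)
    cols <- which(atlas$label_of_vertex == ef$label)
    thick[rows, cols] <- thick[rows, cols] - ef$thinning
  }
  thick[scanner == 2L, ] <- thick[scanner == 2L, ] + scanner_effect
  thick[thick < 0.05] <- 0.05
  covariates <- data.frame(age = age, sex = sex, scanner = scanner)
  cohort_dataset(thick, diagnosis, covariates,
                 effect_truth = list(effects = effect_spec,
                                     baseline_mean = baseline_mean,
                                     subject_sd = subject_sd,
                                     vertex_sd = vertex_sd,
                                     scanner_effect = scanner_effect,
                                     noise_fwhm = noise_fwhm, seed = seed))
}
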