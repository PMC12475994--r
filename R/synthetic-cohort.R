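#' Configuration for the synthetic three-group cohort generator
#'
#' The defaults emulate the design of a diabetic-kidney-disease morphometry
#' study: 70 healthy controls (HC), 65 diabetes-without-kidney-disease
#' patients (DM) and 50 diabetic-kidney-disease patients (DKD); 90 atlas
#' regions; per-ROI voxel counts uniform in 200-2000; six affected regions
#' standing in for right dorsolateral superior frontal, bilateral middle
#' frontal, left lingual, right middle occipital and right precuneus nodes;
#' and clinical variables with published per-group means/SDs. The group
#' effect is a graded perturbation of the affected regions' value
#' distributions (`effect_grades`, log-scale units, HC <= DM <= DKD), so the
#' similarity of pairs involving those regions decreases progressively from
#' HC to DM to DKD.
#'
#' @param group_sizes named counts for HC, DM, DKD (each >= 2).
#' @param n_rois number of regions (default 90).
#' @param voxels_per_roi length-2 integer range of voxels per ROI.
#' @param affected_rois ROI indices carrying the group effect.
#' @param effect_grades named non-negative dissimilarity scales, monotone
#'   HC <= DM <= DKD.
#' @param clinical_params per-variable, per-group `c(mean, sd)` list; see
#'   [default_clinical_params()].
#' @param male_prop named per-group probability that `gender == 1` (male).
#' @param min_voxels lower bound accepted for any ROI vector.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(HC = 70L, DM = 65L, DKD = 50L),
                          n_rois = 90L,
                          voxels_per_roi = c(200L, 2000L),
                          affected_rois = c(4L, 7L, 8L, 47L, 52L, 68L),
                          effect_grades = c(HC = 0, DM = 0.30, DKD = 0.60),
                          clinical_params = default_clinical_params(),
                          male_prop = c(HC = 48 / 70, DM = 39 / 65,
                                        DKD = 31 / 50),
                          min_voxels = 10L,
                          seed = 42L) {
  grp <- c("HC", "DM", "DKD")
  if (!all(grp %in% names(group_sizes)) || any(group_sizes[grp] < 2)) {
    stop_morphnet("group_sizes must name HC, DM, DKD with counts >= 2",
                  class = "morphnet_config_error")
  }
  eg <- effect_grades[grp]
  if (any(is.na(eg)) || any(eg < 0) || eg["HC"] > eg["DM"] ||
      eg["DM"] > eg["DKD"]) {
    stop_morphnet(
      "effect_grades must be non-negative and monotone HC <= DM <= DKD",
      class = "morphnet_config_error")
  }
  if (any(affected_rois < 1) || any(affected_rois > n_rois)) {
    stop_morphnet("affected_rois must lie in 1..n_rois",
                  class = "morphnet_config_error")
  }
  if (length(voxels_per_roi) != 2 || voxels_per_roi[1] < min_voxels ||
      voxels_per_roi[2] < voxels_per_roi[1]) {
    stop_morphnet("invalid voxels_per_roi range",
                  class = "morphnet_config_error")
  }
  group_sizes <- setNames(as.integer(group_sizes[grp]), grp)
  eg <- setNames(as.numeric(eg), grp)
  male_prop <- setNames(as.numeric(male_prop[grp]), grp)
  structure(list(group_sizes = group_sizes, n_rois = as.integer(n_rois),
                 voxels_per_roi = as.integer(voxels_per_roi),
                 affected_rois = as.integer(affected_rois),
                 effect_grades = eg, clinical_params = clinical_params,
                 male_prop = male_prop[grp],
                 min_voxels = as.integer(min_voxels),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-group clinical marginals
#'
#' Per-variable `c(mean, sd)` for each group. Values for the HC group's
#' kidney indicators (eGFR, Scr) are synthetic healthy-range choices, since
#' studies of this design report them for patients only; everything else
#' follows typical published three-group marginals. TIV is in milliliters.
#'
#' @return named list: variable -> list(HC=, DM=, DKD=) of `c(mean, sd)`.
#' @export
default_clinical_params <- function() {
  list(
    age       = list(HC = c(51.36, 11.05), DM = c(53.88, 8.80),
                     DKD = c(52.82, 8.00)),
    education = list(HC = c(10.71, 5.56), DM = c(9.89, 3.35),
                     DKD = c(10.38, 3.72)),
    TIV       = list(HC = c(1450, 130), DM = c(1450, 130),
                     DKD = c(1450, 130)),
    eGFR      = list(HC = c(110, 12), DM = c(107.84, 11.27),
                     DKD = c(56.14, 13.54)),
    Scr       = list(HC = c(58, 10), DM = c(61.31, 14.09),
                     DKD = c(216.54, 31.52)),
    MMSE      = list(HC = c(28.23, 1.21), DM = c(26.48, 2.69),
                     DKD = c(25.82, 2.99)),
    MoCA      = list(HC = c(27.06, 1.35), DM = c(25.20, 3.58),
                     DKD = c(23.22, 3.84)),
    DST       = list(HC = c(48.89, 12.53), DM = c(44.65, 14.64),
                     DKD = c(36.42, 15.35)),
    NCTA      = list(HC = c(41.17, 17.01), DM = c(46.40, 16.02),
                     DKD = c(61.12, 27.69)),
    NCTB      = list(HC = c(63.03, 26.08), DM = c(67.43, 18.45),
                     DKD = c(96.30, 57.67)))
}

# latent-severity loadings of the coupled clinical variables: kidney function
# degrades (eGFR down, Scr up) and psychomotor speed slows (NCT-A up) with
# the same severity factor that scales the network effect
severity_loadings <- c(eGFR = -0.6, Scr = 0.6, NCTA = 0.4)

#' Generate a complete synthetic cohort
#'
#' Draws, for every subject, per-ROI voxel value vectors from log-normal
#' distributions with ROI-specific base parameters shared across subjects
#' plus subject-level jitter. In the affected ROIs the log-location is
#' shifted and the log-scale widened in proportion to the group's effect
#' grade times a subject-level latent severity factor, with a fixed per-ROI
#' sign/scale pattern, so pairwise distributional similarity involving those
#' ROIs decreases monotonically HC -> DM -> DKD. Clinical variables are drawn
#' from the configured per-group marginals; eGFR, Scr and NCT-A are coupled
#' to the same latent severity (eGFR negatively, Scr positively), making
#' degree-kidney-function correlations recoverable downstream.
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (data frame: subject_id, group, age, gender,
#'   education, TIV, clinical variables, and the latent `severity` used for
#'   validation) and `samples` (list of [roi_sample_set()], one per subject,
#'   same order as the rows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_rois <- config$n_rois
  atlas <- if (n_rois == 90L) aal90_atlas() else
    atlas_spec(paste0("synthetic", n_rois), n_rois)

  # ROI base distribution parameters, shared by all subjects
  meanlog0 <- rnorm(n_rois, log(0.45), 0.15)
  sdlog0 <- runif(n_rois, 0.25, 0.45)
  aff <- config$affected_rois
  # affected ROIs are pushed away from the cohort's value-space center (and
  # their distributions widened) in proportion to grade x subject severity.
  # Each affected ROI gets a fixed, staggered sensitivity multiplier so the
  # six regions sit at different points of their dose-response curves: at any
  # grade some are still in the steep regime, which keeps the aggregate
  # degradation of similarity, clustering and degree monotone in grade
  # rather than saturating all at once.
  # moderate-eccentricity baselines (0.1-0.2 log-units off center, random
  # side) exclude the two regimes where the global clustering response
  # degenerates: near-central nodes (threshold redistribution initially
  # raises Cp) and far-peripheral nodes (already isolated, effect saturates)
  aff_sign <- sample(c(-1, 1), length(aff), replace = TRUE)
  meanlog0[aff] <- log(0.45) +
    aff_sign * runif(length(aff), 0.10, 0.20)
  aff_scale <- seq(0.5, 1.5, length.out = length(aff))

  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_subj <- length(groups)
  ids <- unlist(lapply(names(config$group_sizes), function(g) {
    sprintf("%s%03d", g, seq_len(config$group_sizes[[g]]))
  }))

  severity <- rnorm(n_subj, 1, 0.15)
  vars <- names(config$clinical_params)
  clin <- matrix(NA_real_, n_subj, length(vars),
                 dimnames = list(NULL, vars))
  gender <- integer(n_subj)
  samples <- vector("list", n_subj)

  for (s in seq_len(n_subj)) {
    g <- groups[s]
    grade <- config$effect_grades[[g]]
    z <- severity[s]
    z_std <- (z - 1) / 0.15
    for (v in vars) {
      ms <- config$clinical_params[[v]][[g]]
      rho <- unname(severity_loadings[v])
      u <- if (!is.na(rho) && length(rho)) {
        rho * z_std + sqrt(1 - rho^2) * rnorm(1)
      } else {
        rnorm(1)
      }
      clin[s, v] <- ms[1] + ms[2] * u
    }
    gender[s] <- rbinom(1, 1, config$male_prop[[g]])

    meanlog <- meanlog0 + rnorm(n_rois, 0, 0.01)
    sdlog <- sdlog0
    if (grade > 0) {
      meanlog[aff] <- meanlog[aff] + aff_sign * aff_scale * grade * z
      sdlog[aff] <- sdlog[aff] * pmax(0.2, 1 + 0.5 * aff_scale * grade * z)
    }
    nv <- sample(config$voxels_per_roi[1]:config$voxels_per_roi[2], n_rois,
                 replace = TRUE)
    roi_vals <- lapply(seq_len(n_rois), function(r) {
      rlnorm(nv[r], meanlog[r], sdlog[r])
    })
    names(roi_vals) <- atlas$roi_names
    samples[[s]] <- roi_sample_set(roi_vals, ids[s], atlas$name,
                                   config$min_voxels)
  }

  clin_df <- as.data.frame(clin)
  # plausible-range truncation (well beyond 3 SD for the default marginals,
  # so marginal means/SDs are essentially unaffected)
  clin_df$age <- pmin(pmax(clin_df$age, 18), 90)
  clin_df$education <- pmin(pmax(clin_df$education, 0), 22)
  for (v in c("MMSE", "MoCA")) clin_df[[v]] <- pmin(pmax(clin_df[[v]], 0), 30)
  for (v in c("DST", "NCTA", "NCTB", "eGFR", "Scr")) {
    clin_df[[v]] <- pmax(clin_df[[v]], 1)
  }
  cohort <- data.frame(subject_id = ids,
                       group = factor(groups,
                                      levels = names(config$group_sizes)),
                       gender = gender, clin_df, severity = severity,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, samples = samples, atlas = atlas, config = config)
}

#' Write / read the cohort table as CSV
#'
#' @param cohort the `cohort` data frame from [generate_cohort()].
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = intersect(c("HC", "DM", "DKD"),
                                                  unique(df$group)))
  df
}

#' Generate a spatially aligned toy gray-matter map / atlas pair
#'
#' Writes two NIfTI volumes on the same grid: an integer label atlas whose
#' labels 1..n_rois tile a random 80% of the voxels (the rest are 0 =
#' background), and a float gray-matter map that is positive exactly at the
#' labeled voxels. Deterministic given `seed`. Exercises the NIfTI branch of
#' ROI extraction.
#'
#' @param n_rois number of regions.
#' @param shape 3-element volume dimensions, each >= 8.
#' @param seed RNG seed.
#' @param dir output directory.
#' @param min_voxels feasibility floor per ROI.
#' @return list with `gm` and `atlas` file paths and the matching
#'   [atlas_spec()].
#' @export
generate_toy_volumes <- function(n_rois, shape = c(12L, 12L, 12L), seed = 1L,
                                 dir = tempdir(), min_voxels = 10L) {
  if (length(shape) != 3 || any(shape < 8)) {
    stop_morphnet("shape must be 3 dimensions, each >= 8",
                  class = "morphnet_config_error")
  }
  nvox <- prod(shape)
  vpr <- floor(0.8 * nvox / n_rois)
  if (vpr < min_voxels) {
    stop_morphnet("%d ROIs infeasible for shape %s (%d voxels/ROI < %d)",
                  n_rois, paste(shape, collapse = "x"), vpr, min_voxels,
                  class = "morphnet_config_error")
  }
  set.seed(seed)
  perm <- sample(nvox)
  labels <- integer(nvox)
  for (k in seq_len(n_rois)) {
    labels[perm[((k - 1) * vpr + 1):(k * vpr)]] <- k
  }
  gm <- numeric(nvox)
  gm[labels > 0] <- rlnorm(sum(labels > 0), log(0.5), 0.3)
  atlas_path <- file.path(dir, sprintf("toy_atlas_%d.nii.gz", seed))
  gm_path <- file.path(dir, sprintf("toy_gm_%d.nii.gz", seed))
  write_nifti(array(labels, shape), atlas_path, datatype = "int16")
  write_nifti(array(gm, shape), gm_path, datatype = "float64")
  list(gm = gm_path, atlas = atlas_path,
       spec = atlas_spec("toy", n_rois))
}
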