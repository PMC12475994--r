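#' Bundle per-ROI gray-matter value vectors for one subject
#'
#' @param samples named list of numeric vectors, one per ROI, in atlas order.
#' @param subject_id subject identifier.
#' @param atlas_name atlas the ROIs come from.
#' @param min_voxels minimum admissible vector length per ROI.
#' @return a `roi_sample_set` object.
#' @export
roi_sample_set <- function(samples, subject_id, atlas_name = "custom",
                           min_voxels = 10L) {
  lens <- lengths(samples)
  if (any(lens < min_voxels)) {
    bad <- names(samples)[lens < min_voxels] %||%
      which(lens < min_voxels)
    stop_morphnet(
      "degenerate ROI(s) with fewer than %d values: %s",
      min_voxels, paste(bad, collapse = ", "),
      class = "morphnet_degenerate_roi")
  }
  ok <- vapply(samples, function(v) all(is.finite(v)) && all(v >= 0), TRUE)
  if (!all(ok)) {
    stop_morphnet("non-finite or negative values in ROI(s): %s",
                  paste(names(samples)[!ok], collapse = ", "),
                  class = "morphnet_value_error")
  }
  structure(list(subject_id = subject_id, atlas_name = atlas_name,
                 samples = samples),
            class = "roi_sample_set")
}

#' @export
print.roi_sample_set <- function(x, ...) {
  cat(sprintf("<roi_sample_set> subject %s, atlas %s, %d ROIs, %d-%d voxels/ROI\n",
              x$subject_id, x$atlas_name, length(x$samples),
              min(lengths(x$samples)), max(lengths(x$samples))))
  invisible(x)
}

#' Extract per-ROI gray-matter value vectors from a volume pair
#'
#' For each atlas label, collects the gray-matter map values at voxels that
#' carry that label and strictly exceed `gm_floor`. Zero-valued voxels are
#' outside-brain padding in modulated gray-matter maps, so the default floor
#' of 0 (strict inequality) drops them. No resampling is performed:
#' misaligned inputs are rejected.
#'
#' @param gm_map 3D array or `nifti_volume` with gray-matter values.
#' @param atlas 3D integer array or `nifti_volume` with region labels
#'   (0 = background).
#' @param spec an [atlas_spec()]; ROI order follows `spec$label_values`.
#' @param gm_floor voxels must exceed this value to be kept (default 0).
#' @param min_voxels minimum surviving voxels per ROI (default 10); smaller
#'   ROIs raise a degenerate-ROI error naming the region.
#' @param subject_id identifier stored in the result.
#' @return a [roi_sample_set()]; attribute `voxel_counts` holds per-ROI counts.
#' @export
extract_roi_samples <- function(gm_map, atlas, spec, gm_floor = 0,
                                min_voxels = 10L, subject_id = "subject") {
  gm_aff <- atlas_aff <- NULL
  if (inherits(gm_map, "nifti_volume")) {
    gm_aff <- gm_map$affine
    gm_map <- gm_map$data
  }
  if (inherits(atlas, "nifti_volume")) {
    atlas_aff <- atlas$affine
    atlas <- atlas$data
  }
  if (!identical(dim(gm_map), dim(atlas))) {
    stop_morphnet(
      "gray-matter map (%s) and atlas (%s) grids differ",
      paste(dim(gm_map), collapse = "x"), paste(dim(atlas), collapse = "x"),
      class = "morphnet_alignment_error")
  }
  if (!is.null(gm_aff) && !is.null(atlas_aff) &&
      max(abs(gm_aff - atlas_aff)) > 1e-4) {
    stop_morphnet("gray-matter map and atlas affines differ beyond 1e-4",
                  class = "morphnet_alignment_error")
  }
  keep <- gm_map > gm_floor
  samples <- lapply(spec$label_values, function(lab) {
    as.double(gm_map[atlas == lab & keep])
  })
  names(samples) <- spec$roi_names
  counts <- lengths(samples)
  if (any(counts < min_voxels)) {
    bad <- spec$roi_names[counts < min_voxels]
    stop_morphnet(
      "degenerate ROI(s) with fewer than %d voxels above gm_floor=%g: %s",
      min_voxels, gm_floor, paste(bad, collapse = ", "),
      class = "morphnet_degenerate_roi")
  }
  out <- roi_sample_set(samples, subject_id, spec$name, min_voxels)
  attr(out, "voxel_counts") <- counts
  out
}

#' Write / read a subject's ROI samples as a two-column TSV
#'
#' Long format with columns `roi_label` and `value`, one file per subject.
#'
#' @param x a [roi_sample_set()].
#' @param path output TSV path.
#' @return `path` (write) or a `roi_sample_set` (read), invisibly for write.
#' @export
write_roi_samples <- function(x, path) {
  df <- data.frame(
    roi_label = rep(names(x$samples), lengths(x$samples)),
    value = unlist(x$samples, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_samples
#' @param subject_id,atlas_name metadata for the reconstructed object.
#' @param roi_order optional label order; defaults to first appearance.
#' @export
read_roi_samples <- function(path, subject_id = basename(path),
                             atlas_name = "custom", roi_order = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  roi_order <- roi_order %||% unique(df$roi_label)
  samples <- lapply(roi_order, function(r) df$value[df$roi_label == r])
  names(samples) <- roi_order
  roi_sample_set(samples, subject_id, atlas_name)
}
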