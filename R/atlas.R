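#' Describe a parcellation atlas
#'
#' An atlas specification fixes the identity and order of network nodes:
#' ROI ordering everywhere in the package is a pure function of
#' `label_values`, never of the data.
#'
#' @param name atlas name, e.g. `"AAL90"` or `"Brainnetome246"`.
#' @param n_rois number of regions.
#' @param label_values integer labels in the volume, one per ROI, sorted;
#'   defaults to `1:n_rois`.
#' @param roi_names optional character vector of region names.
#' @return an `atlas_spec` object.
#' @export
atlas_spec <- function(name, n_rois, label_values = seq_len(n_rois),
                       roi_names = NULL) {
  n_rois <- as.integer(n_rois)
  label_values <- as.integer(label_values)
  if (n_rois < 1L) {
    stop_morphnet("n_rois must be positive", class = "morphnet_config_error")
  }
  if (length(label_values) != n_rois || anyDuplicated(label_values) ||
      any(label_values <= 0L)) {
    stop_morphnet(
      "label_values must be %d distinct positive integers", n_rois,
      class = "morphnet_config_error")
  }
  if (is.unsorted(label_values)) label_values <- sort(label_values)
  if (!is.null(roi_names) && length(roi_names) != n_rois) {
    stop_morphnet("roi_names must have length n_rois",
                  class = "morphnet_config_error")
  }
  structure(list(name = name, n_rois = n_rois, label_values = label_values,
                 roi_names = roi_names %||% paste0("ROI", label_values)),
            class = "atlas_spec")
}

#' Serialize / load an atlas specification as JSON
#'
#' @param spec an [atlas_spec()].
#' @param path JSON file path.
#' @export
write_atlas_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_atlas_spec
#' @export
read_atlas_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas_spec(x$name, x$n_rois, x$label_values, x$roi_names)
}

#' The 90-region AAL atlas specification
#'
#' Standard automated-anatomical-labeling cortical/subcortical parcellation
#' with 90 regions (cerebellum excluded), using the conventional abbreviated
#' region names with `.L`/`.R` hemisphere suffixes.
#'
#' @return an [atlas_spec()] with 90 regions.
#' @export
aal90_atlas <- function() {
  base <- c("PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc",
            "IFGtriang", "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed",
            "REC", "INS", "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL",
            "CUN", "LING", "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL",
            "SMG", "ANG", "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES",
            "STG", "TPOsup", "MTG", "TPOmid", "ITG")
  names90 <- as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
  atlas_spec("AAL90", 90L, roi_names = names90)
}
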