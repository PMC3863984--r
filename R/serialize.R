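# Serialization of the trained artifacts: ROI dictionaries as NIfTI
# label volumes plus JSON metadata, and the second-layer model as JSON.

#' Write / read an ROI dictionary
#'
#' Writes one NIfTI label volume per contrast (voxels carry the
#' dictionary column index of their ROI; where ROIs from different
#' subjects overlap, the later column wins — the label volumes are a
#' visualization aid) plus `dictionary.json` holding the full
#' metadata and voxel lists (contrast, source subject, sign, column
#' index), which is what [read_dictionary()] reconstructs from.
#'
#' @param dict an `roi_dictionary` from [build_dictionary()].
#' @param directory output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_dictionary <- function(dict, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (cn in names(dict$contrast_sizes)) {
    lab <- array(0L, dict$grid_shape)
    for (j in seq_along(dict$rois)) {
      r <- dict$rois[[j]]
      if (r$contrast == cn) lab[r$voxels] <- j
    }
    write_volume(lab, file.path(directory, paste0("dictionary_", cn, ".nii.gz")))
  }
  meta <- list(
    grid_shape = dict$grid_shape,
    contrast_sizes = as.list(dict$contrast_sizes),
    rois = lapply(seq_along(dict$rois), function(j) {
      r <- dict$rois[[j]]
      list(column = j, contrast = r$contrast, subject = r$subject,
           sign = r$sign, voxels = r$voxels)
    }))
  jp <- file.path(directory, "dictionary.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}

#' @rdname write_dictionary
#' @param path path to a `dictionary.json`.
#' @export
read_dictionary <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(seq_len(nrow(meta$rois)), function(j) {
    list(voxels = as.integer(meta$rois$voxels[[j]]),
         sign = as.integer(meta$rois$sign[j]),
         contrast = meta$rois$contrast[j],
         subject = meta$rois$subject[j])
  })
  sizes <- unlist(meta$contrast_sizes)
  structure(list(rois = rois, grid_shape = as.integer(meta$grid_shape),
                 contrast_sizes = sizes),
            class = "roi_dictionary")
}

#' Write / read the second-layer model as JSON
#'
#' @param model a `second_layer_model`.
#' @param path output JSON path.
#' @return `path` invisibly (write) or a `second_layer_model` (read).
#' @export
write_second_layer <- function(model, path) {
  jsonlite::write_json(list(w1 = model$w1, w2 = model$w2,
                            bias = model$bias, eps_i = model$eps_i),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_second_layer
#' @export
read_second_layer <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w1 = m$w1, w2 = m$w2, bias = m$bias, eps_i = m$eps_i),
            class = "second_layer_model")
}
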