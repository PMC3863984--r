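# SIFT feature banks: extraction over a cube partition and the
# tabular (meta + descriptor matrix) container shared by the
# similarity, likelihood and classification stages.

empty_bank <- function() {
  structure(list(
    meta = data.frame(subject_id = character(0), group = character(0),
                      cube_id = character(0), orientation = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      sigma = numeric(0), orient = numeric(0)),
    desc = matrix(0, 0, 128)), class = "sift_bank")
}

#' Extract SIFT features from a slice stack
#'
#' Runs the 2D detector on every slice of the stack and maps keypoint
#' centers back to global voxel coordinates through the stack's cube
#' geometry. Each feature carries its provenance (subject, cube, slice
#' orientation); the full numeric form of a feature is 3 coordinates +
#' scale + orientation + 128 descriptor entries = 133 numbers.
#'
#' @param stack one slice stack from [slice_cube()].
#' @param subject_id subject identifier.
#' @param group `"HI"`, `"NH"` or `"unknown"`.
#' @param params [sift_params()].
#' @return a `sift_bank`: list with `meta` (one row per feature) and
#'   `desc` (matching 128-column descriptor matrix).
#' @export
extract_sift <- function(stack, subject_id, group = "unknown",
                         params = sift_params()) {
  meta <- NULL; desc <- NULL
  for (s in seq_along(stack$slices)) {
    det <- sift_detect(stack$slices[[s]], params)
    nk <- nrow(det$keypoints)
    if (!nk) next
    for (i in seq_len(nk)) {
      kp <- det$keypoints[i, ]
      gx <- local_to_global(stack$cube, stack$orientation, s,
                            c(kp$row, kp$col))
      meta <- rbind(meta, data.frame(
        subject_id = subject_id, group = group,
        cube_id = stack$cube$cube_id, orientation = stack$orientation,
        x = gx[1], y = gx[2], z = gx[3],
        sigma = kp$sigma, orient = kp$orient %% (2 * pi)))
    }
    desc <- rbind(desc, det$descriptors)
  }
  if (is.null(meta)) return(empty_bank())
  rownames(meta) <- NULL
  structure(list(meta = meta, desc = desc), class = "sift_bank")
}

#' Extract a subject's SIFT features over the whole cube partition
#'
#' @param volume 3D numeric array on the training grid.
#' @param subject_id subject identifier.
#' @param group group label.
#' @param cube_side cube side length (default 20).
#' @param params [sift_params()].
#' @return a `sift_bank` covering all cubes and all three orientations.
#' @export
extract_subject_features <- function(volume, subject_id, group = "unknown",
                                     cube_side = 20L,
                                     params = sift_params()) {
  cubes <- partition_cubes(dim(volume), cube_side)
  banks <- list()
  for (ci in seq_len(nrow(cubes))) {
    stacks <- slice_cube(volume, cubes[ci, ])
    for (o in ORIENTATIONS)
      banks[[length(banks) + 1L]] <-
        extract_sift(stacks[[o]], subject_id, group, params)
  }
  bind_banks(banks)
}

#' Combine SIFT feature banks
#' @param banks list of `sift_bank` objects.
#' @return a single `sift_bank`.
#' @export
bind_banks <- function(banks) {
  banks <- Filter(function(b) nrow(b$meta) > 0, banks)
  if (!length(banks)) return(empty_bank())
  structure(list(meta = do.call(rbind, lapply(banks, `[[`, "meta")),
                 desc = do.call(rbind, lapply(banks, `[[`, "desc"))),
            class = "sift_bank")
}

#' Assemble the 133-number vector form of SIFT features
#'
#' @param bank a `sift_bank`.
#' @return numeric matrix, one row per feature: x, y, z, sigma,
#'   orientation, then the 128 descriptor entries.
#' @export
sift_vectors <- function(bank) {
  m <- cbind(bank$meta$x, bank$meta$y, bank$meta$z,
             bank$meta$sigma, bank$meta$orient, bank$desc)
  colnames(m) <- c("x", "y", "z", "sigma", "orient",
                   paste0("a", seq_len(128)))
  m
}

#' Write / read a feature bank as a tabular file
#'
#' One row per feature: provenance, geometry and the 128 descriptor
#' columns, as a plain CSV.
#'
#' @param bank a `sift_bank`.
#' @param path output CSV path.
#' @return `path` invisibly (write), or a `sift_bank` (read).
#' @export
write_bank <- function(bank, path) {
  desc <- bank$desc
  colnames(desc) <- paste0("a", seq_len(ncol(desc)))
  utils::write.csv(cbind(bank$meta, as.data.frame(desc)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dcols <- grep("^a[0-9]+$", names(df))
  structure(list(meta = df[, setdiff(seq_along(df), dcols), drop = FALSE],
                 desc = as.matrix(df[, dcols, drop = FALSE])),
            class = "sift_bank")
}
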