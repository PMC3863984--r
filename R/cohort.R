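# Synthetic cohort generator: normalized T1-like structural volumes
# with group-discriminative Gaussian blobs, and contrast maps with
# group-dependent activation sites, subject-specific nuisance
# activations and spatially coarse noise.

add_blob <- function(vol, center, radius, amp) {
  if (amp == 0) return(vol)
  d <- dim(vol)
  lo <- pmax(1L, floor(center - 3 * radius))
  hi <- pmin(d, ceiling(center + 3 * radius))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  g <- exp(-(outer(outer(dx2, dy2, "+"), dz2, "+")) / (2 * radius^2))
  vol[xs, ys, zs] <- vol[xs, ys, zs] + amp * g
  vol
}

# coarse Gaussian field: white noise on a block grid, block-upsampled
# with a small voxel-level jitter for tie breaking
coarse_field <- function(grid_shape, sd, factor = 5L) {
  nb <- ceiling(grid_shape / factor)
  cells <- array(stats::rnorm(prod(nb), 0, sd), nb)
  idx1 <- rep(seq_len(nb[1]), each = factor)[seq_len(grid_shape[1])]
  idx2 <- rep(seq_len(nb[2]), each = factor)[seq_len(grid_shape[2])]
  idx3 <- rep(seq_len(nb[3]), each = factor)[seq_len(grid_shape[3])]
  f <- cells[idx1, idx2, idx3, drop = FALSE]
  f + array(stats::rnorm(prod(grid_shape), 0, sd * 0.02), grid_shape)
}

# fixed site layouts: discriminative structural sites sit at cube
# centers (so they survive cube partitioning); activation sites sit at
# fixed grid fractions that differ per contrast
structural_sites <- function(grid_shape, n, cube_side = 20L) {
  cubes <- partition_cubes(grid_shape, cube_side)
  centers <- cbind(cubes$ox + (cubes$ex - 1) / 2,
                   cubes$oy + (cubes$ey - 1) / 2,
                   cubes$oz + (cubes$ez - 1) / 2)
  centers[rep(seq_len(nrow(centers)), length.out = n), , drop = FALSE]
}

activation_sites <- function(grid_shape, n, contrast_index) {
  fr <- list(c(0.30, 0.30, 0.50), c(0.70, 0.30, 0.40), c(0.30, 0.70, 0.60),
             c(0.70, 0.70, 0.50), c(0.50, 0.50, 0.35), c(0.25, 0.55, 0.65))
  shift <- (contrast_index - 1) * 0.06
  t(vapply(seq_len(n), function(i) {
    f <- fr[[(i - 1) %% length(fr) + 1]] + shift
    pmax(3, pmin(grid_shape - 2, f * grid_shape))
  }, numeric(3)))
}

#' Simulate a synthetic imaging cohort
#'
#' Generates `n_hi + n_nh` subjects on a common voxel grid. Anatomical
#' volumes are a smooth bright-center background plus fixed-location
#' Gaussian blobs and i.i.d. voxel noise; at `n_discriminative_blobs`
#' designated sites (cube centers) the blob amplitude differs between
#' groups by `blob_effect`. Contrast maps (one per contrast condition)
#' are zero-background fields of spatially coarse noise plus
#' group-dependent activation blobs at fixed sites (amplitude differing
#' by `activation_effect`, signs alternating across sites) and
#' subject-specific nuisance activations. Sedation (1..3) is assigned
#' by randomized blocks within each group (random order, near-uniform
#' marginal, structurally confound-free) unless `sedation_confounded`
#' couples it to group.
#'
#' @param n_hi,n_nh subjects per group (>= 1).
#' @param grid_shape voxel grid; all dimensions must be >= 20 when the
#'   full cube pipeline is exercised (default 40 x 40 x 20; the full
#'   template grid 157 x 189 x 136 is supported).
#' @param n_discriminative_blobs number of group-discriminative
#'   structural sites.
#' @param blob_effect group difference in structural blob amplitude
#'   (arbitrary intensity units; 0 = null).
#' @param n_activation_sites activation sites per contrast.
#' @param activation_effect group difference in activation amplitude
#'   (0 = null).
#' @param noise_sd i.i.d. anatomical voxel noise sd; contrast-map
#'   coarse noise uses `4 * noise_sd`.
#' @param cube_side cube side used to place structural sites.
#' @param blob_base,blob_radius shared blob amplitude baseline and
#'   radius (voxels).
#' @param activation_base,activation_radius activation baseline
#'   amplitude and radius.
#' @param n_nuisance random nuisance activations per contrast map.
#' @param coarse_factor block size of the coarse contrast noise field.
#' @param sedation_confounded couple sedation to group (for testing
#'   the sedation feature's effect).
#' @param seed integer seed; identical spec + seed gives
#'   voxel-identical cohorts.
#' @return an `hi_cohort`: list with `subjects` (each: `subject_id`,
#'   `group`, `sedation`, `anatomical`, `contrasts`) and the
#'   generating `spec`.
#' @export
simulate_cohort <- function(n_hi = 10L, n_nh = 10L,
                            grid_shape = c(40L, 40L, 20L),
                            n_discriminative_blobs = 4L,
                            blob_effect = 0.6,
                            n_activation_sites = 3L,
                            activation_effect = 0.6,
                            noise_sd = 0.05,
                            cube_side = 20L,
                            blob_base = 0.15, blob_radius = 3,
                            activation_base = 0.6, activation_radius = 3,
                            n_nuisance = 2L, coarse_factor = 5L,
                            sedation_confounded = FALSE,
                            seed = 1L) {
  if (n_hi < 1 || n_nh < 1) stop_config("need at least one subject per group")
  grid_shape <- check_grid_shape(grid_shape)
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  set.seed(seed)
  groups <- rep(c("HI", "NH"), c(n_hi, n_nh))
  n <- length(groups)
  ids <- sprintf("S%02d", seq_len(n))

  disc_sites <- structural_sites(grid_shape, n_discriminative_blobs, cube_side)
  common_sites <- structural_sites(grid_shape, n_discriminative_blobs, cube_side)
  common_sites <- common_sites + matrix(rep(c(4, -4, 2), each = nrow(common_sites)),
                                        ncol = 3)
  common_sites <- pmin(pmax(common_sites, 3),
                       matrix(grid_shape - 2, nrow(common_sites), 3, byrow = TRUE))

  # smooth bright-center background shared by everyone
  bg <- array(0, grid_shape)
  ctr <- (grid_shape + 1) / 2
  dx2 <- ((seq_len(grid_shape[1]) - ctr[1]) / (grid_shape[1] / 2))^2
  dy2 <- ((seq_len(grid_shape[2]) - ctr[2]) / (grid_shape[2] / 2))^2
  dz2 <- ((seq_len(grid_shape[3]) - ctr[3]) / (grid_shape[3] / 2))^2
  bg <- 0.2 + 0.6 * exp(-outer(outer(dx2, dy2, "+"), dz2, "+") / 0.9)

  act_sites <- lapply(seq_along(CONTRAST_NAMES), function(ci)
    activation_sites(grid_shape, n_activation_sites, ci))
  act_signs <- lapply(seq_along(CONTRAST_NAMES), function(ci)
    rep_len(c(1, -1), n_activation_sites))

  # sedation: randomized block assignment within each group so the
  # 3-level covariate stays confound-free by design even at small n;
  # the confounded variant skews HI toward method 1
  sedation_all <- integer(n)
  for (grp in c("HI", "NH")) {
    gi <- which(groups == grp)
    sedation_all[gi] <- if (sedation_confounded && grp == "HI")
      sample(1:3, length(gi), replace = TRUE, prob = c(0.7, 0.2, 0.1))
    else sample(rep_len(1:3, length(gi)))
  }

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    hi <- groups[i] == "HI"
    vol <- bg
    for (s in seq_len(nrow(disc_sites)))
      vol <- add_blob(vol, disc_sites[s, ], blob_radius,
                      blob_base + if (hi) blob_effect else 0)
    for (s in seq_len(nrow(common_sites)))
      vol <- add_blob(vol, common_sites[s, ], blob_radius, 0.4)
    vol <- vol + array(stats::rnorm(prod(grid_shape), 0, noise_sd), grid_shape)

    contrasts <- list()
    for (ci in seq_along(CONTRAST_NAMES)) {
      map <- coarse_field(grid_shape, 4 * noise_sd, coarse_factor)
      sites <- act_sites[[ci]]
      for (s in seq_len(nrow(sites))) {
        amp <- (activation_base + if (hi) activation_effect else 0) *
          act_signs[[ci]][s]
        map <- add_blob(map, sites[s, ], activation_radius, amp)
      }
      for (k in seq_len(n_nuisance)) {
        cc <- stats::runif(3, 4, grid_shape - 3)
        map <- add_blob(map, cc, activation_radius,
                        sample(c(-1, 1), 1) * activation_base)
      }
      contrasts[[CONTRAST_NAMES[ci]]] <- map
    }

    subjects[[i]] <- list(subject_id = ids[i], group = groups[i],
                          sedation = sedation_all[i], anatomical = vol,
                          contrasts = contrasts)
  }
  structure(list(subjects = subjects,
                 spec = list(n_hi = n_hi, n_nh = n_nh,
                             grid_shape = grid_shape,
                             n_discriminative_blobs = n_discriminative_blobs,
                             blob_effect = blob_effect,
                             n_activation_sites = n_activation_sites,
                             activation_effect = activation_effect,
                             noise_sd = noise_sd, seed = seed,
                             cube_side = cube_side,
                             disc_sites = disc_sites,
                             act_sites = act_sites, act_signs = act_signs)),
            class = "hi_cohort")
}

#' @export
print.hi_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("Synthetic imaging cohort: %d subjects (%d HI, %d NH)\n",
              length(g), sum(g == "HI"), sum(g == "NH")))
  cat(sprintf("  grid %s, blob effect %.3g, activation effect %.3g, noise sd %.3g\n",
              paste(x$spec$grid_shape, collapse = " x "),
              x$spec$blob_effect, x$spec$activation_effect, x$spec$noise_sd))
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort an `hi_cohort`.
#' @return character vector of `"HI"`/`"NH"`.
#' @export
cohort_groups <- function(cohort)
  vapply(cohort$subjects, `[[`, character(1), "group")

#' Write a cohort to NIfTI files plus a CSV manifest
#'
#' One NIfTI file per volume (anatomical + three contrasts per
#' subject) and a manifest with subject id, group, sedation and the
#' four file paths.
#'
#' @param cohort an `hi_cohort`.
#' @param directory output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    anat <- file.path(directory, paste0(s$subject_id, "_anat.nii.gz"))
    write_volume(s$anatomical, anat)
    cpaths <- vapply(CONTRAST_NAMES, function(cn) {
      p <- file.path(directory, paste0(s$subject_id, "_", cn, ".nii.gz"))
      write_volume(s$contrasts[[cn]], p)
      p
    }, character(1))
    data.frame(subject_id = s$subject_id, group = s$group,
               sedation = s$sedation, anatomical = anat,
               t(cpaths))
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0),
               sedation = integer(0), anatomical = character(0),
               speech_vs_silence = character(0),
               speech_vs_tones = character(0),
               tones_vs_silence = character(0))
  mp <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path path to `manifest.csv`.
#' @return an `hi_cohort` (without a generating spec).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    contrasts <- lapply(CONTRAST_NAMES, function(cn) {
      v <- read_volume(man[[cn]][i])
      attr(v, "affine") <- NULL
      v
    })
    names(contrasts) <- CONTRAST_NAMES
    anat <- read_volume(man$anatomical[i])
    attr(anat, "affine") <- NULL
    list(subject_id = man$subject_id[i], group = man$group[i],
         sedation = man$sedation[i], anatomical = anat,
         contrasts = contrasts)
  })
  structure(list(subjects = subjects, spec = NULL), class = "hi_cohort")
}
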