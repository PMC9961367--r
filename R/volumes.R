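#' Atrophy mask of the synthetic volume phantom
#'
#' The phantom places two ellipsoidal "medial temporal" regions inside a
#' smooth gray-matter blob; those regions are attenuated in proportion to
#' disease severity. This returns the logical voxel mask of the attenuated
#' regions for a given volume shape, in the same relative coordinates used
#' by [generate_volumes()].
#'
#' @param shape Integer vector of 3 positive voxel dimensions.
#' @return Logical 3D array of dimension `shape`.
#' @export
volume_atrophy_mask <- function(shape) {
  stopifnot(length(shape) == 3, all(shape > 0))
  centers <- rbind(c(0.35, 0.5, 0.45), c(0.65, 0.5, 0.45))
  semi <- c(0.10, 0.12, 0.10)
  g <- expand.grid(x = (seq_len(shape[1]) - 0.5) / shape[1],
                   y = (seq_len(shape[2]) - 0.5) / shape[2],
                   z = (seq_len(shape[3]) - 0.5) / shape[3])
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(centers))) {
    d2 <- ((g$x - centers[i, 1]) / semi[1])^2 +
      ((g$y - centers[i, 2]) / semi[2])^2 +
      ((g$z - centers[i, 3]) / semi[3])^2
    inside <- inside | d2 <= 1
  }
  array(inside, dim = shape)
}

# Smooth baseline "gray matter" intensity: a broad radial bump in [0, 1].
volume_base_pattern <- function(shape) {
  g <- expand.grid(x = (seq_len(shape[1]) - 0.5) / shape[1],
                   y = (seq_len(shape[2]) - 0.5) / shape[2],
                   z = (seq_len(shape[3]) - 0.5) / shape[3])
  r2 <- (g$x - 0.5)^2 + (g$y - 0.5)^2 + (g$z - 0.5)^2
  array(exp(-r2 / (2 * 0.22^2)), dim = shape)
}

#' Generate toy 3D volumes for a cohort
#'
#' One nonnegative 3D array per subject: a smooth gray-matter-like blob in
#' which the fixed ellipsoidal regions of [volume_atrophy_mask()] are
#' attenuated by `atrophy_amplitude * severity / 2` (severity: CN = 0,
#' MCI = 1, AD = 2, so AD loses the full `atrophy_amplitude` fraction of
#' intensity in the region), plus iid voxel noise clipped at zero.
#' Deterministic given `seed`. These are geometric phantoms for exercising
#' the CNN path, not simulated MRI.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param shape 3 positive integers; default `c(64, 64, 64)`.
#' @param atrophy_amplitude Nonnegative attenuation amplitude (0 = no
#'   class effect).
#' @param noise_sd Voxel noise SD (default 0.05).
#' @param seed Integer seed.
#' @return A `volume_set`: list with `ids`, `volumes` (named list of 3D
#'   arrays), `shape`.
#' @export
generate_volumes <- function(cohort, shape = c(64, 64, 64),
                             atrophy_amplitude = 0.5, noise_sd = 0.05,
                             seed = 1) {
  stopifnot(length(shape) == 3)
  if (any(shape <= 0)) abort("`shape` must be positive in every dimension.")
  if (atrophy_amplitude < 0) abort("`atrophy_amplitude` must be nonnegative.")
  base <- volume_base_pattern(shape)
  mask <- volume_atrophy_mask(shape)
  severity <- c(CN = 0, MCI = 1, AD = 2)[as.character(cohort$diagnosis)]
  vols <- with_seed(derive_seed(seed, 3L), {
    lapply(seq_len(nrow(cohort)), function(i) {
      v <- base
      v[mask] <- v[mask] * (1 - min(1, atrophy_amplitude * severity[i] / 2))
      v <- v + array(rnorm(prod(shape), sd = noise_sd), dim = shape)
      pmax(v, 0)
    })
  })
  names(vols) <- cohort$id
  structure(list(ids = cohort$id, volumes = vols, shape = as.integer(shape)),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat("volume_set: ", length(x$volumes), " volumes of ",
      paste(x$shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Write / read a volume set as NIfTI-1 files
#'
#' One file per subject (`<id>.nii`), RAS orientation with an isotropic
#' voxel size recorded in the header.
#'
#' @param vols A `volume_set`.
#' @param dir Output directory (created if needed).
#' @param voxel_mm Isotropic voxel edge length in millimetres (default 3,
#'   matching 64^3 maps resampled to 3 mm).
#' @return `write_volumes()` returns `dir` invisibly; `read_volumes()`
#'   returns a `volume_set` with subjects ordered by `ids`.
#' @export
write_volumes <- function(vols, dir, voxel_mm = 3) {
  stopifnot(inherits(vols, "volume_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in vols$ids) {
    img <- RNifti::asNifti(vols$volumes[[id]])
    RNifti::pixdim(img) <- rep(voxel_mm, 3)
    RNifti::writeNifti(img, file.path(dir, paste0(id, ".nii")))
  }
  invisible(dir)
}

#' @rdname write_volumes
#' @param ids Subject ids to read; default all `*.nii`/`*.nii.gz` in `dir`.
#' @export
read_volumes <- function(dir, ids = NULL) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  found <- sub("\\.nii(\\.gz)?$", "", basename(files))
  if (is.null(ids)) ids <- sort(found)
  missing <- setdiff(ids, found)
  if (length(missing) > 0) {
    abort(paste0("No volume file for ids: ", paste(missing, collapse = ", ")))
  }
  vols <- lapply(ids, function(id) {
    f <- files[match(id, found)]
    arr <- as.array(RNifti::readNifti(f))
    array(as.numeric(arr), dim = dim(arr))
  })
  names(vols) <- ids
  shape <- dim(vols[[1]])
  structure(list(ids = ids, volumes = vols, shape = as.integer(shape)),
            class = "volume_set")
}
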