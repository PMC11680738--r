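# File I/O: the k-space/trajectory container and NIfTI image export.
#
# The container is a single RDS file with a fixed layout:
#   list(
#     format  = "ztegap-kspace", version = 1L,
#     data    = complex array (n_spokes x n_readout x n_coils),
#     mask    = logical matrix (n_spokes x n_readout),
#     trajectory = list(dirs, pair_index, oversampling, n_readout, fov_mm)
#   )
# All writes are atomic (temp file + rename).

#' Write a k-space container
#'
#' @param kspace `multicoil_kspace`.
#' @param traj matching `radial_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_kspace <- function(kspace, traj, path) {
  check_conformal(kspace, traj)
  obj <- list(format = "ztegap-kspace", version = 1L,
              data = kspace$data, mask = kspace$mask,
              trajectory = list(dirs = traj$spoke_dirs,
                                pair_index = traj$pair_index,
                                oversampling = traj$oversampling,
                                n_readout = traj$n_readout,
                                fov_mm = traj$fov_mm))
  atomic_write(path, function(tmp) saveRDS(obj, tmp))
  invisible(path)
}

#' Read a k-space container
#'
#' @param path file written by [write_kspace()].
#' @return list with `kspace` (`multicoil_kspace`) and `traj`
#'   (`radial_trajectory`).
#' @export
read_kspace <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ztegap-kspace"))
    stop("not a ztegap k-space container: ", path)
  tr <- obj$trajectory
  traj <- radial_trajectory(tr$dirs, tr$n_readout, tr$oversampling,
                            tr$pair_index, tr$fov_mm)
  list(kspace = multicoil_kspace(obj$data, obj$mask), traj = traj)
}

#' Write an image volume as NIfTI
#'
#' Magnitude is written; the affine encodes the voxel size from the FOV.
#'
#' @param image an `image_volume` (complex volumes are written as modulus).
#' @param path output `.nii`/`.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(image, path) {
  vals <- as_magnitude(image)
  fov <- image$fov %||% image$shape   # default: 1 mm per pixel
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- fov / image$shape
  atomic_write(path, function(tmp) RNifti::writeNifti(img, tmp))
  invisible(path)
}

atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # keep the real extension so format-by-suffix writers behave
  tmp <- file.path(dirname(path),
                   paste0(".tmp", Sys.getpid(), "_", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
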