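# File interfaces: NIfTI volumes, landmark files, trajectory CSVs and
# phantom ground-truth sidecars.

#' Read / write CT and BMD volumes as NIfTI
#'
#' Voxel spacing is carried in the NIfTI header (`pixdim`); the world
#' origin is stored in the qform offset. Use `.nii` or `.nii.gz` paths.
#'
#' @param vol A [ct_volume()] or [bmd_volume()].
#' @param path Output file.
#' @return `write_ct_nifti()` returns the path invisibly;
#'   `read_ct_nifti()` returns a [ct_volume()] (pass `bmd = TRUE` for a
#'   [bmd_volume()]).
#' @export
write_ct_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  affine <- diag(c(vol$spacing_mm, 1))
  affine[1:3, 4L] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @param bmd Return a `bmd_volume` instead of a `ct_volume`.
#' @export
read_ct_nifti <- function(path, bmd = FALSE) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  ctor <- if (bmd) bmd_volume else ct_volume
  affine <- RNifti::xform(img)
  ctor(vals, spacing_mm = RNifti::pixdim(img)[seq_len(3L)],
       origin = affine[1:3, 4L])
}

#' Read / write glenoid landmarks as structured text (YAML)
#'
#' @param lm A [glenoid_landmarks()].
#' @param path File path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "glenoid_landmarks"))
  yaml::write_yaml(lapply(unclass(lm), as.numeric), path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  do.call(glenoid_landmarks, yaml::read_yaml(path))
}

#' Write a marker recording as a trajectory CSV
#'
#' Long format, one row per marker per frame, with the fixed column set
#' `time_s, body, marker_id, x_mm, y_mm, z_mm, shear_N, phase`.
#'
#' @param rec A [marker_recording()].
#' @param path Output CSV path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "marker_recording"))
  rows <- do.call(rbind, lapply(names(rec$bodies), function(bn) {
    b <- rec$bodies[[bn]]
    nm <- dim(b)[2L]
    ids <- dimnames(b)[[2L]] %||% paste0("m", seq_len(nm))
    do.call(rbind, lapply(seq_len(nm), function(j)
      data.frame(time_s = rec$time_s, body = bn, marker_id = ids[j],
                 x_mm = b[, j, 1L], y_mm = b[, j, 2L], z_mm = b[, j, 3L],
                 shear_N = rec$shear_n, phase = rec$phase,
                 stringsAsFactors = FALSE)))
  }))
  rows <- rows[order(rows$time_s, rows$body, rows$marker_id), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV back into a marker recording
#'
#' @param path CSV written by [write_recording_csv()] (or any file in the
#'   same dialect).
#' @param meta Optional protocol metadata list to attach.
#' @return A [marker_recording()].
#' @export
read_recording_csv <- function(path, meta = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "body", "marker_id", "x_mm", "y_mm", "z_mm",
            "shear_N", "phase")
  if (!all(need %in% names(df)))
    stop(sprintf("trajectory CSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  times <- sort(unique(df$time_s))
  bodies <- lapply(split(df, df$body), function(bd) {
    ids <- sort(unique(bd$marker_id))
    arr <- array(NA_real_, c(length(times), length(ids), 3L),
                 dimnames = list(NULL, ids, c("x_mm", "y_mm", "z_mm")))
    ti <- match(bd$time_s, times)
    mi <- match(bd$marker_id, ids)
    arr[cbind(ti, mi, 1L)] <- bd$x_mm
    arr[cbind(ti, mi, 2L)] <- bd$y_mm
    arr[cbind(ti, mi, 3L)] <- bd$z_mm
    arr
  })
  first <- df[match(times, df$time_s), ]
  if (is.null(meta$sample_hz) && length(times) > 1L)
    meta$sample_hz <- 1 / stats::median(diff(times))
  marker_recording(time_s = times, bodies = bodies,
                   shear_n = first$shear_N,
                   phase = unique(df$phase)[1L], meta = meta)
}

#' Write a phantom and its ground truth to disk
#'
#' Emits the observed CT (`ct.nii.gz`), the noiseless truth BMD
#' (`truth_bmd.nii.gz`), a label map (`labels.nii.gz`: 1 cortical shell,
#' 2 marrow, 3 trabecular bone, 4 air, 5 fat, 6 muscle), the landmarks
#' (`landmarks.yml`) and scalar truth values (`truth.yml`).
#'
#' @param phantom A `glenoid_phantom`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "glenoid_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ct_nifti(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_ct_nifti(phantom$truth$bmd, file.path(dir, "truth_bmd.nii.gz"))
  m <- phantom$truth$masks
  labels <- array(0L, dim(phantom$ct$values))
  labels[m$glenoid & !m$trabecular] <- 1L
  labels[m$trabecular] <- 2L
  labels[m$bone] <- 3L
  labels[m$air] <- 4L
  labels[m$fat] <- 5L
  labels[m$muscle] <- 6L
  write_ct_nifti(ct_volume(labels, phantom$ct$spacing_mm,
                           phantom$ct$origin),
                 file.path(dir, "labels.nii.gz"))
  write_landmarks(phantom$truth$landmarks, file.path(dir, "landmarks.yml"))
  tr <- phantom$truth
  yaml::write_yaml(list(bone_fraction_achieved = tr$bone_fraction_achieved,
                        n_bone = tr$n_bone,
                        n_trabecular = tr$n_trabecular,
                        width_mm = tr$width_mm,
                        vault_depth_mm = tr$vault_depth_mm,
                        axis = as.numeric(tr$axis)),
                   file.path(dir, "truth.yml"))
  invisible(dir)
}
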