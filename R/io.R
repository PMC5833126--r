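# Readers and writers for velocity volumes, masks and result tables.
#
# On-disk layout: velocity data go to NIfTI, either as a single 5-D volume
# (x, y, z, t, direction) or as three 4-D volumes (one per direction), with a
# YAML sidecar carrying the acquisition metadata that NIfTI headers do not
# hold reliably (frame interval, VENC, ED/ES frames). The sidecar is the
# entry point for loading.

#' Write a velocity field to disk
#'
#' @param field a [velocity_field()].
#' @param prefix file path prefix; files \code{<prefix>.nii.gz} (or
#'   \code{<prefix>_vx/vy/vz.nii.gz}) and \code{<prefix>.yaml} are written.
#' @param format \code{"nifti5d"} for a single 5-D volume, \code{"nifti3"}
#'   for three 4-D volumes (one per velocity direction).
#' @return the sidecar path, invisibly.
#' @export
write_velocity_field <- function(field, prefix,
                                 format = c("nifti5d", "nifti3")) {
  format <- match.arg(format)
  pd <- c(field$voxel_spacing, field$frame_interval)
  if (format == "nifti5d") {
    files <- paste0(basename(prefix), ".nii.gz")
    img <- RNifti::asNifti(field$data)
    RNifti::pixdim(img) <- c(pd, 1)
    RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  } else {
    comp <- c("vx", "vy", "vz")
    files <- paste0(basename(prefix), "_", comp, ".nii.gz")
    for (d in 1:3) {
      img <- RNifti::asNifti(field$data[, , , , d, drop = TRUE])
      RNifti::pixdim(img) <- pd
      RNifti::writeNifti(img, paste0(prefix, "_", comp[d], ".nii.gz"))
    }
  }
  meta <- list(
    format = format,
    files = as.list(files),
    voxel_spacing_mm = as.list(field$voxel_spacing),
    frame_interval_ms = field$frame_interval,
    n_frames = field$n_frames,
    venc_cm_s = field$venc,
    origin_mm = as.list(field$origin),
    velocity_units = "cm/s"
  )
  sidecar <- paste0(prefix, ".yaml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Load a velocity field
#'
#' Reads a velocity dataset written by [write_velocity_field()]: a YAML
#' sidecar naming either one 5-D NIfTI volume or three 4-D volumes (vx, vy,
#' vz). All metadata required to interpret the data (frame interval, VENC,
#' spacing) must be present in the sidecar; a missing entry is an error that
#' names the absent field.
#'
#' @param path path to the YAML sidecar (or to a NIfTI file next to one,
#'   sharing its prefix).
#' @return a [velocity_field()].
#' @export
load_velocity_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.ya?ml$", path)) {
    prefix <- sub("(_v[xyz])?\\.nii(\\.gz)?$", "", path)
    path <- paste0(prefix, ".yaml")
    if (!file.exists(path))
      stop("no YAML sidecar found at ", path)
  }
  meta <- yaml::read_yaml(path)
  for (key in c("format", "files", "voxel_spacing_mm", "frame_interval_ms",
                "venc_cm_s")) {
    if (is.null(meta[[key]]))
      stop("velocity metadata is missing required field '", key, "' in ", path)
  }
  dirn <- dirname(path)
  files <- file.path(dirn, unlist(meta$files))
  if (!all(file.exists(files)))
    stop("velocity volume file(s) missing: ",
         paste(files[!file.exists(files)], collapse = ", "))
  if (identical(meta$format, "nifti5d")) {
    arr <- as.array(RNifti::readNifti(files[1]))
    if (length(dim(arr)) != 5L)
      stop("expected a 5-axis volume (x, y, z, timeframe, direction); got ",
           length(dim(arr)), " axes in ", files[1])
  } else if (identical(meta$format, "nifti3")) {
    if (length(files) != 3L)
      stop("format 'nifti3' requires three files (vx, vy, vz)")
    vols <- lapply(files, function(f) as.array(RNifti::readNifti(f)))
    for (v in vols) if (length(dim(v)) != 4L)
      stop("expected 4-axis volumes for per-direction files; got ",
           length(dim(v)), " axes")
    arr <- array(0, c(dim(vols[[1]]), 3L))
    for (d in 1:3) arr[, , , , d] <- vols[[d]]
  } else {
    stop("unknown velocity format '", meta$format, "'")
  }
  velocity_field(
    data = arr,
    voxel_spacing = unlist(meta$voxel_spacing_mm),
    frame_interval = meta$frame_interval_ms,
    venc = meta$venc_cm_s,
    origin = unlist(meta$origin_mm %||% c(0, 0, 0))
  )
}

#' Write / read a binary mask as NIfTI
#'
#' @param mask logical 3-D array.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing voxel size in mm (length 1 or 3).
#' @return \code{write_mask}: the path, invisibly. \code{read_mask}: a
#'   logical 3-D array with attributes \code{spacing}.
#' @export
write_mask <- function(mask, path, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.array(img) != 0, dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write an analysis result table
#'
#' One row per subject and visit, with each component's volume (ml), share of
#' EDV (%), kinetic energy at ED (uJ) and KE per millilitre (uJ/ml), the LV
#' volumetric indices and the inflow/outflow quality-control fields. Written
#' as plain CSV; numeric fields round-trip through [read_component_table()]
#' at full precision.
#'
#' @param results a single \code{lv4dflow} fit, a list of them, or a
#'   data frame already in table form.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_component_table <- function(results, path) {
  if (inherits(results, "lv4dflow")) results <- list(results)
  tab <- if (is.data.frame(results)) results
         else do.call(rbind, lapply(results, as.data.frame))
  if (nrow(tab) == 0L) stop("results must be non-empty")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
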