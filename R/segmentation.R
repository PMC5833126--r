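#' LV segmentation
#'
#' Binary endocardial masks at the end-diastolic (ED) and end-systolic (ES)
#' timeframes, on their acquisition ("cine") grid. The ED and ES timeframe
#' indices are inputs: in practice they are chosen by visual inspection of
#' valve positions and LV size, so the package never infers them.
#'
#' @param ed_mask logical (or 0/1) 3-D array: LV cavity at ED.
#' @param es_mask logical (or 0/1) 3-D array: LV cavity at ES.
#' @param ed_frame,es_frame 0-based timeframe indices of ED and ES on the
#'   flow time axis; must differ.
#' @param spacing per-axis voxel size of the cine grid in mm (length 1 or 3).
#' @param origin world position (mm) of the centre of cine voxel (0, 0, 0).
#' @param check_connectivity warn if a mask is not a single 6-connected
#'   component (default TRUE).
#'
#' @return An object of class \code{lv_segmentation}.
#' @export
lv_segmentation <- function(ed_mask, es_mask, ed_frame, es_frame,
                            spacing, origin = c(0, 0, 0),
                            check_connectivity = TRUE) {
  ed_mask <- array(as.logical(ed_mask), dim(ed_mask))
  es_mask <- array(as.logical(es_mask), dim(es_mask))
  if (length(dim(ed_mask)) != 3L || length(dim(es_mask)) != 3L)
    stop("masks must be 3-D arrays")
  if (!any(ed_mask)) stop("ED mask is empty")
  if (!any(es_mask)) stop("ES mask is empty")
  if (ed_frame == es_frame) stop("ed_frame and es_frame must differ")
  if (ed_frame < 0 || es_frame < 0) stop("frame indices must be >= 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  if (check_connectivity) {
    for (nm in c("ed_mask", "es_mask")) {
      m <- if (nm == "ed_mask") ed_mask else es_mask
      ncomp <- max(label_components(m))
      if (ncomp > 1L)
        warning(sprintf("%s has %d connected components; expected a single LV cavity",
                        nm, ncomp))
    }
  }
  structure(
    list(ed_mask = ed_mask, es_mask = es_mask,
         ed_frame = as.integer(ed_frame), es_frame = as.integer(es_frame),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "lv_segmentation"
  )
}

#' @export
print.lv_segmentation <- function(x, ...) {
  cat("LV segmentation\n")
  cat(sprintf("  cine grid: %s voxels, spacing %s mm\n",
              paste(dim(x$ed_mask), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  ED frame %d (%d voxels), ES frame %d (%d voxels)\n",
              x$ed_frame, sum(x$ed_mask), x$es_frame, sum(x$es_mask)))
  invisible(x)
}
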