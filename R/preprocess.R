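# Background phase-offset correction, mask resampling onto the flow grid and
# LV volumetric indices.
#
# Phase-contrast velocity data carry a spatially smooth spurious baseline
# (eddy-current induced). It is temporally static by physical origin, so it
# is estimated from the time-averaged velocity of static tissue and modelled
# per direction as a full third-order polynomial in space, then subtracted
# from every timeframe.

#' Identify static tissue
#'
#' Voxels whose temporal standard deviation of speed is below
#' \code{threshold} and whose temporal mean speed is below
#' \code{2 * threshold} are taken as static (chest wall and other
#' non-moving tissue). These anchor the background polynomial fit.
#'
#' @param field a [velocity_field()].
#' @param threshold speed threshold in cm/s (default 2).
#' @return logical 3-D array marking static voxels.
#' @export
identify_static_tissue <- function(field, threshold = 2) {
  d <- dim(field$data)
  nvox <- prod(d[1:3]); nt <- d[4]
  m <- matrix(field$data, nvox * nt, 3L)
  speed <- matrix(sqrt(rowSums(m^2)), nvox, nt)
  mu <- rowMeans(speed)
  sdv <- sqrt(pmax(0, (rowSums(speed^2) - nt * mu^2) / (nt - 1)))
  mask <- sdv < threshold & mu < 2 * threshold
  if (!any(mask))
    stop("no static voxels found at threshold ", threshold,
         " cm/s; increase the threshold")
  array(mask, d[1:3])
}

#' Fit the third-order background phase-offset polynomial
#'
#' Per velocity direction, ordinary least squares of the time-averaged
#' velocity in static voxels on the 20 monomials x^a y^b z^c (a + b + c <= 3)
#' of world coordinates. For numerical conditioning the coordinates are
#' centred on the field-of-view midpoint and scaled to [-1, 1] before
#' fitting; coefficients are stored in that scaled basis and can be reported
#' in world units via [coef.phase_offset_model()].
#'
#' @param field a [velocity_field()].
#' @param static_mask logical 3-D array (from [identify_static_tissue()]).
#' @param min_voxels minimum number of static voxels required (default 200).
#' @return An object of class \code{phase_offset_model} with elements
#'   \code{coefficients} (20 x 3, scaled basis), \code{centre}, \code{scale},
#'   \code{exponents}, \code{rms_residual} (cm/s, per direction) and
#'   \code{n_voxels}.
#' @export
fit_background_polynomial <- function(field, static_mask, min_voxels = 200) {
  if (!identical(dim(static_mask), as.integer(field$dim)) &&
      !identical(dim(static_mask), field$dim))
    stop("static_mask grid does not match the velocity field")
  n_static <- sum(static_mask)
  if (n_static < min_voxels)
    stop("only ", n_static, " static voxels; need at least ", min_voxels)
  d <- dim(field$data)
  nvox <- prod(d[1:3]); nt <- d[4]
  idx <- which(static_mask)
  # time-averaged velocity per static voxel and direction
  vbar <- matrix(0, length(idx), 3L)
  for (dirn in 1:3) {
    m <- matrix(field$data[, , , , dirn], nvox, nt)
    vbar[, dirn] <- rowMeans(m[idx, , drop = FALSE])
  }
  centres <- voxel_centres(field$dim, field$voxel_spacing, field$origin)
  ctr <- field$origin + (field$dim - 1) * field$voxel_spacing / 2
  scl <- pmax((field$dim - 1) * field$voxel_spacing / 2, .Machine$double.eps)
  scaled <- sweep(sweep(centres[idx, , drop = FALSE], 2L, ctr, `-`),
                  2L, scl, `/`)
  exponents <- polynomial_exponents(3L)
  X <- polynomial_design(scaled, exponents)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient polynomial design (static voxels are degenerate, ",
         "e.g. coplanar); rank ", qrX$rank, " of ", ncol(X))
  beta <- qr.coef(qrX, vbar)
  resid <- vbar - X %*% beta
  structure(
    list(coefficients = beta, centre = ctr, scale = scl,
         exponents = exponents,
         rms_residual = sqrt(colMeans(resid^2)),
         n_voxels = n_static),
    class = "phase_offset_model"
  )
}

#' Evaluate a phase-offset model at world positions
#'
#' @param object a \code{phase_offset_model}.
#' @param positions n x 3 matrix of world positions in mm.
#' @param ... unused.
#' @return n x 3 matrix of offsets in cm/s.
#' @export
predict.phase_offset_model <- function(object, positions, ...) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  scaled <- sweep(sweep(positions, 2L, object$centre, `-`),
                  2L, object$scale, `/`)
  polynomial_design(scaled, object$exponents) %*% object$coefficients
}

#' Coefficients of a phase-offset model
#'
#' @param object a \code{phase_offset_model}.
#' @param basis \code{"scaled"} (the fitting basis: coordinates centred on
#'   the FOV midpoint, scaled to [-1, 1]) or \code{"world"} (monomials of
#'   raw mm coordinates).
#' @param ... unused.
#' @return 20 x 3 coefficient matrix, rows named by monomial.
#' @export
coef.phase_offset_model <- function(object, basis = c("scaled", "world"), ...) {
  basis <- match.arg(basis)
  if (basis == "scaled") {
    out <- object$coefficients
    rownames(out) <- colnames(polynomial_design(matrix(0, 1, 3),
                                                object$exponents))
    return(out)
  }
  # expand each scaled monomial prod_k ((x_k - c_k)/s_k)^e_k into world
  # monomials by three binomial expansions
  ex <- object$exponents
  out <- matrix(0, nrow(ex), 3L)
  key <- function(e) paste(e, collapse = ",")
  row_of <- stats::setNames(seq_len(nrow(ex)),
                            apply(ex, 1L, key))
  for (j in seq_len(nrow(ex))) {
    e <- ex[j, ]
    for (ia in 0:e[1]) for (ib in 0:e[2]) for (ic in 0:e[3]) {
      w <- choose(e[1], ia) * choose(e[2], ib) * choose(e[3], ic) *
        (-object$centre[1])^(e[1] - ia) *
        (-object$centre[2])^(e[2] - ib) *
        (-object$centre[3])^(e[3] - ic) /
        (object$scale[1]^e[1] * object$scale[2]^e[2] * object$scale[3]^e[3])
      tgt <- row_of[[key(c(ia, ib, ic))]]
      out[tgt, ] <- out[tgt, ] + w * object$coefficients[j, ]
    }
  }
  rownames(out) <- colnames(polynomial_design(matrix(0, 1, 3),
                                              object$exponents))
  out
}

#' @export
print.phase_offset_model <- function(x, ...) {
  cat("Third-order background phase-offset model\n")
  cat(sprintf("  fitted on %d static voxels\n", x$n_voxels))
  cat(sprintf("  RMS residual (cm/s): %s\n",
              paste(sprintf("%.3f", x$rms_residual), collapse = ", ")))
  invisible(x)
}

#' Subtract the background phase offset from a velocity field
#'
#' Evaluates the fitted polynomial at every voxel centre and subtracts it
#' from every timeframe, per direction. The input field is not modified.
#'
#' @param field a [velocity_field()].
#' @param model a \code{phase_offset_model}.
#' @return a corrected [velocity_field()].
#' @export
apply_phase_correction <- function(field, model) {
  centres <- voxel_centres(field$dim, field$voxel_spacing, field$origin)
  offsets <- predict(model, centres)  # nvox x 3, cm/s
  d <- dim(field$data)
  corrected <- field$data
  for (dirn in 1:3) {
    off <- array(offsets[, dirn], d[1:3])
    for (j in seq_len(d[4])) {
      corrected[, , , j, dirn] <- corrected[, , , j, dirn] - off
    }
  }
  out <- field
  out$data <- corrected
  out
}

# nearest-neighbour resampling of a binary mask from its own grid onto the
# flow grid: a flow voxel is inside if its centre falls in an inside source
# voxel (centre exactly on a boundary belongs to the lower-index source
# voxel)
resample_mask_to_flow <- function(mask, spacing, origin, field) {
  centres <- voxel_centres(field$dim, field$voxel_spacing, field$origin)
  idx <- containing_voxel(centres, dim(mask), spacing, origin)
  inside <- !is.na(idx[, 1])
  out <- logical(nrow(centres))
  if (any(inside)) {
    lin <- 1 + idx[inside, 1] +
      dim(mask)[1] * (idx[inside, 2] + dim(mask)[2] * idx[inside, 3])
    out[inside] <- mask[lin]
  }
  array(out, field$dim)
}

#' Resample the ED segmentation mask onto the flow grid
#'
#' The ED cine mask is resampled to isotropic voxels equal to the flow data
#' voxels by nearest-neighbour lookup: a flow voxel is inside if its centre
#' falls in an inside cine voxel. The resampled voxel count times the flow
#' voxel volume defines the EDV used for pathline seeding.
#'
#' @param seg an [lv_segmentation()].
#' @param field a [velocity_field()].
#' @param which \code{"ed"} (default) or \code{"es"}: which mask to resample.
#' @return logical 3-D array on the flow grid.
#' @export
resample_ed_mask <- function(seg, field, which = c("ed", "es")) {
  which <- match.arg(which)
  src <- if (which == "ed") seg$ed_mask else seg$es_mask
  out <- resample_mask_to_flow(src, seg$spacing, seg$origin, field)
  if (!any(out))
    stop("resampled ", toupper(which),
         " mask is empty; cine and flow grids may not overlap")
  out
}

#' LV volumetric indices
#'
#' End-diastolic and end-systolic volumes from the voxelised masks, stroke
#' volume, ejection fraction and cardiac output.
#'
#' @param ed_mask_flow logical array: ED mask on the flow grid.
#' @param es_mask_flow logical array: ES mask on the flow grid.
#' @param voxel_volume_ml volume of one flow voxel in ml.
#' @param heart_rate beats per minute (NA allowed: cardiac output is then NA).
#' @return An object of class \code{lv_volumetrics}: list with \code{edv_ml},
#'   \code{esv_ml}, \code{sv_ml}, \code{ef_pct}, \code{cardiac_output_l_min}.
#' @export
compute_volumetric_indices <- function(ed_mask_flow, es_mask_flow,
                                       voxel_volume_ml, heart_rate = NA) {
  edv <- sum(ed_mask_flow) * voxel_volume_ml
  esv <- sum(es_mask_flow) * voxel_volume_ml
  if (edv == 0) stop("ED mask is empty")
  if (esv >= edv)
    stop(sprintf("ESV (%.1f ml) >= EDV (%.1f ml); ED/ES masks are likely swapped",
                 esv, edv))
  sv <- edv - esv
  structure(
    list(edv_ml = edv, esv_ml = esv, sv_ml = sv,
         ef_pct = 100 * sv / edv,
         cardiac_output_l_min =
           if (is.na(heart_rate)) NA_real_ else sv * heart_rate / 1000),
    class = "lv_volumetrics"
  )
}

#' @export
print.lv_volumetrics <- function(x, ...) {
  cat(sprintf("EDV %.1f ml, ESV %.1f ml, SV %.1f ml, EF %.1f%%",
              x$edv_ml, x$esv_ml, x$sv_ml, x$ef_pct))
  if (!is.na(x$cardiac_output_l_min))
    cat(sprintf(", CO %.2f L/min", x$cardiac_output_l_min))
  cat("\n")
  invisible(x)
}
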