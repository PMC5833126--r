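# Four-component classification of pathlines, component volumes and ratios,
# the inflow/outflow quality-control rule and kinetic energy curves.

COMPONENT_LEVELS <- c("direct_flow", "retained_inflow",
                      "delayed_ejection_flow", "residual_volume")

#' Classify pathlines into the four functional flow components
#'
#' The positions of the pathlines at the two ES times bracketing the
#' analysed cycle, relative to the LV cavity defined by the ES segmentation,
#' determine the component of each pathline:
#' \itemize{
#'   \item outside at preceding ES, outside at next ES: \strong{direct flow}
#'     (enters and exits the LV within the cycle);
#'   \item outside, inside: \strong{retained inflow} (enters but is not
#'     ejected);
#'   \item inside, outside: \strong{delayed ejection flow} (starts within the
#'     LV and is ejected);
#'   \item inside, inside: \strong{residual volume} (resides in the LV for at
#'     least two cycles).
#' }
#' "Inside" means the flow voxel containing the endpoint is labelled inside
#' the ES mask; endpoints outside the FOV (including frozen tracks) are
#' outside. Only the ES endpoints matter: intermediate excursions are
#' ignored.
#'
#' @param pathlines an \code{lv_pathlines} object from [track_all()].
#' @param es_mask_flow logical 3-D array: ES mask on the flow grid.
#' @return factor of length n with levels
#'   \code{direct_flow, retained_inflow, delayed_ejection_flow,
#'   residual_volume}.
#' @export
classify_pathlines <- function(pathlines, es_mask_flow) {
  g <- pathlines$grid
  end_fwd <- pathlines$pos_fwd[, , dim(pathlines$pos_fwd)[3], drop = FALSE]
  end_bwd <- pathlines$pos_bwd[, , dim(pathlines$pos_bwd)[3], drop = FALSE]
  dim(end_fwd) <- dim(end_fwd)[1:2]
  dim(end_bwd) <- dim(end_bwd)[1:2]
  inside_at <- function(pos, frozen) {
    idx <- containing_voxel(pos, g$dim, g$spacing, g$origin)
    ok <- !is.na(idx[, 1])
    ins <- logical(nrow(pos))
    if (any(ok)) {
      lin <- 1 + idx[ok, 1] + g$dim[1] * (idx[ok, 2] + g$dim[2] * idx[ok, 3])
      ins[ok] <- es_mask_flow[lin]
    }
    ins & !frozen
  }
  in_next <- inside_at(end_fwd, pathlines$left_fov_fwd)
  in_prev <- inside_at(end_bwd, pathlines$left_fov_bwd)
  lab <- ifelse(!in_prev & !in_next, "direct_flow",
         ifelse(!in_prev & in_next, "retained_inflow",
         ifelse(in_prev & !in_next, "delayed_ejection_flow",
                "residual_volume")))
  factor(lab, levels = COMPONENT_LEVELS)
}

#' Component volumes and EDV ratios
#'
#' Each pathline carries the volume of one flow voxel, so a component's
#' volume is its pathline count times the voxel volume and the four volumes
#' partition the EDV exactly.
#'
#' @param labels factor from [classify_pathlines()].
#' @param voxel_volume_ml volume of one flow voxel in ml.
#' @param edv_ml end-diastolic volume in ml (defaults to the seeded volume).
#' @return data frame with columns \code{component}, \code{n_pathlines},
#'   \code{volume_ml}, \code{pct_edv}. Components with no pathlines are kept
#'   with volume 0.
#' @export
component_volumes <- function(labels, voxel_volume_ml,
                              edv_ml = length(labels) * voxel_volume_ml) {
  counts <- table(factor(labels, levels = COMPONENT_LEVELS))
  vol <- as.numeric(counts) * voxel_volume_ml
  data.frame(
    component = factor(COMPONENT_LEVELS, levels = COMPONENT_LEVELS),
    n_pathlines = as.integer(counts),
    volume_ml = vol,
    pct_edv = 100 * vol / edv_ml
  )
}

#' Inflow/outflow quality-control rule
#'
#' Compares the LV inflow components (direct flow + retained inflow) with
#' the outflow components (direct flow + delayed ejection flow). The
#' relative difference is normalised by the mean of inflow and outflow;
#' datasets with more than 10\% difference fail the check.
#'
#' @param volumes data frame from [component_volumes()], or a named numeric
#'   vector of component volumes in ml.
#' @param tolerance maximum allowed relative difference (default 0.10).
#' @return list with \code{inflow_ml}, \code{outflow_ml}, \code{rel_diff},
#'   \code{pass}.
#' @export
qc_inflow_outflow <- function(volumes, tolerance = 0.10) {
  v <- if (is.data.frame(volumes)) {
    stats::setNames(volumes$volume_ml, as.character(volumes$component))
  } else volumes
  inflow <- unname(v["direct_flow"] + v["retained_inflow"])
  outflow <- unname(v["direct_flow"] + v["delayed_ejection_flow"])
  if (inflow == 0 && outflow == 0)
    return(list(inflow_ml = 0, outflow_ml = 0, rel_diff = NA_real_,
                pass = FALSE,
                message = "both inflow and outflow volumes are zero"))
  rel <- abs(inflow - outflow) / mean(c(inflow, outflow))
  list(inflow_ml = inflow, outflow_ml = outflow, rel_diff = rel,
       pass = rel <= tolerance)
}

#' Kinetic energy curves per flow component
#'
#' KE of a pathline at a time point is \code{0.5 * rho * V * |v|^2} with
#' \code{rho} the blood density, \code{V} the blood volume the pathline was
#' emitted from (one flow voxel) and \code{v} its velocity at that time; a
#' component's KE is the sum over its pathlines. Times before ED are covered
#' by the backward track, times after ED by the forward track; the curve
#' spans the full cycle at the stored integration nodes. Pathlines outside
#' the FOV contribute zero from the moment they leave.
#'
#' @param pathlines an \code{lv_pathlines} object.
#' @param labels factor from [classify_pathlines()].
#' @param rho_blood blood density in kg/m^3 (default 1060).
#' @return data frame with \code{component}, \code{t_ms} (relative to ED;
#'   negative = before ED), \code{ke_uJ}.
#' @export
kinetic_energy_curves <- function(pathlines, labels, rho_blood = 1060) {
  if (rho_blood <= 0) stop("rho_blood must be > 0")
  v_m3 <- pathlines$voxel_volume_ml * 1e-6
  half_rho_v <- 0.5 * rho_blood * v_m3
  ke_at <- function(vel, i) {
    # |v| in cm/s -> m/s; KE in J -> uJ
    sp2 <- (vel[, 1, i]^2 + vel[, 2, i]^2 + vel[, 3, i]^2) / 1e4
    half_rho_v * sp2 * 1e6
  }
  lab <- factor(labels, levels = COMPONENT_LEVELS)
  sum_by <- function(kevec) {
    out <- rowsum(kevec, lab)
    full <- stats::setNames(numeric(length(COMPONENT_LEVELS)),
                            COMPONENT_LEVELS)
    full[rownames(out)] <- out[, 1]
    full
  }
  # backward nodes run ED -> preceding ES; reverse so time increases
  kb <- length(pathlines$t_bwd)
  t_all <- c(rev(pathlines$t_bwd[-1L]), pathlines$t_fwd)
  ke <- matrix(0, length(COMPONENT_LEVELS), length(t_all))
  col <- 1L
  for (i in seq(kb, 2L)) {
    ke[, col] <- sum_by(ke_at(pathlines$vel_bwd, i))
    col <- col + 1L
  }
  for (i in seq_along(pathlines$t_fwd)) {
    ke[, col] <- sum_by(ke_at(pathlines$vel_fwd, i))
    col <- col + 1L
  }
  data.frame(
    component = factor(rep(COMPONENT_LEVELS, times = length(t_all)),
                       levels = COMPONENT_LEVELS),
    t_ms = rep(t_all, each = length(COMPONENT_LEVELS)),
    ke_uJ = as.vector(ke)
  )
}

#' Kinetic energy at ED, absolute and per millilitre
#'
#' The KE at ED (the seed time, always a stored node) of each component,
#' divided by the component volume to remove the dependence on LV cavity
#' size. Components with zero volume report NA rather than dividing.
#'
#' @param ke_curves data frame from [kinetic_energy_curves()].
#' @param volumes data frame from [component_volumes()].
#' @return data frame with \code{component}, \code{ke_ed_uJ},
#'   \code{ke_ed_uJ_per_ml}.
#' @export
ke_at_ed_per_ml <- function(ke_curves, volumes) {
  at_ed <- ke_curves[ke_curves$t_ms == 0, ]
  # ED appears once per component (forward node 0; the backward node 0 is
  # identical by construction and excluded from the curve)
  ke_ed <- stats::setNames(at_ed$ke_uJ, as.character(at_ed$component))
  ke_ed <- ke_ed[COMPONENT_LEVELS]
  vol <- stats::setNames(volumes$volume_ml, as.character(volumes$component))
  vol <- vol[COMPONENT_LEVELS]
  data.frame(
    component = factor(COMPONENT_LEVELS, levels = COMPONENT_LEVELS),
    ke_ed_uJ = unname(ke_ed),
    ke_ed_uJ_per_ml = ifelse(vol > 0, unname(ke_ed) / unname(vol), NA_real_)
  )
}
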