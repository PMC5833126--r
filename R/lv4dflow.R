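#' Left-ventricular 4D-flow component analysis
#'
#' Runs the full analysis on one dataset: optional background phase-offset
#' correction, resampling of the ED and ES masks onto the flow grid, LV
#' volumetric indices, pathline tracking of the whole EDV over one cardiac
#' cycle, four-component classification, the inflow/outflow quality-control
#' rule and per-component kinetic energy curves.
#'
#' @param field a [velocity_field()].
#' @param seg an [lv_segmentation()].
#' @param heart_rate beats per minute (used for cardiac output; NA allowed).
#' @param correct_background fit and subtract the third-order background
#'   phase-offset polynomial before tracking (default TRUE).
#' @param static_threshold static-tissue speed threshold in cm/s for the
#'   offset fit domain; set it comfortably above the velocity noise floor
#'   (default 2).
#' @param min_static_voxels minimum static voxels for the polynomial fit.
#' @param step pathline integration step in ms (default
#'   \code{frame_interval / 10}).
#' @param rho_blood blood density in kg/m^3 (default 1060, the standard
#'   literature value).
#' @param subject_id,visit_label identifiers carried into result tables.
#'
#' @return An object of class \code{lv4dflow}: a list with components
#'   \code{volumetrics}, \code{components} (volumes and \%EDV),
#'   \code{ke} (KE at ED per component, uJ and uJ/ml), \code{ke_curves},
#'   \code{qc}, \code{labels}, \code{pathlines}, \code{offset_model} (NULL
#'   if correction was off), \code{ed_mask_flow}, \code{es_mask_flow}, and
#'   the call parameters.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' fit <- lv4dflow(ph$field, ph$seg, heart_rate = ph$heart_rate)
#' fit
#' coef(fit)
#' @export
lv4dflow <- function(field, seg, heart_rate = NA,
                     correct_background = TRUE,
                     static_threshold = 2, min_static_voxels = 200,
                     step = field$frame_interval / 10,
                     rho_blood = 1060,
                     subject_id = "subject", visit_label = "visit1") {
  stopifnot(inherits(field, "velocity_field"),
            inherits(seg, "lv_segmentation"))
  offset_model <- NULL
  if (correct_background) {
    static <- identify_static_tissue(field, static_threshold)
    offset_model <- fit_background_polynomial(field, static,
                                              min_voxels = min_static_voxels)
    field <- apply_phase_correction(field, offset_model)
  }
  ed_mask_flow <- resample_ed_mask(seg, field, "ed")
  es_mask_flow <- resample_ed_mask(seg, field, "es")
  voxvol <- prod(field$voxel_spacing) / 1000
  volumetrics <- compute_volumetric_indices(ed_mask_flow, es_mask_flow,
                                            voxvol, heart_rate)
  pathlines <- track_all(field, ed_mask_flow, seg$ed_frame, seg$es_frame,
                         step = step)
  labels <- classify_pathlines(pathlines, es_mask_flow)
  comp <- component_volumes(labels, voxvol, edv_ml = volumetrics$edv_ml)
  qc <- qc_inflow_outflow(comp)
  ke_curves <- kinetic_energy_curves(pathlines, labels, rho_blood)
  ke <- ke_at_ed_per_ml(ke_curves, comp)
  structure(
    list(volumetrics = volumetrics, components = comp, ke = ke,
         ke_curves = ke_curves, qc = qc, labels = labels,
         pathlines = pathlines, offset_model = offset_model,
         ed_mask_flow = ed_mask_flow, es_mask_flow = es_mask_flow,
         heart_rate = heart_rate, rho_blood = rho_blood, step = step,
         subject_id = subject_id, visit_label = visit_label),
    class = "lv4dflow"
  )
}

#' @export
print.lv4dflow <- function(x, ...) {
  cat(sprintf("LV 4D-flow analysis: %s / %s\n", x$subject_id, x$visit_label))
  print(x$volumetrics)
  cat("Flow components:\n")
  tab <- merge(x$components, x$ke, by = "component", sort = FALSE)
  tab <- tab[order(match(tab$component, COMPONENT_LEVELS)), ]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-22s %6.1f ml  %5.1f %% EDV  KE(ED) %8.2f uJ  %6.2f uJ/ml\n",
                tab$component[i], tab$volume_ml[i], tab$pct_edv[i],
                tab$ke_ed_uJ[i], tab$ke_ed_uJ_per_ml[i]))
  }
  cat(sprintf("QC inflow %.1f ml vs outflow %.1f ml: %.1f%% difference (%s)\n",
              x$qc$inflow_ml, x$qc$outflow_ml, 100 * x$qc$rel_diff,
              if (isTRUE(x$qc$pass)) "pass" else "FAIL"))
  invisible(x)
}

#' @export
summary.lv4dflow <- function(object, ...) {
  structure(list(fit = object), class = "summary.lv4dflow")
}

#' @export
print.summary.lv4dflow <- function(x, ...) {
  print(x$fit)
  pl <- x$fit$pathlines
  cat(sprintf("Pathlines: %d seeds, step %.2f ms; left FOV forward %d, backward %d\n",
              nrow(pl$seeds), pl$step,
              sum(pl$left_fov_fwd), sum(pl$left_fov_bwd)))
  if (!is.null(x$fit$offset_model)) {
    cat(sprintf("Background correction: %d static voxels, RMS residual %s cm/s\n",
                x$fit$offset_model$n_voxels,
                paste(sprintf("%.3f", x$fit$offset_model$rms_residual),
                      collapse = "/")))
  }
  invisible(x)
}

#' @export
coef.lv4dflow <- function(object, ...) {
  stats::setNames(object$components$pct_edv,
                  as.character(object$components$component))
}

#' @export
as.data.frame.lv4dflow <- function(x, ...) {
  comp <- x$components
  ke <- x$ke
  short <- c(direct_flow = "direct", retained_inflow = "retained",
             delayed_ejection_flow = "delayed", residual_volume = "residual")
  row <- data.frame(subject_id = x$subject_id, visit_label = x$visit_label,
                    heart_rate_bpm = x$heart_rate,
                    edv_ml = x$volumetrics$edv_ml,
                    esv_ml = x$volumetrics$esv_ml,
                    sv_ml = x$volumetrics$sv_ml,
                    ef_pct = x$volumetrics$ef_pct,
                    cardiac_output_l_min = x$volumetrics$cardiac_output_l_min)
  for (i in seq_len(nrow(comp))) {
    s <- short[[as.character(comp$component[i])]]
    row[[paste0(s, "_volume_ml")]] <- comp$volume_ml[i]
    row[[paste0(s, "_pct_edv")]] <- comp$pct_edv[i]
    row[[paste0(s, "_ke_ed_uJ")]] <- ke$ke_ed_uJ[i]
    row[[paste0(s, "_ke_ed_uJ_per_ml")]] <- ke$ke_ed_uJ_per_ml[i]
  }
  row$qc_inflow_ml <- x$qc$inflow_ml
  row$qc_outflow_ml <- x$qc$outflow_ml
  row$qc_rel_diff <- x$qc$rel_diff
  row$qc_pass <- x$qc$pass
  row
}

#' Plot an lv4dflow fit
#'
#' Left panel: component volumes as a percentage of EDV. Right panel:
#' kinetic energy curves over the cardiac cycle (time relative to ED).
#'
#' @param x an \code{lv4dflow} object.
#' @param which \code{"both"}, \code{"volumes"} or \code{"ke"}.
#' @param ... passed to [graphics::barplot()] / [graphics::matplot()].
#' @export
plot.lv4dflow <- function(x, which = c("both", "volumes", "ke"), ...) {
  which <- match.arg(which)
  cols <- c("#D55E00", "#0072B2", "#009E73", "#999999")
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "volumes")) {
    graphics::barplot(x$components$pct_edv,
                      names.arg = c("direct", "retained", "delayed", "residual"),
                      col = cols, ylab = "% of EDV",
                      main = "Flow components", las = 2, ...)
  }
  if (which %in% c("both", "ke")) {
    kc <- x$ke_curves
    tms <- sort(unique(kc$t_ms))
    m <- sapply(COMPONENT_LEVELS, function(cc)
      kc$ke_uJ[kc$component == cc][order(kc$t_ms[kc$component == cc])])
    graphics::matplot(tms, m, type = "l", lty = 1, col = cols,
                      xlab = "time relative to ED (ms)", ylab = "KE (uJ)",
                      main = "Kinetic energy", ...)
    graphics::abline(v = 0, lty = 3)
    graphics::legend("topright", legend = c("direct", "retained",
                                            "delayed", "residual"),
                     col = cols, lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
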