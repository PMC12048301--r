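#' Tissue grid geometry
#'
#' @param n_rows,n_cols grid size in pixels (>= 32 each)
#' @param dx_mm pixel pitch in mm (default 0.39, the mapped optical pitch)
#' @param D diffusion coefficient, mm^2/ms
#' @return list of class `vf_grid`; boundaries are always no-flux
#' @export
tissue_grid <- function(n_rows = 128, n_cols = 128, dx_mm = 0.39, D = 0.1) {
  stopifnot(n_rows >= 32, n_cols >= 32, dx_mm > 0, D > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, dx_mm = dx_mm, D = D,
                 boundary = "no-flux"),
            class = "vf_grid")
}

#' Specification of the localized short-APD lesion
#'
#' The lesion emulates a drug-perfused region of shortened action potential
#' duration: a disc of radius `radius_mm` where APD80 is reduced by
#' `delta_apd_ms` (negative), with a linear radial ramp of width
#' `border_width_mm` across the border, superimposed on a weak linear
#' background APD gradient in the surrounding normal tissue.
#'
#' Defaults reproduce a region of about 7.5 % of the default tissue area
#' with APD shortened by 89 ms and a maximal border ramp slope of
#' 89 / 5.6 = 15.9 ms/mm.
#'
#' @param center_row,center_col lesion center, pixel indices (1-based);
#'   `NULL` centers the lesion on the grid
#' @param radius_mm lesion radius (to mid-ramp), mm
#' @param border_width_mm full width of the linear border ramp, mm
#' @param delta_apd_ms APD80 change inside the core, ms (negative)
#' @param bg_gradient_ms_mm magnitude of the background APD gradient, ms/mm
#' @param bg_direction_deg direction of the background gradient, degrees
#'   (0 = increasing along columns)
#' @param core_sd_ms standard deviation of the smooth, zero-mean APD
#'   heterogeneity confined to the lesion core interior. Drug perfusion is
#'   not uniform (the reference preparation shows APD shortening with a
#'   spread of tens of ms), and a perfectly uniform core would repolarize
#'   unrealistically synchronously, producing an artificially sharp T wave.
#'   The field is tapered to zero across the inner 15 % of the border
#'   ramp, so the ramp itself — including the measurement stencil around
#'   border-zone sites — stays deterministic.
#' @param core_corr_mm correlation length of that heterogeneity
#' @return list of class `vf_lesion`
#' @export
lesion_spec <- function(center_row = NULL, center_col = NULL,
                        radius_mm = 7.7, border_width_mm = 5.6,
                        delta_apd_ms = -89, bg_gradient_ms_mm = 1.5,
                        bg_direction_deg = 0, core_sd_ms = 12,
                        core_corr_mm = 2) {
  stopifnot(radius_mm > 0, border_width_mm > 0, delta_apd_ms <= 0,
            bg_gradient_ms_mm >= 0, core_sd_ms >= 0, core_corr_mm > 0)
  structure(list(center_row = center_row, center_col = center_col,
                 radius_mm = radius_mm, border_width_mm = border_width_mm,
                 delta_apd_ms = delta_apd_ms,
                 bg_gradient_ms_mm = bg_gradient_ms_mm,
                 bg_direction_deg = bg_direction_deg,
                 core_sd_ms = core_sd_ms, core_corr_mm = core_corr_mm),
            class = "vf_lesion")
}

#' Build the per-pixel APD-scaling field for a lesion
#'
#' Computes the target APD80 map (baseline plus background gradient, minus
#' the lesion deficit with its linear border ramp) and inverts the
#' single-cell calibration curve to obtain the per-pixel `tau_close`
#' scaling field that realizes it.
#'
#' @param grid `vf_grid`
#' @param lesion `vf_lesion`, or `NULL` for a uniform lesion-free field
#' @param ionic `vf_ionic` parameters
#' @param baseline_apd_ms APD80 of unaffected tissue at the calibration rate
#' @param cycle_ms pacing cycle used for calibration
#' @param seed RNG seed for the core heterogeneity field
#' @return list with `scale` (matrix in (0, 1.5]), `target_apd` (matrix, ms),
#'   `truth_contour` (data.frame row/col of the true border circle),
#'   `lesion_fraction` (fraction of tissue area inside the mid-ramp border),
#'   and the inputs
#' @export
build_lesion_field <- function(grid, lesion, ionic = ionic_params(),
                               baseline_apd_ms = 240, cycle_ms = 500,
                               seed = 1) {
  nr <- grid$n_rows; nc <- grid$n_cols; dx <- grid$dx_mm
  rowmm <- (seq_len(nr) - 1) * dx
  colmm <- (seq_len(nc) - 1) * dx
  cy <- mean(rowmm); cx <- mean(colmm)
  R <- matrix(rowmm, nr, nc)
  C <- matrix(colmm, nr, nc, byrow = TRUE)

  target <- matrix(baseline_apd_ms, nr, nc)
  truth_contour <- NULL
  lesion_fraction <- 0

  if (!is.null(lesion)) {
    th <- lesion$bg_direction_deg * pi / 180
    target <- target +
      lesion$bg_gradient_ms_mm * ((C - cx) * cos(th) + (R - cy) * sin(th))
    lr <- if (is.null(lesion$center_row)) (nr + 1) / 2 else lesion$center_row
    lc <- if (is.null(lesion$center_col)) (nc + 1) / 2 else lesion$center_col
    ly <- (lr - 1) * dx; lx <- (lc - 1) * dx
    d <- sqrt((R - ly)^2 + (C - lx)^2)
    wb2 <- lesion$border_width_mm / 2
    outer_r <- lesion$radius_mm + wb2
    if (lr < 1 || lr > nr || lc < 1 || lc > nc ||
        ly - outer_r < -dx / 2 || ly + outer_r > max(rowmm) + dx / 2 ||
        lx - outer_r < -dx / 2 || lx + outer_r > max(colmm) + dx / 2)
      stop("lesion disc plus transition ring does not fit inside the grid")
    # linear radial ramp: full deficit in the core, zero outside
    frac <- pmin(1, pmax(0, (outer_r - d) / lesion$border_width_mm))
    target <- target + lesion$delta_apd_ms * frac
    det_range <- range(target)
    if (lesion$core_sd_ms > 0) {
      set.seed(seed)
      noise <- matrix(rnorm(nr * nc), nr, nc)
      fld <- EBImage::gblur(noise, sigma = lesion$core_corr_mm / dx,
                            boundary = "replicate")
      taper <- pmin(1, pmax(0, (frac - 0.85) / 0.15))
      core_px <- taper > 0
      fld <- fld / sd(fld[core_px]) * lesion$core_sd_ms
      fld <- fld - sum(fld * taper) / sum(taper)
      target <- target + fld * taper
      # heterogeneity tails are clipped to the calibrated range below;
      # the deterministic part of the map is range-checked unclipped
    }
    ang <- seq(0, 2 * pi, length.out = 361)
    truth_contour <- data.frame(
      row = lr + lesion$radius_mm * sin(ang) / dx,
      col = lc + lesion$radius_mm * cos(ang) / dx)
    lesion_fraction <- mean(d <= lesion$radius_mm)
  }

  calib <- apd_calibration(ionic, cycle_ms = cycle_ms)
  rng <- range(calib$apd80_ms)
  if (!is.null(lesion)) {
    if (det_range[1] < rng[1] || det_range[2] > rng[2])
      stop(sprintf(
        "target APD80 range [%.1f, %.1f] exceeds the calibrated range [%.1f, %.1f]; reduce |delta_apd_ms| or the background gradient",
        det_range[1], det_range[2], rng[1], rng[2]))
  }
  target <- matrix(pmin(rng[2] - 0.5, pmax(rng[1] + 0.5, target)), nr, nc)
  scale <- matrix(scale_for_apd(as.vector(target), calib), nr, nc)
  list(scale = scale, target_apd = target, truth_contour = truth_contour,
       lesion_fraction = lesion_fraction, grid = grid, lesion = lesion,
       ionic = ionic, baseline_apd_ms = baseline_apd_ms)
}
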