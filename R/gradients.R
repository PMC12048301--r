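#' Local spatial gradient magnitude of a scalar map
#'
#' Estimates the two-component spatial derivative by central differences
#' (step 1 px) after a light Gaussian pre-smooth (sigma 1 px by default,
#' applied by normalized convolution so masked pixels do not bleed in), and
#' returns the gradient magnitude in ms/mm. A pixel is masked when any
#' pixel inside the smoothing-plus-difference stencil is invalid, so the
#' estimator is unbiased on linear ramps over the retained pixels.
#'
#' @param map `vf_map` (ms)
#' @param sigma_px Gaussian pre-smooth sigma in pixels (0 disables)
#' @return `vf_map` of kind "gradient" (ms/mm)
#' @export
local_gradient <- function(map, sigma_px = 1) {
  stopifnot(inherits(map, "vf_map"))
  v <- map$values
  ok <- map$valid & is.finite(v)
  if (!any(ok)) stop("fully masked input map")
  v[!ok] <- 0
  if (sigma_px > 0) {
    num <- EBImage::gblur(v, sigma = sigma_px, boundary = "replicate")
    den <- EBImage::gblur(ok + 0, sigma = sigma_px, boundary = "replicate")
    sm <- ifelse(den > 1e-8, num / den, NA_real_)
  } else sm <- ifelse(ok, v, NA_real_)
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- gc <- matrix(NA_real_, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / (2 * map$dx_mm)
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / (2 * map$dx_mm)
  g <- sqrt(gr^2 + gc^2)
  # mask pixels whose 1-px difference stencil touches an invalid pixel
  # (normalized convolution keeps the smoothing itself NA-safe), and a
  # boundary ring where the replicated smoothing support biases ramps
  okm <- erode_mask(ok, 1L)
  ring <- max(1L, if (sigma_px > 0) ceiling(2 * sigma_px) + 1L else 1L)
  okm[c(seq_len(ring), nr - seq_len(ring) + 1L), ] <- FALSE
  okm[, c(seq_len(ring), nc - seq_len(ring) + 1L)] <- FALSE
  okm <- okm & is.finite(g)
  vf_map(ifelse(okm, g, NA_real_), okm, "gradient", map$dx_mm, map$beat)
}

#' @keywords internal
erode_mask <- function(ok, r) {
  out <- ok
  nr <- nrow(ok); nc <- ncol(ok)
  for (dr in -r:r) for (dc in -r:r) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- ok[rs - dr, cs - dc]
    out <- out & sh
  }
  out
}

#' Delineate the short-APD region and its border
#'
#' Thresholds the APD80 map at the minimum between the two modes of its
#' valid-pixel distribution (kernel density estimate); when no clean
#' bimodality is found but the distribution still has contrast, falls back
#' to Otsu's threshold. The largest connected component below threshold is
#' kept as the lesion mask; the border contour is extracted at the mask
#' boundary (sub-pixel, at level 0.5) and a signed distance map to the
#' contour is computed (mm, negative inside the lesion).
#'
#' @param apd_map `vf_map` of kind "APD80" (RT maps are accepted via
#'   `allow_kind`)
#' @param manual_threshold_ms optional manual threshold (ms); required when
#'   the distribution shows no contrast
#' @param min_contrast_ms minimum valid-pixel APD range for automatic
#'   thresholding
#' @param allow_kind map kinds accepted
#' @return object of class `vf_border`: list with `mask` (logical matrix),
#'   `contour` (data.frame `row`, `col`, sub-pixel, closed), `signed_dist_mm`
#'   (matrix), `threshold_ms`, `dx_mm`
#' @export
delineate_border <- function(apd_map, manual_threshold_ms = NULL,
                             min_contrast_ms = 20,
                             allow_kind = c("APD80", "RT")) {
  stopifnot(inherits(apd_map, "vf_map"), apd_map$kind %in% allow_kind)
  v <- apd_map$values
  ok <- apd_map$valid & is.finite(v)
  vals <- v[ok]
  if (length(vals) < 10) stop("too few valid pixels to delineate a region")
  if (is.null(manual_threshold_ms)) {
    if (diff(range(vals)) < min_contrast_ms)
      stop("no bimodality in the APD distribution; supply manual_threshold_ms")
    # Detrend first: the weak background APD gradient of normal tissue
    # broadens the normal mode until it swallows the core-normal valley.
    # A plane is fitted robustly to the normal tissue (iteratively
    # down-weighting the short-APD tail) and subtracted; on the residual
    # the normal mode is tight and the valley deep.
    df <- data.frame(val = vals,
                     r = (row(v))[ok], c = (col(v))[ok])
    use <- rep(TRUE, nrow(df))
    for (it in 1:3) {
      fit <- stats::lm(val ~ r + c, data = df[use, , drop = FALSE])
      res_all <- df$val - stats::predict(fit, df)
      s <- mad(res_all[use])
      use <- res_all > -2.5 * s
    }
    res <- df$val - stats::predict(fit, df)
    thr_res <- NULL
    den <- density(res, bw = 2 * stats::bw.nrd0(res), n = 512)
    pk <- which(diff(sign(diff(den$y))) == -2) + 1
    pk <- pk[den$y[pk] > 0.02 * max(den$y)]
    if (length(pk) >= 2) {
      # the lesion is by definition the lowest-APD mode: consider only
      # valleys between it and each higher mode
      best <- NULL; best_dip <- Inf
      for (b in seq(2, length(pk))) {
        seg <- pk[1]:pk[b]
        valley <- seg[which.min(den$y[seg])]
        dip <- den$y[valley] / min(den$y[pk[1]], den$y[pk[b]])
        if (dip < best_dip) { best_dip <- dip; best <- valley }
      }
      if (best_dip < 0.8) thr_res <- den$x[best]
    }
    if (is.null(thr_res)) {
      sc <- (res - min(res)) / diff(range(res))
      thr_res <- min(res) + diff(range(res)) *
        EBImage::otsu(matrix(sc, 1), range = c(0, 1))
    }
    # threshold in residual space; report the equivalent mean APD level
    resmap <- matrix(NA_real_, nrow(v), ncol(v))
    resmap[ok] <- res
    mask <- ok & resmap < thr_res
    thr <- mean(df$val[res >= thr_res - 2 & res <= thr_res + 2])
  } else {
    thr <- manual_threshold_ms
    mask <- ok & v < thr
  }
  if (!any(mask)) stop("threshold leaves no lesion pixels")
  lab <- EBImage::bwlabel(mask + 0)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  # sub-pixel contour at level 0.5 of the (filled) mask indicator
  ind <- mask + 0
  clines <- contourLines(x = seq_len(nrow(ind)), y = seq_len(ncol(ind)),
                         z = ind, levels = 0.5)
  if (length(clines) == 0) stop("could not extract a border contour")
  len <- vapply(clines, function(cl) length(cl$x), numeric(1))
  cl <- clines[[which.max(len)]]
  contour <- data.frame(row = cl$x, col = cl$y)
  if (contour$row[1] != contour$row[nrow(contour)] ||
      contour$col[1] != contour$col[nrow(contour)])
    contour <- rbind(contour, contour[1, ])
  nr <- nrow(v); nc <- ncol(v)
  dmm <- contour_distance_mm(cbind(rep(seq_len(nr), nc),
                                   rep(seq_len(nc), each = nr)),
                             contour, apd_map$dx_mm)
  sd_map <- matrix(dmm, nr, nc)
  sd_map[mask] <- -sd_map[mask]
  structure(list(mask = mask, contour = contour, signed_dist_mm = sd_map,
                 threshold_ms = thr, dx_mm = apd_map$dx_mm),
            class = "vf_border")
}

#' @keywords internal
contour_distance_mm <- function(sites, contour, dx_mm) {
  # min distance from each site (row, col) to the contour vertices, mm
  cr <- contour$row; cc <- contour$col
  vapply(seq_len(nrow(sites)), function(i) {
    sqrt(min((cr - sites[i, 1])^2 + (cc - sites[i, 2])^2)) * dx_mm
  }, numeric(1))
}

#' Distance from a site to the lesion border
#'
#' Unsigned Euclidean distance (mm) from the site to the nearest contour
#' point, with the border-zone predicate at the 3.5-mm criterion
#' (boundary-inclusive).
#'
#' @param site numeric length-2 (row, col), pixel indices (may be sub-pixel)
#' @param geometry `vf_border`
#' @return list with `distance_mm` and `border_zone` (distance <= 3.5 mm)
#' @export
distance_to_border <- function(site, geometry) {
  stopifnot(inherits(geometry, "vf_border"), length(site) == 2)
  d <- contour_distance_mm(matrix(site, 1), geometry$contour, geometry$dx_mm)
  list(distance_mm = d, border_zone = d <= 3.5)
}

#' Sample nontrigger reference sites in the remote normal region
#'
#' Draws `n` valid pixels uniformly at random (seeded) from the normal
#' region beyond a clearance outside the lesion border and measures the
#' local gradients there.
#'
#' @param geometry `vf_border`
#' @param grad_apd,grad_rt gradient `vf_map`s (ms/mm)
#' @param n number of sites (the reference protocol uses 3 per preparation)
#' @param seed RNG seed
#' @param clearance_mm minimum distance outside the border
#' @param edge_margin_mm minimum distance from the tissue edge (no-flux
#'   boundaries flatten repolarization gradients over a few space
#'   constants, and real optical maps exclude tissue-edge pixels anyway)
#' @return data.frame of site measurements (one row per site) plus the mean
#'   in attribute `"mean"`
#' @export
sample_nontrigger_sites <- function(geometry, grad_apd, grad_rt = NULL,
                                    n = 3, seed = 1, clearance_mm = 10,
                                    edge_margin_mm = 4) {
  stopifnot(inherits(geometry, "vf_border"), inherits(grad_apd, "vf_map"))
  elig <- geometry$signed_dist_mm > clearance_mm & grad_apd$valid
  if (!is.null(grad_rt)) elig <- elig & grad_rt$valid
  if (edge_margin_mm > 0) {
    m <- ceiling(edge_margin_mm / geometry$dx_mm)
    nr <- nrow(elig); nc <- ncol(elig)
    if (2 * m >= nr || 2 * m >= nc)
      stop("edge margin leaves no eligible pixels")
    elig[c(seq_len(m), nr - seq_len(m) + 1L), ] <- FALSE
    elig[, c(seq_len(m), nc - seq_len(m) + 1L)] <- FALSE
  }
  idx <- which(elig)
  if (length(idx) < n)
    stop(sprintf(
      "normal region too small: %d eligible pixels beyond %.1f mm clearance",
      length(idx), clearance_mm))
  set.seed(seed)
  pick <- sample(idx, n)
  nr <- nrow(geometry$mask)
  rows <- (pick - 1) %% nr + 1
  cols <- (pick - 1) %/% nr + 1
  out <- data.frame(
    row = rows, col = cols,
    apd_gradient = grad_apd$values[pick],
    rt_gradient = if (is.null(grad_rt)) NA_real_ else grad_rt$values[pick],
    distance_mm = geometry$signed_dist_mm[pick],
    role = "nontrigger", stringsAsFactors = FALSE)
  attr(out, "mean") <- c(apd_gradient = mean(out$apd_gradient),
                         rt_gradient = mean(out$rt_gradient))
  out
}

#' Measure gradients and border distance at a (trigger) site
#'
#' Gradient values are averaged over the valid pixels of the 3x3
#' neighborhood around the site; errors if the site itself is masked
#' (suggesting the nearest valid pixel).
#'
#' @param site numeric length-2 (row, col)
#' @param geometry `vf_border`
#' @param grad_apd,grad_rt gradient `vf_map`s
#' @param role site role label
#' @param snap_mm when > 0, a masked site is snapped to the nearest valid
#'   pixel within this radius instead of erroring (dead camera pixels can
#'   mask the exact origin pixel)
#' @return one-row data.frame (site, gradients, distance, border-zone flag)
#' @export
measure_trigger_site <- function(site, geometry, grad_apd, grad_rt = NULL,
                                 role = "trigger", snap_mm = 0) {
  stopifnot(inherits(grad_apd, "vf_map"))
  r <- round(site[1]); c <- round(site[2])
  nr <- nrow(grad_apd$values); nc <- ncol(grad_apd$values)
  if (r < 1 || r > nr || c < 1 || c > nc) stop("site outside the grid")
  if (!grad_apd$valid[r, c]) {
    vi <- which(grad_apd$valid)
    vr <- (vi - 1) %% nr + 1; vc <- (vi - 1) %/% nr + 1
    j <- which.min((vr - r)^2 + (vc - c)^2)
    dj <- sqrt((vr[j] - r)^2 + (vc[j] - c)^2) * grad_apd$dx_mm
    if (snap_mm > 0 && dj <= snap_mm) {
      r <- vr[j]; c <- vc[j]
    } else {
      stop(sprintf(
        "site (%d, %d) is masked; nearest valid pixel is (%d, %d)",
        r, c, vr[j], vc[j]))
    }
  }
  rs <- max(1, r - 1):min(nr, r + 1)
  cs <- max(1, c - 1):min(nc, c + 1)
  nb_apd <- grad_apd$values[rs, cs][grad_apd$valid[rs, cs]]
  nb_rt <- if (is.null(grad_rt)) NA_real_ else
    grad_rt$values[rs, cs][grad_rt$valid[rs, cs]]
  db <- distance_to_border(c(r, c), geometry)
  data.frame(row = r, col = c,
             apd_gradient = mean(nb_apd),
             rt_gradient = mean(nb_rt, na.rm = TRUE),
             distance_mm = db$distance_mm, border_zone = db$border_zone,
             role = role, stringsAsFactors = FALSE)
}
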