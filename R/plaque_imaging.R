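# Plate-photograph plaque quantification: scale calibration, rolling-ball
# style background subtraction, dual thresholding inside an elliptical ROI,
# 8-connected particle analysis with area and circularity filters.

#' Construct a plate image
#'
#' @param pixels Numeric matrix of 8-bit grayscale values (0-255), rows = y,
#'   columns = x.
#' @param mm_per_px Scale factor (mm per pixel, > 0).
#' @param plate_diameter_mm Physical plate diameter (default 86).
#' @param roi_width_mm,roi_height_mm Dimensions of the centred elliptical
#'   region of interest (default 72.24 x 72.24).
#' @return Object of class `plate_image`.
#' @export
plate_image <- function(pixels, mm_per_px, plate_diameter_mm = 86,
                        roi_width_mm = 72.24, roi_height_mm = 72.24) {
  if (mm_per_px <= 0) stop("mm_per_px must be > 0")
  pixels <- pmin(pmax(as.matrix(pixels), 0), 255)
  a_px <- roi_width_mm / 2 / mm_per_px
  b_px <- roi_height_mm / 2 / mm_per_px
  if (2 * a_px > ncol(pixels) || 2 * b_px > nrow(pixels)) {
    stop("elliptical ROI exceeds image bounds")
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 plate_diameter_mm = plate_diameter_mm,
                 roi_width_mm = roi_width_mm, roi_height_mm = roi_height_mm),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px at %.4g mm/px (plate %g mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px, x$plate_diameter_mm))
  invisible(x)
}

#' Read a plate photograph into a `plate_image`
#'
#' PNG (and, via EBImage, TIFF/JPEG) input; RGB is converted to 8-bit
#' grayscale by Rec. 709 luminance.
#'
#' @param path Image file.
#' @param mm_per_px Scale factor, e.g. from [calibrate_scale()].
#' @inheritParams plate_image
#' @export
read_plate_image <- function(path, mm_per_px, plate_diameter_mm = 86,
                             roi_width_mm = 72.24, roi_height_mm = 72.24) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
  }
  # EBImage stores x in dim 1; transpose to rows = y
  plate_image(t(dat) * 255, mm_per_px, plate_diameter_mm,
              roi_width_mm, roi_height_mm)
}

#' Calibrate the pixel-to-mm scale from the plate outline
#'
#' @param measured_plate_diameter_px Plate diameter measured on the image,
#'   in pixels (> 0).
#' @param plate_diameter_mm Physical plate diameter (default 86 mm).
#' @return mm per pixel.
#' @export
calibrate_scale <- function(measured_plate_diameter_px, plate_diameter_mm = 86) {
  if (measured_plate_diameter_px <= 0) stop("plate diameter in px must be > 0")
  plate_diameter_mm / measured_plate_diameter_px
}

#' Subtract a slowly varying background
#'
#' Rolling-ball style background flattening: the background is estimated by
#' grayscale morphological opening with a disc structuring element of the
#' given radius and subtracted; output is clipped to 0-255. A flat image
#' maps to all zeros; a radius larger than the image reduces to subtracting
#' the global minimum.
#'
#' @param image A `plate_image` or numeric matrix (0-255).
#' @param rolling_ball_radius_px Structuring-element radius in pixels (> 0).
#' @return Same type as the input, background-subtracted.
#' @export
subtract_background <- function(image, rolling_ball_radius_px = 50) {
  if (rolling_ball_radius_px <= 0) stop("radius must be > 0")
  px <- if (inherits(image, "plate_image")) image$pixels else as.matrix(image)
  side <- 2L * as.integer(rolling_ball_radius_px) + 1L
  # EBImage grayscale morphology clamps to [0,1]; work on that scale
  bg <- EBImage::opening(px / 255, EBImage::makeBrush(side, shape = "disc")) * 255
  out <- pmin(pmax(px - bg, 0), 255)
  if (inherits(image, "plate_image")) {
    image$pixels <- out
    image
  } else {
    out
  }
}

roi_mask <- function(image) {
  px <- image$pixels
  cy <- (nrow(px) + 1) / 2
  cx <- (ncol(px) + 1) / 2
  a <- image$roi_width_mm / 2 / image$mm_per_px
  b <- image$roi_height_mm / 2 / image$mm_per_px
  row_i <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  col_j <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  ((col_j - cx) / a)^2 + ((row_i - cy) / b)^2 <= 1
}

#' Dual-threshold segmentation inside the elliptical ROI
#'
#' Selects pixels with `lower <= value <= upper` lying inside the centred
#' elliptical region of interest.
#'
#' @param image A `plate_image`.
#' @param lower,upper Inclusive intensity bounds in [0,255], lower <= upper.
#' @return Logical mask matrix with the ROI mask attached as attribute
#'   `"roi"`.
#' @export
apply_threshold <- function(image, lower = 180, upper = 238) {
  if (lower > upper) stop("lower threshold exceeds upper threshold")
  if (lower < 0 || upper > 255) stop("thresholds must lie in [0,255]")
  roi <- roi_mask(image)
  mask <- image$pixels >= lower & image$pixels <= upper & roi
  attr(mask, "roi") <- roi
  mask
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right neighbours
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # down-left neighbours
  sel1 <- a > 0 & b > 0 & a != b
  sel2 <- c_ > 0 & d > 0 & c_ != d
  pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c_[sel2], d[sel2]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0] <- dense[lab[lab > 0]]
  lab
}

# Vossepoel-Smeulders corrected perimeter of an 8-connected boundary chain
contour_perimeter <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  steps <- diff(rbind(coords, coords[1, , drop = FALSE]))
  axial <- sum(abs(steps[, 1]) + abs(steps[, 2]) == 1)
  diag_ <- sum(abs(steps[, 1]) == 1 & abs(steps[, 2]) == 1)
  0.980 * axial + 1.406 * diag_
}

#' Identify and measure particles in a segmentation mask
#'
#' Connected components (8-connectivity) are measured and filtered:
#' area within `area_range_mm2`, circularity `4*pi*A/P^2` (perimeter from
#' corrected boundary-chain length, capped at 1.0) within
#' `circularity_range`, and components touching the ROI boundary discarded.
#'
#' @param mask Logical mask from [apply_threshold()] (its `"roi"` attribute
#'   is used for the boundary rule when present).
#' @param mm_per_px Scale factor.
#' @param area_range_mm2 Inclusive area filter (default 0.2-64 mm^2).
#' @param circularity_range Inclusive circularity filter (default 0.20-1.00).
#' @return Data frame of plaque measurements: `area_mm2`,
#'   `equivalent_diameter_mm` (`2*sqrt(A/pi)`), `perimeter_mm`,
#'   `circularity`, `centroid_x_mm`, `centroid_y_mm`.
#' @export
analyze_particles <- function(mask, mm_per_px,
                              area_range_mm2 = c(0.2, 64),
                              circularity_range = c(0.20, 1.00)) {
  empty <- data.frame(area_mm2 = numeric(0), equivalent_diameter_mm = numeric(0),
                      perimeter_mm = numeric(0), circularity = numeric(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0))
  if (!any(mask)) return(empty)
  roi <- attr(mask, "roi")
  lab <- label_components8(unclass(mask))
  nlab <- max(lab)
  # boundary ring: ROI pixels with a 4-neighbour outside the ROI
  on_ring <- NULL
  if (!is.null(roi)) {
    nr <- nrow(roi); nc <- ncol(roi)
    inner <- roi
    inner[2:nr, ] <- inner[2:nr, ] & roi[1:(nr - 1), ]
    inner[1:(nr - 1), ] <- inner[1:(nr - 1), ] & roi[2:nr, ]
    inner[, 2:nc] <- inner[, 2:nc] & roi[, 1:(nc - 1)]
    inner[, 1:(nc - 1)] <- inner[, 1:(nc - 1)] & roi[, 2:nc]
    inner[c(1, nr), ] <- FALSE; inner[, c(1, nc)] <- FALSE
    ring <- roi & !inner
    on_ring <- sort(unique(lab[ring & lab > 0]))
  }
  contours <- EBImage::ocontour(lab)
  idx <- which(lab > 0)
  by_lab <- split(idx, lab[idx])
  rows <- lapply(seq_len(nlab), function(k) {
    if (!is.null(on_ring) && k %in% on_ring) return(NULL)
    pix <- by_lab[[as.character(k)]]
    area <- length(pix) * mm_per_px^2
    if (area < area_range_mm2[1] || area > area_range_mm2[2]) return(NULL)
    per <- contour_perimeter(contours[[k]]) * mm_per_px
    circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
    if (circ < circularity_range[1] || circ > circularity_range[2]) return(NULL)
    ri <- (pix - 1) %% nrow(lab) + 1
    cj <- (pix - 1) %/% nrow(lab) + 1
    data.frame(area_mm2 = area,
               equivalent_diameter_mm = 2 * sqrt(area / pi),
               perimeter_mm = per,
               circularity = circ,
               centroid_x_mm = mean(cj) * mm_per_px,
               centroid_y_mm = mean(ri) * mm_per_px)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full plaque quantification pipeline for one plate image
#'
#' Background subtraction, dual thresholding inside the ROI, and particle
#' analysis with the standard filters.
#'
#' @param image A `plate_image`.
#' @param rolling_ball_radius_px Background structuring-element radius
#'   (default 50); `NA` skips background subtraction.
#' @inheritParams apply_threshold
#' @inheritParams analyze_particles
#' @return Data frame of plaque measurements (see [analyze_particles()]).
#' @export
plaque_pipeline <- function(image, rolling_ball_radius_px = 50,
                            lower = 180, upper = 238,
                            area_range_mm2 = c(0.2, 64),
                            circularity_range = c(0.20, 1.00)) {
  if (!is.na(rolling_ball_radius_px)) {
    image <- subtract_background(image, rolling_ball_radius_px)
  }
  mask <- apply_threshold(image, lower, upper)
  analyze_particles(mask, image$mm_per_px, area_range_mm2, circularity_range)
}

#' Per-sample plaque size report with comparisons against a reference
#'
#' Mean equivalent diameter and t-distribution 95% CI per sample, plus
#' pairwise two-tailed t tests of every sample against the reference sample
#' with Holm-Bonferroni correction.
#'
#' @param measurements Data frame with columns `sample` and
#'   `equivalent_diameter_mm` (e.g. row-bound outputs of [plaque_pipeline()]).
#' @param reference Name of the reference sample.
#' @param alpha Family-wise error level for significance flags.
#' @return List with `summary` (per-sample n, mean, CI) and `comparisons`
#'   (per non-reference sample: t, p, adjusted p, significant).
#' @export
plaque_size_report <- function(measurements, reference, alpha = 0.05) {
  samples <- unique(measurements$sample)
  if (!reference %in% samples) stop("reference sample not present: ", reference)
  diam <- split(measurements$equivalent_diameter_mm, measurements$sample)
  diam <- diam[vapply(diam, function(d) {
    ok <- length(d) > 0
    if (!ok) warning("sample with no measurements skipped")
    ok
  }, logical(1))]
  summary <- do.call(rbind, lapply(names(diam), function(s) {
    d <- diam[[s]]
    ci <- if (length(d) >= 2) summarize_replicates(d) else
      list(mean = mean(d), ci_lower = NA_real_, ci_upper = NA_real_)
    data.frame(sample = s, n = length(d), mean_diameter_mm = ci$mean,
               ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
               stringsAsFactors = FALSE)
  }))
  others <- setdiff(names(diam), reference)
  comparisons <- NULL
  if (length(others)) {
    tests <- lapply(others, function(s) {
      compare_groups(diam[[s]], diam[[reference]], tails = "two")
    })
    holm <- holm_bonferroni(vapply(tests, `[[`, numeric(1), "p_value"), alpha)
    comparisons <- data.frame(sample = others,
                              t = vapply(tests, `[[`, numeric(1), "t"),
                              p = holm$p, p_adjusted = holm$p_adjusted,
                              significant = holm$reject,
                              stringsAsFactors = FALSE)
  }
  list(summary = summary, comparisons = comparisons)
}
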