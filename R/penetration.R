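#' Euclidean distance field from a source mask
#'
#' Distance (in micrometres) from each pixel to the nearest source pixel
#' (vessel mask or tumor-surface contour). Source pixels have distance 0.
#'
#' @param mask binary source matrix (1 = source), or a `vessel_mask`.
#' @param pixel_size_um micrometres per pixel.
#' @return numeric matrix of distances in micrometres.
#' @export
distance_field <- function(mask, pixel_size_um) {
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  check_binary_mask(mask, "mask")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0", call. = FALSE)
  if (sum(mask) == 0) stop("empty source mask", call. = FALSE)
  d <- EBImage::distmap(EBImage::Image(1 - mask))
  as_plain_matrix(EBImage::imageData(d)) * pixel_size_um
}

#' Tumor-surface source mask
#'
#' Outer contour of the tumor mask, for penetration profiles referenced to
#' the tumor surface instead of vessels: tumor pixels with at least one
#' 4-neighbor outside the mask.
#'
#' @param tumor_mask binary matrix.
#' @return binary matrix of boundary pixels.
#' @export
surface_contour_mask <- function(tumor_mask) {
  check_binary_mask(tumor_mask, "tumor_mask")
  H <- nrow(tumor_mask); W <- ncol(tumor_mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- tumor_mask
  inner <- pad[2:(H + 1), 2:(W + 1)] == 1 &
    pad[1:H, 2:(W + 1)] == 1 & pad[3:(H + 2), 2:(W + 1)] == 1 &
    pad[2:(H + 1), 1:W] == 1 & pad[2:(H + 1), 3:(W + 2)] == 1
  out <- tumor_mask == 1 & !inner
  storage.mode(out) <- "integer"
  out
}

#' Antibody intensity versus distance profile
#'
#' Bins pixels of the antibody channel by their distance to the reference
#' structure and reports the mean intensity per bin, the trapezoidal area
#' under the profile over `[0, max_depth_um]`, and the depth of the profile
#' peak. Source pixels (distance 0) are excluded by default: intravascular
#' signal is not penetration. The trapezoid is evaluated on the profile
#' extended to the interval endpoints by the nearest bin value, so with
#' uniform bins the AUC equals bin width times the sum of bin means. The
#' reported peak depth is the argmax of a 3-bin moving-average-smoothed
#' profile; the raw argmax is also returned.
#'
#' @param section a `section_image` (its antibody channel is profiled), or a
#'   plain numeric intensity matrix.
#' @param distance_um distance field in micrometres, e.g. from
#'   [distance_field()].
#' @param bin_width_um histogram bin width (default 1 um).
#' @param max_depth_um profile depth limit (default 80 um, inclusive).
#' @param exclude_source drop distance-0 pixels (default `TRUE`).
#' @param empty_bins `"interpolate"` (default) fills empty bins linearly
#'   from their neighbors and flags them; `"drop"` removes them.
#' @param tumor_mask optional binary matrix restricting the profiled pixels;
#'   defaults to the section's own mask when present.
#' @param reference label recorded in the result (`"vessel"` or
#'   `"surface"`).
#' @return a data frame of class `penetration_profile` with columns
#'   `bin_center_um`, `mean_intensity`, `n_pixels`, `interpolated`, and
#'   attributes `auc_0_80` (AU um), `peak_depth_um`, `peak_depth_raw_um`,
#'   `bin_width_um`, `max_depth_um`, `reference`.
#' @export
intensity_profile <- function(section, distance_um, bin_width_um = 1,
                              max_depth_um = 80, exclude_source = TRUE,
                              empty_bins = c("interpolate", "drop"),
                              tumor_mask = NULL,
                              reference = "vessel") {
  empty_bins <- match.arg(empty_bins)
  if (inherits(section, "section_image")) {
    img <- section$antibody
    tumor_mask <- tumor_mask %||% section$tumor_mask
  } else {
    img <- as_plain_matrix(section)
  }
  if (!identical(dim(img), dim(distance_um)))
    stop("distance map not aligned with the antibody channel", call. = FALSE)
  if (bin_width_um <= 0 || max_depth_um <= 0)
    stop("bin width and depth must be positive", call. = FALSE)

  sel <- distance_um <= max_depth_um
  if (exclude_source) sel <- sel & distance_um > 0
  if (!is.null(tumor_mask)) sel <- sel & tumor_mask == 1
  d <- distance_um[sel]
  v <- img[sel]

  breaks <- seq(0, max_depth_um, by = bin_width_um)
  if (breaks[length(breaks)] < max_depth_um)
    breaks <- c(breaks, max_depth_um)
  nb <- length(breaks) - 1
  # half-open bins [b_i, b_{i+1}), last bin closed at max_depth_um
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  bin[bin == 0] <- 1L                     # d == 0 when sources are kept
  n_px <- tabulate(bin, nbins = nb)
  agg <- tapply(v, factor(bin, levels = seq_len(nb)), sum)
  sums <- ifelse(is.na(agg), 0, agg)
  means <- ifelse(n_px > 0, sums / pmax(n_px, 1), NA_real_)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  interpolated <- n_px == 0
  if (any(interpolated)) {
    if (empty_bins == "drop") {
      centers <- centers[!interpolated]
      means <- means[!interpolated]
      n_px <- n_px[!interpolated]
      interpolated <- interpolated[!interpolated]
    } else {
      if (all(interpolated))
        stop("no pixels fall inside the profiled depth range", call. = FALSE)
      means <- stats::approx(centers[!interpolated], means[!interpolated],
                             xout = centers, rule = 2)$y
      warning(sprintf("%d empty bin(s) interpolated", sum(interpolated)))
    }
  }

  # trapezoid over [0, max_depth] with endpoint extension
  xs <- c(breaks[1], centers, max_depth_um)
  ys <- c(means[1], means, means[length(means)])
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)

  sm <- means
  if (length(means) >= 3) {
    sm <- stats::filter(means, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(means[1:2])
    sm[length(means)] <- mean(means[(length(means) - 1):length(means)])
    sm <- as.numeric(sm)
  }
  out <- data.frame(bin_center_um = centers,
                    mean_intensity = as.numeric(means),
                    n_pixels = n_px,
                    interpolated = interpolated)
  attr(out, "auc_0_80") <- auc
  attr(out, "peak_depth_um") <- centers[which.max(sm)]
  attr(out, "peak_depth_raw_um") <- centers[which.max(means)]
  attr(out, "bin_width_um") <- bin_width_um
  attr(out, "max_depth_um") <- max_depth_um
  attr(out, "reference") <- reference
  class(out) <- c("penetration_profile", "data.frame")
  out
}

#' Area under a penetration profile
#'
#' @param profile a `penetration_profile`.
#' @return the stored trapezoidal AUC (AU um).
#' @export
profile_auc <- function(profile) {
  stopifnot(inherits(profile, "penetration_profile"))
  attr(profile, "auc_0_80")
}

#' Peak depth of a penetration profile
#'
#' @param profile a `penetration_profile`.
#' @param smoothed use the 3-bin smoothed profile (default) or the raw
#'   argmax.
#' @return depth in micrometres of the maximal bin.
#' @export
profile_peak_depth <- function(profile, smoothed = TRUE) {
  stopifnot(inherits(profile, "penetration_profile"))
  if (smoothed) attr(profile, "peak_depth_um")
  else attr(profile, "peak_depth_raw_um")
}

#' Total antibody accumulation per tumor area
#'
#' Sums the antibody channel inside the tumor mask and divides by the mask
#' area in square micrometres.
#'
#' @param section a `section_image`.
#' @param tumor_mask optional binary matrix; defaults to the section's mask,
#'   or to [default_tumor_mask()] when the section has none.
#' @return a list of class `accumulation_result` with `total_intensity`
#'   (AU), `tumor_area_um2` and `accumulation_density` (AU / um^2).
#' @export
accumulation <- function(section, tumor_mask = NULL) {
  stopifnot(inherits(section, "section_image"))
  mask <- tumor_mask %||% ensure_tumor_mask(section)
  check_binary_mask(mask, "tumor_mask")
  if (sum(mask) == 0) stop("empty tumor mask", call. = FALSE)
  total <- sum(section$antibody[mask == 1])
  area <- sum(mask) * section$pixel_size_um^2
  structure(list(total_intensity = total,
                 tumor_area_um2 = area,
                 accumulation_density = total / area),
            class = "accumulation_result")
}

#' Percent change of a metric versus a reference
#'
#' @param treated scalar metric under treatment.
#' @param reference scalar reference metric (> 0).
#' @param digits optional rounding of the reported percentage.
#' @return `100 * (treated - reference) / reference`.
#' @examples
#' percent_change(3.10, 1.72, digits = 0)  # 80
#' @export
percent_change <- function(treated, reference, digits = NULL) {
  if (!is.numeric(reference) || any(reference <= 0))
    stop("'reference' must be positive", call. = FALSE)
  p <- 100 * (treated - reference) / reference
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Fit an exponential decay to a penetration profile
#'
#' Recovers amplitude and decay length from `I(d) = A * exp(-d / lambda)`:
#' a log-linear regression provides starting values which are refined by
#' nonlinear least squares.
#'
#' @param profile a `penetration_profile` (positive-mean bins are used).
#' @return list with `amplitude` and `decay_length_um`.
#' @export
fit_decay <- function(profile) {
  stopifnot(inherits(profile, "penetration_profile"))
  ok <- profile$mean_intensity > 0 & profile$n_pixels > 0
  if (sum(ok) < 3) stop("too few positive bins to fit a decay", call. = FALSE)
  d <- profile$bin_center_um[ok]
  y <- profile$mean_intensity[ok]
  lf <- stats::lm(log(y) ~ d)
  lam0 <- -1 / stats::coef(lf)[2]
  A0 <- exp(stats::coef(lf)[1])
  fit <- try(stats::nls(y ~ A * exp(-d / lambda),
                        start = list(A = A0, lambda = lam0),
                        control = stats::nls.control(warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(amplitude = unname(A0), decay_length_um = unname(lam0)))
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["A"]), decay_length_um = unname(cf["lambda"]))
}
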