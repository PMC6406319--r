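#' Multi-channel tumor-section image
#'
#' Container for one registered field of view with three channels, as
#' acquired on a widefield fluorescence microscope: a nuclear stain (DAPI),
#' a functional-vessel label (rhodamine-lectin) and an antibody conjugate
#' (FITC / Alexa-488). Channels are plain numeric matrices in arbitrary
#' intensity units; no rescaling is applied at construction.
#'
#' @param nuclei,vessels,antibody numeric matrices of identical shape with
#'   finite, non-negative intensities.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param tumor_mask optional binary matrix marking tumor tissue extent.
#' @return an object of class `section_image`.
#' @examples
#' s <- section_image(matrix(0, 8, 8), matrix(0, 8, 8), matrix(1, 8, 8), 0.65)
#' dim(s$antibody)
#' @export
section_image <- function(nuclei, vessels, antibody, pixel_size_um,
                          tumor_mask = NULL) {
  nuclei <- as_plain_matrix(nuclei)
  vessels <- as_plain_matrix(vessels)
  antibody <- as_plain_matrix(antibody)
  if (!identical(dim(nuclei), dim(vessels)) ||
      !identical(dim(nuclei), dim(antibody)))
    stop("channel shape mismatch: all channels must share one shape",
         call. = FALSE)
  for (ch in list(nuclei, vessels, antibody)) {
    if (anyNA(ch) || any(!is.finite(ch)))
      stop("channel intensities must be finite", call. = FALSE)
    if (any(ch < 0))
      stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number", call. = FALSE)
  if (!is.null(tumor_mask)) {
    tumor_mask <- as_plain_matrix(tumor_mask)
    check_binary_mask(tumor_mask, "tumor_mask")
    if (!identical(dim(tumor_mask), dim(nuclei)))
      stop("tumor_mask shape mismatch", call. = FALSE)
    storage.mode(tumor_mask) <- "integer"
  }
  structure(
    list(nuclei = nuclei, vessels = vessels, antibody = antibody,
         pixel_size_um = pixel_size_um, tumor_mask = tumor_mask),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image: %d x %d px (%.3g um/px)\n",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size_um))
  cat(sprintf("  channels: nuclei / vessels / antibody; tumor mask: %s\n",
              if (is.null(x$tumor_mask)) "absent"
              else sprintf("%d px", sum(x$tumor_mask))))
  invisible(x)
}

read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path),
                               call. = FALSE)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) != 2)
    stop(sprintf("expected a single-channel grayscale TIFF: %s", path),
         call. = FALSE)
  m <- as_plain_matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Load a section from per-channel TIFF files
#'
#' Reads one grayscale TIFF per channel and assembles a validated
#' [section_image()]. Integer payloads (8/16-bit) are kept at their stored
#' values, represented as doubles, so intensities are never rescaled.
#'
#' @param paths named character vector or list with entries `nuclei`,
#'   `vessels` and `antibody` pointing at single-channel TIFF files.
#' @param pixel_size_um micrometres per pixel.
#' @param tumor_mask optional binary matrix (see [default_tumor_mask()]).
#' @return a `section_image`.
#' @seealso [write_section()]
#' @export
load_section <- function(paths, pixel_size_um, tumor_mask = NULL) {
  need <- c("nuclei", "vessels", "antibody")
  if (!all(need %in% names(paths)))
    stop("'paths' must have entries nuclei, vessels, antibody", call. = FALSE)
  chans <- lapply(need, function(k) read_channel_tiff(paths[[k]]))
  section_image(chans[[1]], chans[[2]], chans[[3]], pixel_size_um,
                tumor_mask = tumor_mask)
}

#' Write a section as per-channel 16-bit TIFF files
#'
#' Each channel is stored as an unsigned 16-bit grayscale TIFF holding the
#' integer intensity values, alongside a JSON sidecar with the pixel size.
#' Intensities must lie in `[0, 65535]`; non-integer values are rounded with
#' a warning (integer-valued sections round-trip bit-for-bit).
#'
#' @param section a `section_image`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default `"section"`.
#' @return invisibly, a named character vector of the written channel paths.
#' @export
write_section <- function(section, dir, prefix = "section") {
  stopifnot(inherits(section, "section_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chans <- list(nuclei = section$nuclei, vessels = section$vessels,
                antibody = section$antibody)
  rounded <- FALSE
  paths <- vapply(names(chans), function(k) {
    v <- chans[[k]]
    if (any(v < 0) || any(v > 65535))
      stop("intensities outside the 16-bit range [0, 65535]", call. = FALSE)
    r <- round(v)
    if (!rounded && any(r != v)) rounded <<- TRUE
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, k))
    tiff::writeTIFF(r / 65535, p, bits.per.sample = 16L)
    p
  }, character(1))
  if (rounded)
    warning("non-integer intensities were rounded to 16-bit integers")
  meta <- list(pixel_size_um = section$pixel_size_um,
               channels = as.list(paths),
               shape = dim(section$nuclei))
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Default tumor mask from the nuclear channel
#'
#' When no explicit tumor outline is available the section is assumed to be
#' tumor tissue wherever nuclei are present: Otsu's threshold on the nuclei
#' channel, morphological closing (disc of diameter `close_px`) to bridge
#' the gaps between individual nuclei, then the largest connected component
#' with holes filled.
#'
#' @param section a `section_image`.
#' @param close_px diameter in pixels of the closing brush; should exceed
#'   the typical spacing between nuclei (default 31).
#' @return binary integer matrix of the tumor extent.
#' @export
default_tumor_mask <- function(section, close_px = 31) {
  stopifnot(inherits(section, "section_image"))
  ch <- section$nuclei
  rng <- range(ch)
  if (diff(rng) == 0)
    stop("nuclei channel is constant; cannot derive a tumor mask",
         call. = FALSE)
  sc <- (ch - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sc))
  fg <- EBImage::Image(sc > thr)
  if (close_px > 1)
    fg <- EBImage::closing(fg, EBImage::makeBrush(
      close_px + (close_px + 1) %% 2, shape = "disc"))
  bw <- EBImage::bwlabel(fg)
  lab <- as_plain_matrix(EBImage::imageData(bw))
  if (max(lab) == 0)
    stop("no foreground found in the nuclei channel", call. = FALSE)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  filled <- EBImage::fillHull(EBImage::Image(lab == keep))
  m <- as_plain_matrix(EBImage::imageData(filled))
  storage.mode(m) <- "integer"
  m
}

ensure_tumor_mask <- function(section) {
  section$tumor_mask %||% default_tumor_mask(section)
}

#' Sample the 12-region measurement layout
#'
#' Places the per-tumor sampling scheme used for grouped intensity
#' measurements: four square regions at 25% of the distance from the tumor
#' apex, four in the central band, and four at 75% depth. Depth is measured
#' along the tumor mask's principal axis, with the apex taken as the extreme
#' end of that axis; placement inside each band is random but fully
#' reproducible for a given seed, and every region lies entirely inside the
#' tumor mask.
#'
#' @param section a `section_image` carrying a `tumor_mask`.
#' @param region_size_px side length of the square regions in pixels.
#' @param seed integer seed controlling the placement.
#' @param band_halfwidth fraction of the axis length considered part of each
#'   depth band (default 0.1).
#' @return a `region_set`: data frame with columns `label` (`apex25`,
#'   `central`, `apex75`), `x0`, `y0` (0-based column/row of the region
#'   corner), `w`, `h`. ROI intervals are half-open: `[x0, x0 + w)`.
#' @export
sample_regions <- function(section, region_size_px, seed = 1,
                           band_halfwidth = 0.1) {
  stopifnot(inherits(section, "section_image"))
  if (is.null(section$tumor_mask))
    stop("tumor mask absent: sample_regions requires an explicit tumor_mask",
         call. = FALSE)
  s <- as.integer(region_size_px)
  if (s < 1) stop("'region_size_px' must be >= 1", call. = FALSE)
  mask <- section$tumor_mask
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) < s * s)
    stop("mask too small for requested region size", call. = FALSE)

  # principal axis of the mask (translation invariant by construction)
  ctr <- colMeans(idx)
  cen <- sweep(idx, 2, ctr)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0 || (ev[1] == 0 && ev[2] < 0)) ev <- -ev  # fixed orientation
  proj <- cen %*% ev
  lo <- min(proj); hi <- max(proj)
  frac <- as.vector((proj - lo) / (hi - lo))  # 0 = apex end

  # interior test: region of side s centred at a pixel must sit inside mask
  cs <- apply(apply(mask, 2, cumsum), 1, cumsum)  # transposed integral image
  boxsum <- function(r0, c0, r1, c1) {          # inclusive 1-based bounds
    a <- cs[c1, r1]
    b <- if (c0 > 1) cs[c0 - 1, r1] else 0
    d <- if (r0 > 1) cs[c1, r0 - 1] else 0
    e <- if (c0 > 1 && r0 > 1) cs[c0 - 1, r0 - 1] else 0
    a - b - d + e
  }
  h <- s %/% 2
  fits <- function(r, c) {
    r0 <- r - h; c0 <- c - h; r1 <- r0 + s - 1; c1 <- c0 + s - 1
    r0 >= 1 && c0 >= 1 && r1 <= nrow(mask) && c1 <= ncol(mask) &&
      boxsum(r0, c0, r1, c1) == s * s
  }

  bands <- c(apex25 = 0.25, central = 0.5, apex75 = 0.75)
  # candidate ordering by (depth fraction, perpendicular offset): invariant
  # to translation of the mask within the image
  perp <- as.vector(cen %*% c(-ev[2], ev[1]))
  out <- list()
  for (b in names(bands)) {
    in_band <- which(abs(frac - bands[[b]]) <= band_halfwidth)
    cand <- in_band[vapply(in_band,
                           function(i) fits(idx[i, 1], idx[i, 2]), logical(1))]
    if (length(cand) < 4)
      stop(sprintf("mask too small: fewer than 4 placements in band '%s'", b),
           call. = FALSE)
    cand <- cand[order(frac[cand], perp[cand])]
    pick <- with_rng_seed(seed + match(b, names(bands)), function() {
      chosen <- integer(0)
      for (i in sample(seq_along(cand))) {
        ci <- cand[i]
        if (length(chosen) == 0 ||
            all(sqrt((idx[chosen, 1] - idx[ci, 1])^2 +
                     (idx[chosen, 2] - idx[ci, 2])^2) >= s)) {
          chosen <- c(chosen, ci)
          if (length(chosen) == 4) break
        }
      }
      chosen
    })
    if (length(pick) < 4)
      stop(sprintf("mask too small: cannot place 4 disjoint regions in '%s'", b),
           call. = FALSE)
    out[[b]] <- data.frame(
      label = b,
      x0 = idx[pick, 2] - 1 - h,  # 0-based column of corner
      y0 = idx[pick, 1] - 1 - h,  # 0-based row of corner
      w = s, h = s,
      stringsAsFactors = FALSE)
  }
  rs <- do.call(rbind, out)
  rownames(rs) <- NULL
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Write or read a region set as JSON
#'
#' @param regions a `region_set` from [sample_regions()].
#' @param path file path for the JSON document.
#' @return `regions_to_json` returns `path` invisibly; `regions_from_json`
#'   returns a `region_set`.
#' @export
regions_to_json <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  jsonlite::write_json(as.data.frame(regions), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname regions_to_json
#' @export
regions_from_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("region_set", "data.frame")
  df
}

#' Extract the pixels of one region from a channel
#'
#' @param channel numeric matrix.
#' @param region single-row subset of a `region_set`.
#' @return numeric matrix of the region's pixels.
#' @export
region_pixels <- function(channel, region) {
  r0 <- region$y0 + 1; c0 <- region$x0 + 1
  channel[r0:(r0 + region$h - 1), c0:(c0 + region$w - 1), drop = FALSE]
}
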