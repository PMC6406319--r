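# Nuclear-morphology radiomics: LoG contour extraction, sub-pixel
# circularity, box-counting fractal dimension, vessel-proximal filtering.

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  ax <- seq(-half, half)
  g <- outer(ax, ax, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)  # zero net response on flat fields
}

# boundary polygon(s) of a binary mask: one 0-based coordinate matrix per
# connected component, ordered along the contour (Moore tracing via EBImage)
boundary_chains <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  if (max(lab) == 0) return(list())
  EBImage::ocontour(lab)
}

# resample a closed boundary chain at sub-pixel arc-length steps so box
# occupancy reflects the curve, not the spacing of traced vertices
densify_chain <- function(xy, step = 0.5) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  nxt <- c(2:n, 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    a <- xy[i, ]; b <- xy[nxt[i], ]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) return(rbind(a))
    t <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
}

# pooled densified boundary point set of all components of a mask
boundary_points <- function(mask) {
  unique(do.call(rbind, lapply(boundary_chains(mask), densify_chain)))
}

# sub-pixel perimeter of one boundary chain: circular moving-average
# smoothing of the vertex coordinates (window 2k+1) plus pi for the
# half-pixel outward offset of the pixel-centre polygon
chain_perimeter <- function(xy, k = 2) {
  n <- nrow(xy)
  if (n == 1) return(pi)      # single pixel: circumference of its half-pixel disk
  if (n > 2 * k + 1) {
    idx <- function(v) ((v - 1) %% n) + 1
    sm <- vapply(seq_len(n), function(i)
      colMeans(xy[idx((i - k):(i + k)), , drop = FALSE]), numeric(2))
    xy <- t(sm)
  }
  nxt <- c(2:n, 1)
  sum(sqrt(rowSums((xy - xy[nxt, , drop = FALSE])^2))) + pi
}

#' Perimeter of a binary shape
#'
#' Sub-pixel perimeter estimate: boundary pixel chains are smoothed with a
#' circular 5-point moving average and measured as polygons, with a
#' half-pixel offset correction per closed component. Multi-component masks
#' return the summed perimeter.
#'
#' @param mask binary matrix.
#' @return perimeter length in pixels.
#' @export
shape_perimeter <- function(mask) {
  check_binary_mask(mask, "mask")
  chains <- boundary_chains(mask)
  if (length(chains) == 0) stop("empty mask", call. = FALSE)
  sum(vapply(chains, chain_perimeter, numeric(1)))
}

#' Circularity of a binary shape
#'
#' The standard shape factor `4 * pi * area / perimeter^2`: 1 for a disk,
#' lower for elongated, rough or fragmented shapes. Area and perimeter are
#' pooled over all connected components, so fragmentation lowers
#' circularity. Values may exceed 1 by up to the discretization tolerance
#' (0.05) on small shapes; reporting is capped there.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return circularity in `(0, 1.05]`.
#' @export
shape_circularity <- function(mask) {
  check_binary_mask(mask, "mask")
  a <- sum(mask)
  if (a == 0) stop("empty mask", call. = FALSE)
  if (a == 1) stop("degenerate single-pixel object", call. = FALSE)
  p <- shape_perimeter(mask)
  min(4 * pi * a / p^2, 1.05)
}

#' Box-counting fractal dimension of a contour point set
#'
#' Counts occupied boxes `N(eps)` over a dyadic grid of box sizes and
#' estimates the fractal dimension as minus the slope of the least-squares
#' fit of `log N(eps)` on `log eps`. Counts are averaged over `n_offsets`
#' diagonal grid offsets to stabilize the estimate. Default box sizes are
#' dyadic from 2 px up to one quarter of the bounding-box diagonal; contours
#' smaller than 64 px across extend the grid down to 1 px so at least three
#' scales enter the fit.
#'
#' @param points two-column matrix of contour coordinates (pixels), or a
#'   `nucleus_object`.
#' @param box_sizes optional numeric vector of box sizes in pixels.
#' @param n_offsets number of grid offsets averaged (>= 1, default 4).
#' @return a list of class `fd_estimate`: `fd`, `r2`, `box_sizes`, `counts`,
#'   `degenerate_fit` (TRUE when R^2 < 0.9).
#' @examples
#' line <- cbind(seq(0, 100, 0.5), seq(0, 50, 0.25))
#' fractal_dimension(line)$fd  # close to 1
#' @export
fractal_dimension <- function(points, box_sizes = NULL, n_offsets = 4) {
  if (inherits(points, "nucleus_object")) points <- points$contour
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("'points' must be a two-column matrix",
                              call. = FALSE)
  points <- unique(points)
  if (nrow(points) < 16)
    stop("too few contour points (need >= 16)", call. = FALSE)
  if (is.null(box_sizes)) {
    rng <- apply(points, 2, range)
    diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
    lo <- if (diag_len < 64) 0 else 1          # 1 px floor for small contours
    emax <- max(diag_len / 4, 2^(lo + 2))
    box_sizes <- 2^seq(lo, floor(log2(emax)))
  }
  box_sizes <- sort(unique(box_sizes))
  if (length(box_sizes) < 2)
    stop("need at least two box sizes", call. = FALSE)
  counts <- vapply(box_sizes, function(e) {
    mean(vapply(seq_len(n_offsets), function(o) {
      off <- (o - 1) / n_offsets * e
      cells <- floor((points + off) / e)
      nrow(unique(cells))
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(box_sizes))
  r2 <- summary(fit)$r.squared
  structure(list(fd = -unname(stats::coef(fit)[2]),
                 r2 = r2,
                 box_sizes = box_sizes,
                 counts = counts,
                 degenerate_fit = r2 < 0.9),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("box-counting FD = %.3f (R^2 = %.4f, %d scales%s)\n",
              x$fd, x$r2, length(x$box_sizes),
              if (x$degenerate_fit) ", degenerate fit" else ""))
  invisible(x)
}

#' Combined morphometrics of one (possibly fragmented) nucleus mask
#'
#' Measures all connected components of the mask jointly as one nucleus, the
#' convention used for per-nucleus group statistics: area and perimeter are
#' pooled for circularity, and the fractal dimension is computed on the
#' union of the component boundaries.
#'
#' @param mask binary matrix of one nucleus (possibly several fragments).
#' @param box_sizes optional box sizes passed to [fractal_dimension()].
#' @return list with `area_px`, `perimeter_px`, `circularity`,
#'   `fractal_dimension`, `fd_r2`, `n_components`.
#' @export
nucleus_morphometrics <- function(mask, box_sizes = NULL) {
  check_binary_mask(mask, "mask")
  chains <- boundary_chains(mask)
  if (length(chains) == 0) stop("empty mask", call. = FALSE)
  pts <- boundary_points(mask)
  fd <- if (nrow(pts) >= 16)
    fractal_dimension(pts, box_sizes = box_sizes) else NULL
  list(area_px = sum(mask),
       perimeter_px = shape_perimeter(mask),
       circularity = shape_circularity(mask),
       fractal_dimension = if (is.null(fd)) NA_real_ else fd$fd,
       fd_r2 = if (is.null(fd)) NA_real_ else fd$r2,
       n_components = length(chains))
}

#' Extract nuclei by Laplacian-of-Gaussian edge finding
#'
#' Applies a Laplacian-of-Gaussian filter at scale `log_sigma` to the
#' nuclear channel; the zero-crossing contour of the response outlines each
#' bright object, whose interior (negative LoG response with intensity
#' support above Otsu's threshold of the smoothed channel) becomes a labeled
#' object. Objects below `min_size_px` are discarded. Components whose
#' centroids fall within `merge_radius_px` of each other are optionally
#' merged and measured jointly (fragments of one apoptotic nucleus); by
#' default no merging is applied.
#'
#' @param section a `section_image` or plain intensity matrix.
#' @param log_sigma Gaussian scale of the LoG filter in pixels (default 2).
#' @param min_size_px minimum object area kept (default 20).
#' @param merge_radius_px centroid distance below which components are
#'   merged into one nucleus (default 0 = no merging).
#' @param distance_um optional vessel distance field; when supplied each
#'   object records its centroid distance to the nearest vessel.
#' @return a list of class `nucleus_set`; each element is a
#'   `nucleus_object` with `label`, `contour` (0-based sub-pixel boundary
#'   coordinates, all components pooled), `area_px`, `perimeter_px`, `circularity`,
#'   `fractal_dimension`, `fd_r2`, `n_components`, `centroid` (row, col) and
#'   `distance_to_vessel_um`. A blank (constant) channel yields an empty set
#'   with a warning.
#' @seealso [proximal_filter()], [as.data.frame.nucleus_set()]
#' @export
extract_nuclei <- function(section, log_sigma = 2, min_size_px = 20,
                           merge_radius_px = 0, distance_um = NULL) {
  img <- if (inherits(section, "section_image")) section$nuclei
         else as_plain_matrix(section)
  if (length(img) == 0) stop("empty nuclei channel", call. = FALSE)
  if (diff(range(img)) == 0) {
    warning("blank nuclei channel: no objects found")
    return(structure(list(), class = "nucleus_set"))
  }

  resp <- as_plain_matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(img), log_kernel(log_sigma),
                     boundary = "replicate")))
  sm <- as_plain_matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(img), sigma = log_sigma,
                   boundary = "replicate")))
  rng <- range(sm)
  thr <- rng[1] + EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng))) *
    diff(rng)
  interior <- resp < 0 & sm > thr
  lab <- as_plain_matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(interior))))
  nlab <- max(lab)
  if (nlab == 0) {
    warning("no objects found")
    return(structure(list(), class = "nucleus_set"))
  }
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= min_size_px)
  if (length(keep) == 0) {
    warning(sprintf("all %d objects below min_size_px", nlab))
    return(structure(list(), class = "nucleus_set"))
  }

  cent <- t(vapply(keep, function(l) {
    ij <- which(lab == l, arr.ind = TRUE)
    colMeans(ij)
  }, numeric(2)))

  # union-find merge of components with nearby centroids
  group <- seq_along(keep)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  if (merge_radius_px > 0 && length(keep) > 1) {
    dd <- as.matrix(stats::dist(cent))
    for (i in seq_along(keep)) for (j in seq_len(i - 1)) {
      if (dd[i, j] <= merge_radius_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(keep), find, integer(1))

  objects <- lapply(unique(roots), function(r) {
    members <- keep[roots == r]
    m <- matrix(0L, nrow(img), ncol(img))
    m[lab %in% members] <- 1L
    chains <- boundary_chains(m)
    pts <- boundary_points(m)
    ij <- which(m == 1, arr.ind = TRUE)
    ctr <- colMeans(ij)
    fd <- if (nrow(pts) >= 16) fractal_dimension(pts) else NULL
    dist_v <- if (!is.null(distance_um))
      distance_um[round(ctr[1]), round(ctr[2])] else NA_real_
    structure(list(
      label = r,
      contour = pts,
      area_px = sum(m),
      perimeter_px = shape_perimeter(m),
      circularity = shape_circularity(m),
      fractal_dimension = if (is.null(fd)) NA_real_ else fd$fd,
      fd_r2 = if (is.null(fd)) NA_real_ else fd$r2,
      n_components = length(chains),
      centroid = unname(ctr),
      distance_to_vessel_um = unname(dist_v)),
      class = "nucleus_object")
  })
  for (i in seq_along(objects)) objects[[i]]$label <- i
  structure(objects, class = "nucleus_set",
            provenance = list(log_sigma = log_sigma,
                              min_size_px = min_size_px,
                              merge_radius_px = merge_radius_px,
                              n_raw = nlab,
                              n_discarded_small = nlab - length(keep)))
}

#' Circularity accessor
#'
#' @param object a `nucleus_object` (returns its stored value) or a binary
#'   mask matrix (computed via [shape_circularity()]).
#' @return circularity value.
#' @export
circularity <- function(object) {
  if (inherits(object, "nucleus_object")) return(object$circularity)
  shape_circularity(object)
}

#' Keep nuclei within a distance band of the vessels
#'
#' Retains objects whose centroid lies at most `max_dist_um` from the
#' nearest vessel, the vessel-proximal restriction used for nuclear
#' morphometry (default 80 um).
#'
#' @param objects a `nucleus_set`.
#' @param distance_um vessel distance field in micrometres (optional when
#'   every object already carries `distance_to_vessel_um`).
#' @param max_dist_um distance cut-off, inclusive (default 80; `Inf` keeps
#'   everything).
#' @return the filtered `nucleus_set`.
#' @export
proximal_filter <- function(objects, distance_um = NULL, max_dist_um = 80) {
  stopifnot(inherits(objects, "nucleus_set"))
  keep <- vapply(objects, function(o) {
    d <- o$distance_to_vessel_um
    if (is.na(d)) {
      if (is.null(distance_um))
        stop("no distance field available", call. = FALSE)
      d <- distance_um[round(o$centroid[1]), round(o$centroid[2])]
    }
    d <= max_dist_um
  }, logical(1))
  structure(unclass(objects)[keep], class = "nucleus_set",
            provenance = attr(objects, "provenance"))
}

#' Tabulate a nucleus set
#'
#' @param x a `nucleus_set`.
#' @param ... unused.
#' @return data frame with one row per nucleus: label, centroid, area,
#'   perimeter, circularity, fractal dimension and vessel distance.
#' @export
as.data.frame.nucleus_set <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area_px = numeric(0), perimeter_px = numeric(0),
                      circularity = numeric(0),
                      fractal_dimension = numeric(0), fd_r2 = numeric(0),
                      n_components = integer(0),
                      distance_to_vessel_um = numeric(0)))
  do.call(rbind, lapply(x, function(o)
    data.frame(label = o$label, row = o$centroid[1], col = o$centroid[2],
               area_px = o$area_px, perimeter_px = o$perimeter_px,
               circularity = o$circularity,
               fractal_dimension = o$fractal_dimension, fd_r2 = o$fd_r2,
               n_components = o$n_components,
               distance_to_vessel_um = o$distance_to_vessel_um)))
}
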