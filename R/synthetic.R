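#' Specification for a synthetic tumor section
#'
#' Describes the ground-truth geometry and imaging conditions of a simulated
#' three-channel section: tubular functional vessels, an antibody intensity
#' field that decays exponentially with distance from the nearest vessel,
#' and nuclei rendered as smooth disks (intact) or fragmented, rough-edged
#' blobs (apoptotic). Defaults emulate a 10x widefield acquisition of a
#' xenograft section.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.65, typical for a
#'   10x widefield camera pixel).
#' @param n_vessels number of straight tubular vessels (0 allowed).
#' @param vessel_radius_um vessel tube radius, micrometres.
#' @param decay_length_um exponential decay constant of the antibody field,
#'   micrometres.
#' @param antibody_amplitude antibody intensity at the vessel wall, AU.
#' @param surface_margin_um width of the band between the image border and
#'   the tumor boundary, micrometres.
#' @param n_nuclei number of nuclei to place.
#' @param frac_fragmented fraction of nuclei rendered as fragmented, in
#'   `[0, 1]`.
#' @param nucleus_radius_um nucleus radius, micrometres.
#' @param fragmentation_severity dimensionless severity (>= 0) controlling
#'   lobe separation and boundary roughness of fragmented nuclei.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   applied to every channel, AU.
#' @param rng_seed integer seed; the same spec and seed give bit-identical
#'   output.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_section()], [render_nucleus()]
#' @export
synthetic_spec <- function(image_shape = c(384L, 384L),
                           pixel_size_um = 0.65,
                           n_vessels = 4,
                           vessel_radius_um = 5,
                           decay_length_um = 20,
                           antibody_amplitude = 100,
                           surface_margin_um = 15,
                           n_nuclei = 60,
                           frac_fragmented = 0,
                           nucleus_radius_um = 6.5,
                           fragmentation_severity = 1,
                           noise_sd = 0,
                           rng_seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape),
               pixel_size_um = pixel_size_um,
               n_vessels = as.integer(n_vessels),
               vessel_radius_um = vessel_radius_um,
               decay_length_um = decay_length_um,
               antibody_amplitude = antibody_amplitude,
               surface_margin_um = surface_margin_um,
               n_nuclei = as.integer(n_nuclei),
               frac_fragmented = frac_fragmented,
               nucleus_radius_um = nucleus_radius_um,
               fragmentation_severity = fragmentation_severity,
               noise_sd = noise_sd,
               rng_seed = as.integer(rng_seed))
  if (length(spec$image_shape) != 2 || any(spec$image_shape <= 0))
    stop("'image_shape' must be two positive integers", call. = FALSE)
  lens <- c(pixel_size_um = pixel_size_um,
            vessel_radius_um = vessel_radius_um,
            decay_length_um = decay_length_um,
            antibody_amplitude = antibody_amplitude,
            surface_margin_um = surface_margin_um,
            nucleus_radius_um = nucleus_radius_um)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad))
    stop(sprintf("non-positive dimension(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (frac_fragmented < 0 || frac_fragmented > 1)
    stop("'frac_fragmented' must lie in [0, 1]", call. = FALSE)
  if (fragmentation_severity < 0)
    stop("'fragmentation_severity' must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (spec$n_vessels < 0 || spec$n_nuclei < 0)
    stop("counts must be >= 0", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

# distance from every pixel centre to segment a-b (rows/cols in px coords)
point_segment_distance <- function(pr, pc, a, b) {
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  L2 <- vr^2 + vc^2
  if (L2 == 0) return(sqrt((pr - a[1])^2 + (pc - a[2])^2))
  t <- ((pr - a[1]) * vr + (pc - a[2]) * vc) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

render_ellipse_mask <- function(shape, margin_px) {
  H <- shape[1]; W <- shape[2]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  ar <- max(H / 2 - margin_px, 2); ac <- max(W / 2 - margin_px, 2)
  rr <- matrix(seq_len(H), H, W)
  cci <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- ((rr - cr) / ar)^2 + ((cci - cc) / ac)^2 <= 1
  storage.mode(m) <- "integer"
  m
}

#' Render one synthetic nucleus
#'
#' Intact nuclei are smooth digitized disks. Fragmented nuclei model
#' apoptotic bodies: the disk boundary is roughened by random radial
#' harmonics and the interior is split into Voronoi-style lobes separated by
#' gaps; both the gap width and the roughness amplitude grow with
#' `severity`, so circularity falls and boundary fractal dimension rises as
#' severity increases. `severity = 0` reduces exactly to the intact shape.
#'
#' @param class `"intact"` or `"fragmented"`.
#' @param severity dimensionless >= 0.
#' @param seed integer seed (fragmented shapes are random).
#' @param radius_px nucleus radius in pixels (default 10).
#' @return binary integer matrix containing the shape.
#' @examples
#' m <- render_nucleus("intact", radius_px = 12)
#' sum(m) / (pi * 12^2)  # close to 1
#' @export
render_nucleus <- function(class = c("intact", "fragmented"), severity = 1,
                           seed = 1, radius_px = 10) {
  class <- match.arg(class)
  if (!is.numeric(severity) || severity < 0)
    stop("'severity' must be >= 0", call. = FALSE)
  if (radius_px < 2) stop("'radius_px' must be >= 2", call. = FALSE)
  if (class == "fragmented" && severity == 0) class <- "intact"

  half <- ceiling(radius_px * if (class == "intact") 1.25 else 2.1)
  n <- 2L * half + 1L
  ctr <- half + 1
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- t(dr)
  rho <- sqrt(dr^2 + dc^2)
  if (class == "intact") {
    m <- rho <= radius_px
    storage.mode(m) <- "integer"
    return(m)
  }

  with_rng_seed(seed, function() {
    theta <- atan2(dc, dr)
    # boundary roughening: random radial harmonics whose amplitude grows
    # with severity (capped so the shape stays connected to its centre)
    amp <- min(0.04 + 0.085 * severity, 0.45)
    harm <- 4:14
    rmod <- matrix(1, n, n)
    for (h in harm) {
      rmod <- rmod + amp * stats::rnorm(1) / sqrt(length(harm)) *
        cos(h * theta + stats::runif(1, 0, 2 * pi))
    }
    rmod <- pmax(rmod, 0.3)
    base <- rho <= radius_px * rmod

    # Voronoi-style lobes: a pixel survives only where clearly closer to one
    # lobe seed than to the runner-up; the margin is the gap width
    k <- 2L + as.integer(severity >= 3.5)
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- stats::runif(k, 0.3, 0.6) * radius_px
    sr <- rad * cos(ang); sc <- rad * sin(ang)
    d1 <- matrix(Inf, n, n); d2 <- matrix(Inf, n, n)
    for (i in seq_len(k)) {
      di <- sqrt((dr - sr[i])^2 + (dc - sc[i])^2)
      closer <- di < d1
      d2 <- pmin(d2, ifelse(closer, d1, di))
      d1 <- pmin(d1, di)
    }
    gap <- radius_px * min(0.04 + 0.045 * severity, 0.22)
    m <- base & (d2 - d1 >= gap)
    storage.mode(m) <- "integer"
    if (sum(m) == 0)  # pathological seed draw: fall back to the intact disk
      m <- matrix(as.integer(rho <= radius_px), n, n)
    m
  })
}

#' Generate a synthetic tumor section with ground truth
#'
#' Renders the three co-registered channels described by a
#' [synthetic_spec()]: vessels as constant-radius line-segment tubes clipped
#' to an elliptical tumor mask, an antibody channel
#' `I(d) = A * exp(-d / decay_length_um)` of the true distance `d` (um) to
#' the nearest vessel surface, and nuclei stamped at grid-jittered positions
#' so they never touch. Gaussian noise of `noise_sd` is then added to every
#' channel (clamped at zero). With `n_vessels = 0` the antibody channel is
#' pure noise and the distance field is flagged as undefined.
#'
#' @param spec a `synthetic_spec`.
#' @return a list of class `synthetic_section` with elements
#'   \describe{
#'     \item{section}{the [section_image()] (tumor mask included)}
#'     \item{truth}{ground truth: `vessel_mask`, per-pixel `distance_um`
#'       (`NULL` when `has_vessels` is `FALSE`), `has_vessels`, `tumor_mask`,
#'       `vessel_area_fraction`, and a `nuclei` data frame
#'       (id, row, col, class, seed, n_components, area_px) plus
#'       `nucleus_masks`, a list of per-nucleus binary stamps with their
#'       corner offsets}
#'     \item{spec}{the input spec}
#'   }
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$rng_seed, function() {
    H <- spec$image_shape[1]; W <- spec$image_shape[2]
    px <- spec$pixel_size_um
    margin_px <- spec$surface_margin_um / px
    tumor <- render_ellipse_mask(c(H, W), margin_px)

    pr <- matrix(seq_len(H), H, W)
    pc <- matrix(seq_len(W), H, W, byrow = TRUE)

    vessel_amp <- 180
    nucleus_amp <- 150

    # --- vessels -----------------------------------------------------------
    has_vessels <- spec$n_vessels > 0
    r_px <- spec$vessel_radius_um / px
    if (has_vessels) {
      mind <- matrix(Inf, H, W)
      for (i in seq_len(spec$n_vessels)) {
        # random chord through a random interior point
        cen <- c(stats::runif(1, 0.25 * H, 0.75 * H),
                 stats::runif(1, 0.25 * W, 0.75 * W))
        ang <- stats::runif(1, 0, pi)
        hl <- stats::runif(1, 0.35, 0.75) * min(H, W)
        a <- cen + hl * c(cos(ang), sin(ang))
        b <- cen - hl * c(cos(ang), sin(ang))
        d <- point_segment_distance(pr, pc, a, b)
        mind <- pmin(mind, d)
      }
      vessel_mask <- (mind <= r_px) & (tumor == 1)
      storage.mode(vessel_mask) <- "integer"
      # exact distance (um) to the tube surface; zero inside vessels
      dist_um <- pmax(mind - r_px, 0) * px  # matrix first: pmax keeps its dims
      antibody <- spec$antibody_amplitude * exp(-dist_um / spec$decay_length_um)
      antibody[tumor == 0] <- 0
      vessels_ch <- vessel_amp * vessel_mask
      dist_truth <- dist_um
    } else {
      vessel_mask <- matrix(0L, H, W)
      antibody <- matrix(0, H, W)
      vessels_ch <- matrix(0, H, W)
      dist_truth <- NULL
    }

    # --- nuclei: jittered grid placement guarantees separation -------------
    nr_px <- spec$nucleus_radius_um / px
    cell <- ceiling(3.6 * nr_px)
    rows <- floor((H - 2 * margin_px) / cell)
    cols <- floor((W - 2 * margin_px) / cell)
    grid <- expand.grid(gr = seq_len(rows), gc = seq_len(cols))
    gr0 <- margin_px + (grid$gr - 0.5) * cell
    gc0 <- margin_px + (grid$gc - 0.5) * cell
    inside <- tumor[cbind(pmin(H, pmax(1, round(gr0))),
                          pmin(W, pmax(1, round(gc0))))] == 1
    avail <- which(inside)
    if (spec$n_nuclei > length(avail))
      stop(sprintf(
        "cannot place %d nuclei: only %d grid sites inside the tumor mask",
        spec$n_nuclei, length(avail)), call. = FALSE)
    take <- avail[sample.int(length(avail), spec$n_nuclei)]
    jit <- max(0, floor((cell - ceiling(2.8 * nr_px)) / 2))
    cy <- round(gr0[take] + stats::runif(spec$n_nuclei, -1, 1) * jit)
    cx <- round(gc0[take] + stats::runif(spec$n_nuclei, -1, 1) * jit)

    n_frag <- round(spec$frac_fragmented * spec$n_nuclei)
    is_frag <- rep(FALSE, spec$n_nuclei)
    if (n_frag > 0) is_frag[sample(spec$n_nuclei, n_frag)] <- TRUE
    seeds <- sample.int(.Machine$integer.max - 1L, spec$n_nuclei)

    nuclei_ch <- matrix(0, H, W)
    stamps <- vector("list", spec$n_nuclei)
    ncomp <- integer(spec$n_nuclei)
    area <- integer(spec$n_nuclei)
    for (i in seq_len(spec$n_nuclei)) {
      m <- render_nucleus(if (is_frag[i]) "fragmented" else "intact",
                          severity = spec$fragmentation_severity,
                          seed = seeds[i], radius_px = nr_px)
      hn <- (nrow(m) - 1) %/% 2
      r0 <- cy[i] - hn; c0 <- cx[i] - hn
      rr <- r0:(r0 + nrow(m) - 1); cc <- c0:(c0 + ncol(m) - 1)
      ok_r <- rr >= 1 & rr <= H; ok_c <- cc >= 1 & cc <= W
      sub <- m[ok_r, ok_c, drop = FALSE]
      nuclei_ch[rr[ok_r], cc[ok_c]] <-
        pmax(nuclei_ch[rr[ok_r], cc[ok_c]], nucleus_amp * sub)
      lab <- EBImage::bwlabel(EBImage::Image(m))
      ncomp[i] <- max(as_plain_matrix(EBImage::imageData(lab)))
      area[i] <- sum(m)
      stamps[[i]] <- list(mask = m, r0 = r0, c0 = c0)
    }

    # --- noise -------------------------------------------------------------
    if (spec$noise_sd > 0) {
      addn <- function(ch) pmax(0, ch + stats::rnorm(length(ch), 0,
                                                     spec$noise_sd))
      nuclei_ch <- matrix(addn(nuclei_ch), H, W)
      vessels_ch <- matrix(addn(vessels_ch), H, W)
      antibody <- matrix(addn(antibody), H, W)
    }

    section <- section_image(nuclei_ch, vessels_ch, antibody,
                             pixel_size_um = px, tumor_mask = tumor)
    truth <- list(
      vessel_mask = vessel_mask,
      distance_um = dist_truth,
      has_vessels = has_vessels,
      tumor_mask = tumor,
      vessel_area_fraction = sum(vessel_mask * tumor) / sum(tumor),
      nuclei = data.frame(id = seq_len(spec$n_nuclei),
                          row = cy, col = cx,
                          class = ifelse(is_frag, "fragmented", "intact"),
                          seed = seeds,
                          n_components = ncomp,
                          area_px = area,
                          stringsAsFactors = FALSE),
      nucleus_masks = stamps)
    structure(list(section = section, truth = truth, spec = spec),
              class = "synthetic_section")
  })
}

#' Write a synthetic section to disk
#'
#' Writes the three channels as 16-bit TIFFs (intensities rounded) plus a
#' JSON ground-truth sidecar holding the spec, the vessel area fraction and
#' the per-nucleus table (pixel masks are not serialized).
#'
#' @param synth a `synthetic_section` from [generate_section()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
write_synthetic_section <- function(synth, dir, prefix = "synthetic") {
  stopifnot(inherits(synth, "synthetic_section"))
  suppressWarnings(write_section(synth$section, dir, prefix))
  sidecar <- file.path(dir, sprintf("%s_truth.json", prefix))
  payload <- list(
    spec = unclass(synth$spec),
    has_vessels = synth$truth$has_vessels,
    vessel_area_fraction = synth$truth$vessel_area_fraction,
    nuclei = synth$truth$nuclei[, c("id", "row", "col", "class",
                                    "n_components", "area_px")])
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
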