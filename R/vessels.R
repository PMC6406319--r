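#' Fuzzy c-means clustering of intensity values
#'
#' Minimizes the fuzzy within-cluster objective
#' \deqn{J_m(U, V) = \sum_i \sum_j u_{ij}^m (x_i - v_j)^2,\qquad
#'       \sum_j u_{ij} = 1}
#' by alternating the standard membership and centroid updates until the
#' largest centroid change falls below `tol` or `max_iter` is reached. The
#' objective is recorded after every membership update and is non-increasing
#' across iterations. Initial centroids are drawn (reproducibly, from `seed`)
#' from the distinct observed values, so the result is deterministic for a
#' given seed and equivariant under positive affine rescaling of the input.
#'
#' @param x numeric vector of intensity values.
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1); 2 is the usual choice.
#' @param tol convergence tolerance on the centroid update.
#' @param max_iter maximum number of iterations.
#' @param seed integer seed for centroid initialization.
#' @return a list of class `fcm` with `centroids`, `membership` (rows sum to
#'   1), `objective` (trace over iterations), `iterations`, `converged`.
#' @examples
#' f <- fuzzy_c_means(c(0, 0, 0, 10, 10, 10), c = 2)
#' sort(f$centroids)
#' @export
fuzzy_c_means <- function(x, c = 2, m = 2, tol = 1e-5, max_iter = 300,
                          seed = 1) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  if (c < 2) stop("'c' must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier 'm' must be > 1", call. = FALSE)
  ux <- unique(x)
  if (length(ux) < c)
    stop("degenerate input: fewer distinct values than clusters",
         call. = FALSE)

  v <- with_rng_seed(seed, function() ux[sample.int(length(ux), c)])
  n <- length(x)
  expo <- -1 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps
    w <- d2
    w[!zero] <- d2[!zero]^expo
    u <- w / rowSums(w)
    hit <- rowSums(zero) > 0
    if (any(hit)) {                       # crisp membership at a centroid
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    v_new <- colSums(um * x) / colSums(um)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("fuzzy c-means did not converge in %d iterations (last centroid change %.3g)",
                    max_iter, delta))
  structure(list(centroids = v, membership = u, objective = obj,
                 iterations = length(obj), converged = converged),
            class = "fcm")
}

#' Segment functional vessels from the lectin channel
#'
#' Clusters the vessel-channel pixel intensities with [fuzzy_c_means()] and
#' hard-assigns each pixel to the cluster with the larger membership; the
#' cluster with the higher intensity centroid is the vessel class. Ties are
#' broken toward non-vessel (a pixel must have strictly larger vessel
#' membership to be called vessel). Objects smaller than `min_size_px`
#' pixels are optionally removed and the cleanup is recorded.
#'
#' @param section a `section_image`.
#' @param c,m,tol,max_iter,seed passed to [fuzzy_c_means()].
#' @param min_size_px minimum object size kept after segmentation (0 = no
#'   cleanup).
#' @return a list of class `vessel_mask` with `mask` (binary matrix),
#'   `vascular_density` (vessel / total tumor area), `density_ratio`
#'   (vessel / non-vessel, the secondary convention), `fcm_centroids`,
#'   `fcm_membership_summary` (per-cluster mean membership) and `provenance`.
#' @export
segment_vessels <- function(section, c = 2, m = 2, tol = 1e-5,
                            max_iter = 300, seed = 1, min_size_px = 0) {
  stopifnot(inherits(section, "section_image"))
  ch <- section$vessels
  if (diff(range(ch)) == 0)
    stop("degenerate vessel channel: constant intensity", call. = FALSE)
  fit <- fuzzy_c_means(as.vector(ch), c = c, m = m, tol = tol,
                       max_iter = max_iter, seed = seed)
  vcl <- which.max(fit$centroids)
  u_v <- fit$membership[, vcl]
  u_other <- do.call(pmax, as.data.frame(fit$membership[, -vcl, drop = FALSE]))
  mask <- matrix(as.integer(u_v > u_other), nrow(ch), ncol(ch))

  removed <- 0L
  if (min_size_px > 0 && any(mask == 1)) {
    lab <- as_plain_matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(mask))))
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_size_px)
    if (length(drop)) {
      removed <- length(drop)
      mask[lab %in% drop] <- 0L
    }
  }

  tumor <- section$tumor_mask
  dens <- if (!is.null(tumor)) vascular_density(mask, tumor)
          else vascular_density(mask)
  ratio <- if (!is.null(tumor)) vascular_density(mask, tumor, "ratio")
           else vascular_density(mask, convention = "ratio")
  structure(list(
    mask = mask,
    vascular_density = dens,
    density_ratio = ratio,
    fcm_centroids = fit$centroids,
    fcm_membership_summary = colMeans(fit$membership),
    provenance = list(c = c, m = m, tol = tol, seed = seed,
                      min_size_px = min_size_px,
                      objects_removed = removed,
                      iterations = fit$iterations,
                      converged = fit$converged)),
    class = "vessel_mask")
}

#' Vascular density of a segmented vessel mask
#'
#' Primary convention: vessel pixel count divided by total tumor pixel
#' count, a fraction in `[0, 1]`. The secondary convention
#' (`convention = "ratio"`) reports vessel area / non-vessel area instead.
#'
#' @param mask binary vessel matrix, or a `vessel_mask` object.
#' @param tumor_mask optional binary matrix restricting the tumor area; when
#'   absent the whole image is used.
#' @param convention `"total"` (default) or `"ratio"`.
#' @return a single numeric density.
#' @export
vascular_density <- function(mask, tumor_mask = NULL,
                             convention = c("total", "ratio")) {
  convention <- match.arg(convention)
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  check_binary_mask(mask, "mask")
  if (is.null(tumor_mask)) {
    tumor_mask <- matrix(1L, nrow(mask), ncol(mask))
  } else {
    check_binary_mask(tumor_mask, "tumor_mask")
    if (!identical(dim(tumor_mask), dim(mask)))
      stop("mask shapes differ", call. = FALSE)
  }
  total <- sum(tumor_mask)
  if (total == 0) stop("empty tumor area", call. = FALSE)
  vessel <- sum(mask * tumor_mask)
  if (convention == "total") return(vessel / total)
  nonvessel <- total - vessel
  if (nonvessel == 0) stop("no non-vessel area in tumor", call. = FALSE)
  vessel / nonvessel
}
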