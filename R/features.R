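#' Bright-detail image: small bright spots only
#'
#' White top-hat transform: the input minus its morphological opening by a
#' disk of the given radius. Structures wider than the disk (uniform staining,
#' broad autofluorescence) are removed; compact puncta — such as the
#' rolling-circle amplification products of a proximity ligation assay —
#' survive. Everywhere nonnegative.
#'
#' @param grid Numeric matrix.
#' @param radius Disk radius in pixels (default 3: spots of radius 3 px or
#'   less are retained).
#' @return Matrix of the same shape, `>= 0`.
#' @export
bright_detail_image <- function(grid, radius = 3) {
  stopifnot(is.matrix(grid), radius >= 1)
  kern <- EBImage::makeBrush(2 * radius + 1, "disc")
  pmax(grid - gray_opening(grid, kern), 0)
}

# Grayscale opening (min-then-max filter over the brush, in-image
# neighborhoods). EBImage switches to its binary algorithm when the input has
# at most two distinct values; in that case the grayscale opening is
# reconstructed exactly from the binary opening of the upper level set.
gray_opening <- function(x, kern) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x)
  if (all(x == rng[1] | x == rng[2])) {
    bin <- (EBImage::opening(x > rng[1], kern) > 0)
    out <- rng[1] + (rng[2] - rng[1]) * bin
    dim(out) <- dim(x)
    return(out)
  }
  # EBImage clips grayscale intensities to [0, 1]; rescale by a power of two
  # (exact under IEEE arithmetic — min/max filtering only selects values)
  mx <- max(x)
  if (mx <= 1) return(as.array(EBImage::opening(x, kern)))
  sc <- 2^ceiling(log2(mx))
  as.array(EBImage::opening(x / sc, kern)) * sc
}

#' Bright Detail Intensity (BDI)
#'
#' The summed intensity of localized bright spots (radius `radius` px or less)
#' within the masked area: the sum of [bright_detail_image()] over mask
#' pixels.
#'
#' @inheritParams bright_detail_image
#' @param mask Logical matrix of the same shape.
#' @return Nonnegative scalar; `0` with a warning for an empty mask.
#' @export
bright_detail_intensity <- function(grid, mask, radius = 3) {
  stopifnot(identical(dim(grid), dim(mask)))
  if (!any(mask)) {
    warning("empty mask: BDI is 0.", call. = FALSE)
    return(0)
  }
  sum(bright_detail_image(grid, radius)[mask])
}

#' Background level of a channel grid
#'
#' Estimate used by [max_pixel()] and the staining-area feature: the
#' half-sample mode of the pixels outside the mask (robust, shift- and
#' scale-equivariant). When every pixel is inside the mask, falls back to the
#' mean of the lowest decile of the masked pixels.
#'
#' @inheritParams bright_detail_intensity
#' @return Scalar background estimate.
#' @export
estimate_background <- function(grid, mask) {
  stopifnot(identical(dim(grid), dim(mask)))
  out <- grid[!mask]
  if (length(out) >= 3L) return(half_sample_mode(out))
  v <- sort(grid[mask])
  if (length(v) == 0L) return(0)
  mean(v[seq_len(max(1L, floor(length(v) / 10)))])
}

# Half-sample mode (Robertson & Cryer): repeatedly keep the half of the
# sorted sample with the smallest range. Exactly equivariant under x -> a*x+b.
half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3L) {
    k <- ceiling(length(x) / 2)
    w <- x[seq(k, length(x))] - x[seq_len(length(x) - k + 1L)]
    i <- which.min(w)
    x <- x[seq(i, i + k - 1L)]
  }
  if (length(x) == 3L) {
    d1 <- x[2] - x[1]; d2 <- x[3] - x[2]
    if (d1 < d2) return(mean(x[1:2]))
    if (d2 < d1) return(mean(x[2:3]))
    return(x[2])
  }
  mean(x)
}

#' Max Pixel
#'
#' The largest background-subtracted pixel value within the mask, floored at
#' zero. The background is estimated from outside the mask (see
#' [estimate_background()]) unless supplied.
#'
#' @inheritParams bright_detail_intensity
#' @param background Optional precomputed background level.
#' @return Nonnegative scalar; `0` with a warning for an empty mask.
#' @export
max_pixel <- function(grid, mask, background = NULL) {
  stopifnot(identical(dim(grid), dim(mask)))
  if (!any(mask)) {
    warning("empty mask: max pixel is 0.", call. = FALSE)
    return(0)
  }
  if (is.null(background)) background <- estimate_background(grid, mask)
  max(max(grid[mask]) - background, 0)
}

#' Max Contour Position (MCP)
#'
#' Normalized radial position of the concentric ring with the highest
#' intensity concentration: `0` is the object center, `1` the perimeter. Low
#' MCP indicates interior (nuclear) signal; values near 1 indicate membranal
#' signal. The mask is partitioned into `n_rings` rings of equal normalized
#' width by the Euclidean distance to the mask boundary; the returned value is
#' the midpoint of the ring with the highest mean intensity per pixel
#' (innermost ring wins ties).
#'
#' @inheritParams bright_detail_intensity
#' @param n_rings Number of concentric rings (`>= 2`, default 8).
#' @return Scalar in \[0, 1\]; `NA` (missing feature) for an empty mask.
#' @export
max_contour_position <- function(grid, mask, n_rings = 8) {
  stopifnot(identical(dim(grid), dim(mask)), n_rings >= 2)
  if (!any(mask)) {
    warning("empty mask: MCP undefined.", call. = FALSE)
    return(NA_real_)
  }
  d <- EBImage::distmap(mask)
  mcp_from_distances(grid[mask], d[mask], n_rings)
}

# Ring partition of a mask by normalized boundary distance; reusable across
# channels of one cell.
mcp_ring_prep <- function(dists, n_rings) {
  dmin <- min(dists); dmax <- max(dists)
  if (dmax <= dmin) return(NULL) # degenerate thin mask: single ring
  pos <- (dmax - dists) / (dmax - dmin) # 0 = center, 1 = boundary
  ring <- pmin(floor(pos * n_rings) + 1L, n_rings)
  list(ring = ring, cnt = tabulate(ring, n_rings))
}

mcp_from_rings <- function(vals, prep, n_rings) {
  if (is.null(prep)) return(0.5)
  sums <- numeric(n_rings)
  acc <- rowsum(vals, prep$ring)
  sums[as.integer(rownames(acc))] <- acc
  means <- ifelse(prep$cnt > 0, sums / prep$cnt, -Inf)
  (which.max(means) - 0.5) / n_rings
}

# Shared ring-binning given masked intensities and their boundary distances.
mcp_from_distances <- function(vals, dists, n_rings) {
  mcp_from_rings(vals, mcp_ring_prep(dists, n_rings), n_rings)
}

#' Bright Detail Similarity (BDS)
#'
#' Log-transformed Pearson correlation of the localized bright spots (radius
#' `radius` px or less) of two channels within the masked area: the Fisher
#' z-transform `0.5 * log((1 + r) / (1 - r))` of the correlation between the
#' two bright-detail images over mask pixels, with `r` clipped to
#' `c(-clip, clip)`. High BDS flags strong signal overlay between channels —
#' fluorescence penetrating from one channel into another that compensation
#' cannot resolve.
#'
#' @param grid_a,grid_b Numeric matrices of one shape.
#' @inheritParams bright_detail_intensity
#' @param clip Correlation clip bound (default 0.999, capping BDS at about
#'   3.8).
#' @return Scalar; `0` when either bright-detail image has zero variance over
#'   the mask; `NA` (missing feature) when the mask has fewer than 3 pixels.
#' @export
bright_detail_similarity <- function(grid_a, grid_b, mask, radius = 3,
                                     clip = 0.999) {
  stopifnot(identical(dim(grid_a), dim(grid_b)),
            identical(dim(grid_a), dim(mask)))
  if (sum(mask) < 3L) {
    warning("mask has < 3 pixels: BDS undefined.", call. = FALSE)
    return(NA_real_)
  }
  a <- bright_detail_image(grid_a, radius)[mask]
  b <- bright_detail_image(grid_b, radius)[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  r <- stats::cor(a, b)
  r <- max(min(r, clip), -clip)
  0.5 * log((1 + r) / (1 - r))
}

#' Staining area
#'
#' Number of mask pixels whose background-subtracted intensity exceeds a
#' fraction of the cell's Max Pixel. Compact punctate staining gives a small
#' area; diffuse autofluorescence lifts the whole cell above the cutoff and
#' gives an area close to the full mask — which the gating cascade's area
#' range then rejects.
#'
#' @inheritParams max_pixel
#' @param frac Fraction of Max Pixel defining "stained" (default 0.5).
#' @return Integer pixel count (`0` when Max Pixel is 0 or the mask is empty).
#' @export
staining_area <- function(grid, mask, background = NULL, frac = 0.5) {
  stopifnot(identical(dim(grid), dim(mask)))
  if (!any(mask)) return(0L)
  if (is.null(background)) background <- estimate_background(grid, mask)
  mp <- max_pixel(grid, mask, background = background)
  if (mp <= 0) return(0L)
  sum((grid[mask] - background) > frac * mp)
}

#' Background-subtracted total intensity
#'
#' Sum over mask pixels of the channel minus its background estimate, floored
#' at zero. Used for marker-based population gating and spillover estimation.
#'
#' @inheritParams max_pixel
#' @return Nonnegative scalar.
#' @export
total_intensity <- function(grid, mask, background = NULL) {
  stopifnot(identical(dim(grid), dim(mask)))
  if (!any(mask)) return(0)
  if (is.null(background)) background <- estimate_background(grid, mask)
  max(sum(grid[mask]) - background * sum(mask), 0)
}
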