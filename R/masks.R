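#' Morphology mask: all pixels within the outermost image contour
#'
#' Thresholds the grid (Otsu by default), keeps the largest connected
#' component, and fills its holes so that everything inside the outermost
#' contour — including dark interior pixels — belongs to the mask.
#'
#' @param grid Numeric matrix of finite, nonnegative intensities.
#' @param method `"otsu"` (threshold chosen by Otsu's criterion on the grid)
#'   or `"fixed"`.
#' @param threshold Threshold value when `method = "fixed"`; pixels strictly
#'   above it are foreground.
#' @return Logical matrix with attribute `provenance = "MORPHOLOGY"`. An
#'   all-zero grid yields an empty mask with a warning.
#' @export
morphology_mask <- function(grid, method = c("otsu", "fixed"),
                            threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(grid), all(is.finite(grid)))
  mx <- max(grid)
  if (mx <= 0) {
    warning("all-zero image: empty morphology mask.", call. = FALSE)
    return(mask_with_provenance(matrix(FALSE, nrow(grid), ncol(grid)),
                                "MORPHOLOGY"))
  }
  thr <- if (method == "fixed") {
    stopifnot(is.numeric(threshold))
    threshold
  } else {
    EBImage::otsu(grid / mx, range = c(0, 1)) * mx
  }
  fg <- grid > thr
  if (!any(fg)) {
    warning("threshold leaves no foreground: empty morphology mask.",
            call. = FALSE)
    return(mask_with_provenance(fg, "MORPHOLOGY"))
  }
  lab <- EBImage::bwlabel(fg)
  keep <- which.max(tabulate(lab[lab > 0]))
  m <- lab == keep
  m <- EBImage::fillHull(m) > 0
  mask_with_provenance(m, "MORPHOLOGY")
}

mask_with_provenance <- function(m, provenance) {
  storage.mode(m) <- "logical"
  attr(m, "provenance") <- provenance
  m
}

erode_brush <- function() EBImage::makeBrush(3, "box")

#' Adaptive-erode mask: shape-aware interior of a base mask
#'
#' Iteratively erodes the base mask and returns the largest eroded version
#' whose pixel area is still at least `percent`/100 of the base area. Because
#' erosion follows the mask's own boundary, the result adapts to the cell's
#' shape; at the default 78 it isolates the cell interior, excluding the
#' membranal rim where nonspecific PLA probe binding accumulates.
#'
#' @param base Logical matrix (e.g. from [morphology_mask()]).
#' @param percent Retained-area percentage in \[0, 100\]. `100` returns the
#'   base unchanged; `0` returns the last non-empty erosion (the shape's inner
#'   core).
#' @return Logical matrix, a subset of `base`, with attribute
#'   `provenance = "ADAPTIVE_ERODE"` and attribute `percent`.
#' @export
adaptive_erode_mask <- function(base, percent = 78) {
  stopifnot(is.logical(base), is.matrix(base), percent >= 0, percent <= 100)
  base_area <- sum(base)
  if (base_area == 0L) {
    warning("empty base mask: empty adaptive-erode mask.", call. = FALSE)
    out <- mask_with_provenance(base, "ADAPTIVE_ERODE")
    attr(out, "percent") <- percent
    return(out)
  }
  target <- percent / 100 * base_area
  m <- base
  kern <- erode_brush()
  repeat {
    m2 <- EBImage::erode(m, kern) > 0
    a2 <- sum(m2)
    if (a2 >= max(target, 1) && a2 < sum(m)) m <- m2 else break
  }
  out <- mask_with_provenance(m, "ADAPTIVE_ERODE")
  attr(out, "percent") <- percent
  out
}

# Batched versions over rows x cols x n stacks. EBImage applies 2D kernels
# framewise, so these agree exactly with the per-image operators.

morphology_mask_stack <- function(stack) {
  d <- dim(stack)
  mx <- apply(stack, 3, max)
  thr <- rep(0, d[3])
  pos <- mx > 0
  if (any(pos)) {
    norm <- stack[, , pos, drop = FALSE]
    for (i in seq_len(sum(pos))) norm[, , i] <- norm[, , i] / mx[pos][i]
    thr[pos] <- EBImage::otsu(norm, range = c(0, 1)) * mx[pos]
  }
  fg <- array(FALSE, d)
  for (i in seq_len(d[3])) fg[, , i] <- stack[, , i] > thr[i]
  lab <- EBImage::bwlabel(fg)
  m <- array(FALSE, d)
  for (i in seq_len(d[3])) {
    li <- lab[, , i]
    if (any(li > 0)) m[, , i] <- li == which.max(tabulate(li[li > 0]))
  }
  (EBImage::fillHull(m) > 0)
}

adaptive_erode_stack <- function(base, percent) {
  d <- dim(base)
  areas0 <- apply(base, 3, sum)
  target <- pmax(percent / 100 * areas0, 1)
  cur <- base
  out <- base
  active <- areas0 > 0
  kern <- erode_brush()
  prev <- areas0
  while (any(active)) {
    nxt <- (EBImage::erode(cur, kern) > 0)
    a <- apply(nxt, 3, sum)
    accept <- active & a >= target & a < prev
    if (any(accept)) out[, , accept] <- nxt[, , accept]
    active <- accept
    cur <- nxt
    prev <- a
  }
  out
}
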