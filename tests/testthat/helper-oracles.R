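# Brute-force reference implementations, independent of the EBImage-based
# code paths under test. All use explicit neighborhood scans / flood fills on
# small grids; in-image neighborhoods (pixels outside the grid are ignored).

disc_offsets <- function(radius) {
  side <- 2 * radius + 1
  ctr <- radius + 1
  k <- EBImage::makeBrush(side, "disc") # geometry only: which offsets
  w <- which(k == 1, arr.ind = TRUE)
  cbind(w[, 1] - ctr, w[, 2] - ctr)
}

box_offsets <- function() as.matrix(expand.grid(-1:1, -1:1))

neighborhood_filter <- function(x, offsets, fun) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- i + offsets[, 1]; jj <- j + offsets[, 2]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- fun(x[cbind(ii[ok], jj[ok])])
    }
  }
  out
}

# white top-hat: input minus min-then-max filtering over the disc
oracle_bright_detail <- function(x, radius = 3) {
  off <- disc_offsets(radius)
  er <- neighborhood_filter(x, off, min)
  op <- neighborhood_filter(er, off, max)
  pmax(x - op, 0)
}

oracle_binary_erode <- function(m) {
  out <- neighborhood_filter(m * 1, box_offsets(), min)
  out > 0.5
}

# iterative-erosion area-count reference for the adaptive-erode mask
oracle_adaptive_erode <- function(base, percent) {
  target <- percent / 100 * sum(base)
  m <- base
  repeat {
    m2 <- oracle_binary_erode(m)
    if (sum(m2) >= max(target, 1) && sum(m2) < sum(m)) m <- m2 else break
  }
  m
}

# threshold -> label (BFS flood fill, 4-connected) -> largest component ->
# fill holes by flood-filling background from the border
oracle_morphology_mask <- function(x, threshold) {
  nr <- nrow(x); nc <- ncol(x)
  fg <- x > threshold
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  steps <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in which(fg)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
      for (d in steps) {
        ii <- qi + d[1]; jj <- qj + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            fg[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  if (cur == 0L) return(matrix(FALSE, nr, nc))
  keep <- which.max(tabulate(lab[lab > 0L]))
  comp <- lab == keep
  # hole fill: 4-connected background reachable from the border stays out
  outside <- matrix(FALSE, nr, nc)
  queue <- integer(0)
  for (i in seq_len(nr)) for (j in c(1L, nc)) {
    if (!comp[i, j]) { outside[i, j] <- TRUE; queue <- c(queue, (j - 1L) * nr + i) }
  }
  for (j in seq_len(nc)) for (i in c(1L, nr)) {
    if (!comp[i, j] && !outside[i, j]) {
      outside[i, j] <- TRUE; queue <- c(queue, (j - 1L) * nr + i)
    }
  }
  while (length(queue) > 0) {
    q <- queue[1]; queue <- queue[-1]
    qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- qi + d[1]; jj <- qj + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !comp[ii, jj] && !outside[ii, jj]) {
        outside[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1L) * nr + ii)
      }
    }
  }
  !outside
}

# exhaustive distance transform: min Euclidean distance to any non-mask
# pixel (pixels beyond the grid are not background), then ring binning by
# normalized distance
oracle_mcp <- function(x, mask, n_rings = 8) {
  nr <- nrow(x); nc <- ncol(x)
  inside <- which(mask)
  bg <- which(!mask)
  d <- numeric(length(inside))
  bi <- (bg - 1L) %% nr + 1L; bj <- (bg - 1L) %/% nr + 1L
  for (k in seq_along(inside)) {
    i <- (inside[k] - 1L) %% nr + 1L; j <- (inside[k] - 1L) %/% nr + 1L
    d[k] <- if (length(bg) > 0) {
      min(sqrt((bi - i)^2 + (bj - j)^2))
    } else {
      Inf
    }
  }
  dmin <- min(d); dmax <- max(d)
  if (dmax <= dmin) return(0.5)
  pos <- (dmax - d) / (dmax - dmin)
  ring <- pmin(floor(pos * n_rings) + 1L, n_rings)
  means <- rep(-Inf, n_rings)
  for (r in unique(ring)) means[r] <- mean(x[mask][ring == r])
  (which.max(means) - 0.5) / n_rings
}

oracle_bds <- function(a, b, mask, radius = 3, clip = 0.999) {
  ta <- oracle_bright_detail(a, radius)[mask]
  tb <- oracle_bright_detail(b, radius)[mask]
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) return(0)
  r <- sum((ta - mean(ta)) * (tb - mean(tb))) /
    sqrt(sum((ta - mean(ta))^2) * sum((tb - mean(tb))^2))
  r <- max(min(r, clip), -clip)
  0.5 * log((1 + r) / (1 - r))
}

# sorted-array type-7 percentile
oracle_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# small random test images: smooth blob + puncta + noise
random_cell_grid <- function(side = 31, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctr <- (side + 1) / 2
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+")
  r <- stats::runif(1, side / 5, side / 3)
  g <- 50 * exp(-d2 / (2 * r^2))
  npk <- sample(0:4, 1)
  for (k in seq_len(npk)) {
    cx <- stats::runif(1, 4, side - 3); cy <- stats::runif(1, 4, side - 3)
    dd <- outer((seq_len(side) - cx)^2, (seq_len(side) - cy)^2, "+")
    g <- g + stats::runif(1, 50, 300) * exp(-dd / (2 * 0.8^2))
  }
  pmax(g + matrix(stats::rnorm(side^2, 0, 4), side, side), 0)
}

default_disk_mask <- function(side = 31, radius = 10) {
  ctr <- (side + 1) / 2
  outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+") <= radius^2
}

# offset-loop brute force: same in-image neighborhood semantics as
# neighborhood_filter, vectorized over pixels for the larger acceptance runs
shift_filter <- function(x, offsets, op = c("min", "max")) {
  op <- match.arg(op)
  pad <- if (op == "min") Inf else -Inf
  nr <- nrow(x); nc <- ncol(x)
  acc <- matrix(pad, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets[k, 1]; dj <- offsets[k, 2]
    sh <- matrix(pad, nr, nc)
    ri <- max(1, 1 - di):min(nr, nr - di)
    rj <- max(1, 1 - dj):min(nc, nc - dj)
    sh[ri, rj] <- x[ri + di, rj + dj, drop = FALSE]
    acc <- if (op == "min") pmin(acc, sh) else pmax(acc, sh)
  }
  acc
}

oracle_bright_detail_fast <- function(x, radius = 3) {
  off <- disc_offsets(radius)
  er <- shift_filter(x, off, "min")
  pmax(x - shift_filter(er, off, "max"), 0)
}

oracle_binary_erode_fast <- function(m) {
  shift_filter(m * 1, box_offsets(), "min") > 0.5
}

oracle_adaptive_erode_fast <- function(base, percent) {
  target <- percent / 100 * sum(base)
  m <- base
  repeat {
    m2 <- oracle_binary_erode_fast(m)
    if (sum(m2) >= max(target, 1) && sum(m2) < sum(m)) m <- m2 else break
  }
  m
}
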