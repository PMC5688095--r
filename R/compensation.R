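#' Spillover matrix
#'
#' Square mixing matrix of fluorescent dye overlap between detection
#' channels: rows are source channels, columns detected channels; entry
#' `[k, j]` is the fraction of channel `k`'s signal detected in channel `j`.
#' Diagonal is 1; off-diagonals lie in `[0, 1)`.
#'
#' @param x Square numeric matrix, or `NULL` for the identity.
#' @param channels Channel names (used when `x` is `NULL` or unnamed).
#' @return Validated spillover matrix with channel dimnames.
#' @export
spillover_matrix <- function(x = NULL, channels = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(channels))
    x <- diag(length(channels))
    dimnames(x) <- list(channels, channels)
  }
  if (is.null(rownames(x)) && !is.null(channels)) {
    dimnames(x) <- list(channels, channels)
  }
  check_spillover(x, rownames(x))
  x
}

check_spillover <- function(S, channels = NULL, max_kappa = 1e6) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop("spillover must be a square matrix.", call. = FALSE)
  }
  if (!is.null(channels)) {
    if (is.null(rownames(S)) || !setequal(rownames(S), channels)) {
      stop("spillover dimnames must match the channel names.", call. = FALSE)
    }
  }
  if (any(abs(diag(S) - 1) > 1e-12)) {
    stop("spillover diagonal must be 1.", call. = FALSE)
  }
  off <- S[row(S) != col(S)]
  if (any(off < 0 | off >= 1)) {
    stop("off-diagonal spillover coefficients must lie in [0, 1).",
         call. = FALSE)
  }
  if (kappa(S) > max_kappa) {
    stop("spillover matrix is ill-conditioned (condition number > ",
         format(max_kappa), ").", call. = FALSE)
  }
  invisible(S)
}

#' Estimate the spillover matrix from single-stain controls
#'
#' For the control stained only in source channel `k`, each cell's summed
#' intensity in every channel is measured over its morphology mask (seeded
#' from the source channel, since controls carry no other signal) with the
#' out-of-mask mean subtracted — removing the positive bias that zero-clipped
#' read noise would otherwise add to off-channel sums. Row `k` of the matrix
#' is the per-cell median of off-channel/source-channel sum ratios; the
#' diagonal is forced to 1. Cells whose source-channel sum falls below
#' `min_source_signal` are excluded as zero-signal events.
#'
#' @param controls Named list of [plic_sample()] objects, one per channel,
#'   names = source channel (e.g. from [simulate_single_stain_controls()]).
#' @param min_source_signal Floor on the source-channel summed intensity for a
#'   cell to enter the estimate.
#' @return A spillover matrix (see [spillover_matrix()]).
#' @export
estimate_spillover <- function(controls, min_source_signal = 100) {
  stopifnot(is.list(controls), !is.null(names(controls)))
  chans <- names(controls)
  K <- length(chans)
  S <- diag(K)
  dimnames(S) <- list(chans, chans)
  for (k in seq_len(K)) {
    ctrl <- controls[[k]]
    stopifnot(inherits(ctrl, "plic_sample"))
    src <- chans[k]
    sums <- control_channel_sums(ctrl, chans, src)
    keep <- sums[, src] >= min_source_signal
    if (!any(keep)) {
      stop("control for channel '", src,
           "' has no cells above the signal floor; cannot estimate its ",
           "spillover row.", call. = FALSE)
    }
    for (j in seq_len(K)) {
      if (j == k) next
      S[k, j] <- max(stats::median(sums[keep, chans[j]] / sums[keep, src]), 0)
    }
  }
  check_spillover(S, chans)
  S
}

# Background-subtracted per-cell channel sums over the source-channel
# morphology mask.
control_channel_sums <- function(ctrl, chans, src) {
  n <- length(ctrl$cells)
  out <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  src_stack <- channel_stack(ctrl, src)
  masks <- morphology_mask_stack(src_stack)
  npix <- prod(dim(ctrl$cells[[1]]))
  Mm <- matrix(masks, npix, n)
  for (nm in chans) {
    X <- matrix(channel_stack(ctrl, nm), npix, n)
    for (i in seq_len(n)) {
      m <- Mm[, i]
      if (!any(m)) next
      bg <- mean(X[!m, i])
      out[i, nm] <- max(sum(X[m, i]) - bg * sum(m), 0)
    }
  }
  out
}

#' Compensate a cell image for spillover
#'
#' Pixelwise linear unmixing: solves `observed = true %*% S` for the true
#' signal at every pixel and floors negatives at zero. Channel names and roles
#' are preserved.
#'
#' @param cell A [cell_image()].
#' @param S Spillover matrix covering the cell's channels.
#' @return A compensated [cell_image()].
#' @export
compensate <- function(cell, S) {
  stopifnot(inherits(cell, "cell_image"))
  chans <- channel_names(cell)
  check_spillover(S, chans)
  Sinv <- solve(S[chans, chans, drop = FALSE])
  X <- vapply(cell$channels, as.vector, numeric(prod(dim(cell))))
  X <- pmax(X %*% Sinv, 0)
  d <- dim(cell)
  out <- cell
  for (j in seq_along(chans)) {
    out$channels[[chans[j]]] <- matrix(X[, j], d[1], d[2])
  }
  out
}

#' Compensate every cell of a sample
#'
#' @param sample A [plic_sample()].
#' @inheritParams compensate
#' @return A compensated [plic_sample()] (truth carried through unchanged).
#' @export
compensate_sample <- function(sample, S) {
  stopifnot(inherits(sample, "plic_sample"))
  if (length(sample$cells) == 0L) return(sample)
  chans <- channel_names(sample$cells[[1]])
  check_spillover(S, chans)
  Sinv <- solve(S[chans, chans, drop = FALSE])
  d <- dim(sample$cells[[1]])
  out <- sample
  for (i in seq_along(sample$cells)) {
    X <- vapply(sample$cells[[i]]$channels, as.vector, numeric(prod(d)))
    X <- pmax(X %*% Sinv, 0)
    for (j in seq_along(chans)) {
      out$cells[[i]]$channels[[chans[j]]] <- matrix(X[, j], d[1], d[2])
    }
  }
  out
}

#' Read / write a spillover matrix as CSV
#'
#' CSV with channel-name header and row names.
#'
#' @param path File path.
#' @return `read_spillover()` returns the validated matrix.
#' @export
read_spillover <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  S <- as.matrix(df)
  check_spillover(S, rownames(S))
  S
}

#' @rdname read_spillover
#' @param S Spillover matrix.
#' @export
write_spillover <- function(S, path) {
  check_spillover(S)
  utils::write.csv(as.data.frame(S), path, row.names = TRUE)
  invisible(path)
}
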