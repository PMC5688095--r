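#' Multichannel image of a single cellular event
#'
#' Imaging flow cytometry yields one small pixel grid per channel per cellular
#' event. A `cell_image` bundles those grids with the role each channel plays
#' in the analysis (brightfield proxy, PLA signal, or a surface marker).
#'
#' @param channels Named list of numeric matrices, one per channel. All
#'   matrices must share one shape and contain finite, nonnegative values.
#' @param roles Named character vector mapping every channel name to one of
#'   `"brightfield"`, `"pla"`, `"marker"`.
#' @return An object of class `cell_image`: a list with elements `channels`
#'   and `roles`.
#' @examples
#' img <- cell_image(
#'   channels = list(BF = matrix(1, 9, 9), PLA = matrix(0, 9, 9)),
#'   roles = c(BF = "brightfield", PLA = "pla")
#' )
#' channel_names(img)
#' @export
cell_image <- function(channels, roles) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices.", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1)))) {
    stop("all channel grids must be matrices of one shape.", call. = FALSE)
  }
  for (nm in names(channels)) {
    g <- channels[[nm]]
    if (!is.numeric(g) || anyNA(g) || any(!is.finite(g)) || any(g < 0)) {
      stop("channel '", nm, "' must be finite and nonnegative.", call. = FALSE)
    }
  }
  roles <- validate_roles(roles, names(channels))
  structure(list(channels = channels, roles = roles[names(channels)]),
            class = "cell_image")
}

validate_roles <- function(roles, channel_names) {
  ok <- c("brightfield", "pla", "marker")
  if (is.null(names(roles)) || !setequal(names(roles), channel_names)) {
    stop("`roles` must be named for exactly the channels present.", call. = FALSE)
  }
  if (!all(roles %in% ok)) {
    stop("channel roles must be one of: ", paste(ok, collapse = ", "), ".",
         call. = FALSE)
  }
  roles
}

#' @rdname cell_image
#' @param x A `cell_image`.
#' @export
channel_names <- function(x) {
  stopifnot(inherits(x, "cell_image"))
  names(x$channels)
}

#' Look up channels by role
#'
#' @param x A `cell_image` or a `plic_sample`.
#' @param role One of `"brightfield"`, `"pla"`, `"marker"`.
#' @return Character vector of channel names with that role (possibly empty).
#' @export
channels_with_role <- function(x, role) {
  roles <- if (inherits(x, "cell_image")) x$roles else x$roles
  names(roles)[roles == role]
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<cell_image> ", d[1], "x", d[2], " px, ", length(x$channels),
      " channels: ", paste0(names(x$channels), " (", x$roles, ")",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_image <- function(x) dim(x$channels[[1]])

#' Collection of cell images with simulation ground truth
#'
#' A `plic_sample` holds the cells of one acquired (or simulated) sample:
#' a list of [cell_image()] objects, the shared channel roles, and — for
#' simulated samples — a ground-truth tibble with one row per cell.
#'
#' @param cells List of `cell_image` objects with identical channels.
#' @param truth Optional tibble of per-cell ground truth (may be `NULL` for
#'   real data).
#' @param roles Named character role vector; taken from the first cell when
#'   omitted.
#' @return An object of class `plic_sample`.
#' @export
plic_sample <- function(cells, truth = NULL, roles = NULL) {
  stopifnot(is.list(cells))
  if (length(cells) > 0L) {
    stopifnot(all(vapply(cells, inherits, logical(1), "cell_image")))
    nm <- channel_names(cells[[1]])
    same <- vapply(cells, function(c) identical(channel_names(c), nm), logical(1))
    if (!all(same)) stop("all cells must share one channel set.", call. = FALSE)
    if (is.null(roles)) roles <- cells[[1]]$roles
  }
  if (length(cells) == 0L && is.null(roles)) roles <- character(0)
  structure(list(cells = cells, truth = truth, roles = roles),
            class = "plic_sample")
}

#' @export
length.plic_sample <- function(x) length(x$cells)

#' @export
print.plic_sample <- function(x, ...) {
  cat("<plic_sample> ", length(x$cells), " cells", sep = "")
  if (length(x$cells) > 0L) {
    d <- dim(x$cells[[1]])
    cat(", ", d[1], "x", d[2], " px, channels: ",
        paste(channel_names(x$cells[[1]]), collapse = ", "), sep = "")
  }
  if (!is.null(x$truth)) cat(" [with ground truth]")
  cat("\n")
  invisible(x)
}

# Stack one channel of every cell into a rows x cols x n array.
# Returns a 3D array even for n = 1 so framewise EBImage ops apply uniformly.
channel_stack <- function(sample, channel) {
  n <- length(sample$cells)
  d <- dim(sample$cells[[1]])
  a <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) a[, , i] <- sample$cells[[i]]$channels[[channel]]
  a
}
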