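#' Write / read a sample as multi-page TIFF with sidecar metadata
#'
#' `write_sample()` stores every cell of a sample in one multi-page TIFF (one
#' page per channel per cell, cells in acquisition order), a channel manifest
#' JSON (channel order, roles and the intensity scale used to fit the data
#' into the 32-bit float TIFF range), and — when ground truth is present — a
#' truth CSV (speckle coordinates serialized as JSON within the table).
#' `read_sample()` reconstructs the [plic_sample()].
#'
#' @param sample A [plic_sample()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the files (`<name>.tiff`, `<name>_manifest.json`,
#'   `<name>_truth.csv`).
#' @return `write_sample()` returns `dir` invisibly; `read_sample()` a
#'   `plic_sample`.
#' @export
write_sample <- function(sample, dir, name = "sample") {
  stopifnot(inherits(sample, "plic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(sample$cells)
  chans <- if (n > 0) channel_names(sample$cells[[1]]) else names(sample$roles)
  scale <- 1
  if (n > 0) {
    mx <- max(vapply(sample$cells,
                     function(c) max(vapply(c$channels, max, numeric(1))),
                     numeric(1)))
    if (mx > 0) scale <- mx
    pages <- list()
    for (i in seq_len(n)) {
      for (nm in chans) {
        pages[[length(pages) + 1L]] <- sample$cells[[i]]$channels[[nm]] / scale
      }
    }
    tiff::writeTIFF(pages, file.path(dir, paste0(name, ".tiff")),
                    bits.per.sample = 32L)
  }
  manifest <- list(n_cells = n, channels = as.list(sample$roles),
                   channel_order = chans, intensity_scale = scale)
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(sample$truth) && nrow(sample$truth) > 0) {
    tr <- sample$truth
    for (col in names(tr)) {
      if (is.list(tr[[col]])) {
        tr[[col]] <- vapply(tr[[col]], function(x) {
          as.character(jsonlite::toJSON(x, digits = NA))
        }, character(1))
      }
    }
    utils::write.csv(tr, file.path(dir, paste0(name, "_truth.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir, name = "sample") {
  manifest <- jsonlite::read_json(file.path(dir,
                                            paste0(name, "_manifest.json")),
                                  simplifyVector = TRUE)
  roles <- unlist(manifest$channels)
  chans <- manifest$channel_order
  n <- manifest$n_cells
  cells <- list()
  if (n > 0) {
    pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tiff")), all = TRUE)
    stopifnot(length(pages) == n * length(chans))
    k <- 0L
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      grids <- stats::setNames(vector("list", length(chans)), chans)
      for (nm in chans) {
        k <- k + 1L
        grids[[nm]] <- pmax(pages[[k]] * manifest$intensity_scale, 0)
      }
      cells[[i]] <- cell_image(grids, roles)
    }
  }
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- tibble::as_tibble(utils::read.csv(truth_path,
                                               stringsAsFactors = FALSE))
    for (col in intersect(c("speckles", "markers"), names(truth))) {
      truth[[col]] <- lapply(truth[[col]], function(s) {
        tibble::as_tibble(jsonlite::fromJSON(s))
      })
    }
  }
  plic_sample(cells, truth = truth, roles = roles[chans])
}

#' Write a feature table or call table as CSV
#'
#' @param x Tibble (features, calls, or summaries).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
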