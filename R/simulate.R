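#' Scene parameters for the synthetic single-cell image simulator
#'
#' Describes the geometry, signal morphologies and noise of simulated imaging
#' flow cytometry events. Defaults are chosen so the four signal classes
#' reproduce the qualitative morphologies the gating cascade discriminates:
#' compact nuclear-speckle puncta (true PLA signal), membrane-ring puncta
#' (nonspecific probe binding), uniform elevation across the cell
#' (autofluorescence), and noise only.
#'
#' @param image_side Side of the square pixel grid (odd, default 33).
#' @param cell_radius Cell disk radius in pixels.
#' @param nucleus_radius_fraction Nucleus radius as a fraction of the cell
#'   radius, strictly inside (0, 1).
#' @param speckle_lambda Mean punctum count per positive cell. Counts are drawn
#'   zero-truncated Poisson: a cell carrying the punctate class has at least
#'   one rolling-circle product by definition.
#' @param speckle_radius Punctum radius in pixels; must not exceed the
#'   bright-detail radius (3 px) used downstream, or planted positives would be
#'   undetectable by construction.
#' @param speckle_amplitude Peak punctum intensity; per-punctum amplitudes vary
#'   log-normally (sdlog `speckle_amp_sdlog`) around it.
#' @param speckle_amp_sdlog Log-sd of per-punctum amplitude variation.
#' @param membrane_ring_width Width of the membranal compartment, in pixels
#'   inward from the cell boundary.
#' @param diffuse_level Per-pixel elevation of autofluorescent cells.
#' @param noise_sd Additive Gaussian read noise sd (clipped at zero).
#' @param bf_level Brightfield-proxy disk intensity.
#' @param channels Named character vector of channel roles. Default has a
#'   brightfield proxy (`BF`), the PLA channel, a target marker (`CD80`-like)
#'   and a control-population marker (`CD45`-like).
#' @param marker_means Named list (per marker channel) of named numeric vectors
#'   (per population) of mean per-pixel marker staining levels. Populations:
#'   `TARGET_HI`, `TARGET_LO`, `CONTROL_POP`.
#' @param marker_sdlog Log-sd of per-cell marker intensity (log-normal within
#'   population, producing the bimodal hi/lo separation the population gate
#'   relies on).
#' @param probes_bg_membrane Peak amplitude of the weak membranal puncta
#'   present in the probes-only background control.
#' @param probes_bg_lambda Mean count of those background puncta (plain
#'   Poisson; zero is allowed).
#' @param probes_bg_diffuse Weak diffuse elevation in the probes-only control.
#' @param neighbor_mode Speckle content of the BDS neighbor channel (the marker
#'   channel spectrally adjacent to PLA): `"none"` (default), `"copy"`
#'   (PLA bright detail leaks into the neighbor — the channel-bleed artifact
#'   the BDS filter removes), or `"independent"` (its own speckle pattern).
#' @param neighbor_scale Intensity scale of copied/independent neighbor
#'   speckles relative to the PLA ones.
#' @param neighbor_channel Channel receiving the `neighbor_mode` signal.
#' @param spillover Optional spillover matrix (see [spillover_matrix()]);
#'   `NULL` means no mixing. Mixing is applied to the noise-free stack, before
#'   read noise, so compensation is exactly recoverable in the noise-free
#'   limit.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_side = 33,
                         cell_radius = 12,
                         nucleus_radius_fraction = 0.5,
                         speckle_lambda = 5,
                         speckle_radius = 1.5,
                         speckle_amplitude = 400,
                         speckle_amp_sdlog = 0.25,
                         membrane_ring_width = 2,
                         diffuse_level = 80,
                         noise_sd = 5,
                         bf_level = 100,
                         channels = c(BF = "brightfield", PLA = "pla",
                                      CD80 = "marker", CD45 = "marker"),
                         marker_means = list(
                           CD80 = c(TARGET_HI = 500, TARGET_LO = 40,
                                    CONTROL_POP = 15),
                           CD45 = c(TARGET_HI = 10, TARGET_LO = 10,
                                    CONTROL_POP = 400)),
                         marker_sdlog = 0.25,
                         probes_bg_membrane = 12,
                         probes_bg_lambda = 2,
                         probes_bg_diffuse = 2,
                         neighbor_mode = c("none", "copy", "independent"),
                         neighbor_scale = 0.8,
                         neighbor_channel = "CD80",
                         spillover = NULL) {
  neighbor_mode <- match.arg(neighbor_mode)
  p <- list(image_side = as.integer(image_side), cell_radius = cell_radius,
            nucleus_radius_fraction = nucleus_radius_fraction,
            speckle_lambda = speckle_lambda, speckle_radius = speckle_radius,
            speckle_amplitude = speckle_amplitude,
            speckle_amp_sdlog = speckle_amp_sdlog,
            membrane_ring_width = membrane_ring_width,
            diffuse_level = diffuse_level, noise_sd = noise_sd,
            bf_level = bf_level, channels = channels,
            marker_means = marker_means, marker_sdlog = marker_sdlog,
            probes_bg_membrane = probes_bg_membrane,
            probes_bg_lambda = probes_bg_lambda,
            probes_bg_diffuse = probes_bg_diffuse,
            neighbor_mode = neighbor_mode, neighbor_scale = neighbor_scale,
            neighbor_channel = neighbor_channel, spillover = spillover)
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (p$image_side < 9L || p$image_side %% 2L == 0L) {
    stop("`image_side` must be odd and >= 9.", call. = FALSE)
  }
  if (p$cell_radius <= 0 || p$membrane_ring_width <= 0 || p$speckle_radius <= 0) {
    stop("radii and widths must be positive.", call. = FALSE)
  }
  if (p$cell_radius >= (p$image_side - 1) / 2) {
    stop("cell must fit strictly inside the image.", call. = FALSE)
  }
  if (p$nucleus_radius_fraction <= 0 || p$nucleus_radius_fraction >= 1) {
    stop("`nucleus_radius_fraction` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (p$speckle_radius > 3) {
    stop("`speckle_radius` must be <= the 3 px bright-detail radius, or ",
         "planted puncta would not be detectable downstream.", call. = FALSE)
  }
  if (p$noise_sd < 0 || p$diffuse_level < 0) {
    stop("intensity levels must be nonnegative.", call. = FALSE)
  }
  if (!all(c("brightfield", "pla") %in% p$channels)) {
    stop("`channels` must include a brightfield-proxy and a pla channel.",
         call. = FALSE)
  }
  if (!is.null(p$spillover)) check_spillover(p$spillover, names(p$channels))
  invisible(p)
}

cell_classes <- c("NUCLEAR_PLA_POS", "MEMBRANAL_FP", "DIFFUSE_AF", "NEGATIVE")
cell_populations <- c("TARGET_HI", "TARGET_LO", "CONTROL_POP")

# Geometry helpers: squared distance of every pixel to the image center,
# in pixel units, 1-based row/col indices.
center_dist2 <- function(side) {
  ctr <- (side + 1) / 2
  outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+")
}

#' Class mix of a simulated sample
#'
#' Builds the population/class proportion table [simulate_sample()] consumes.
#' The planted positive fraction `f_pos` applies within the `TARGET_HI`
#' population only (nuclear-speckle signal is planted in the marker-defined
#' rare population); membranal and diffuse false-positive classes occur in
#' every population.
#'
#' @param f_pos Fraction of `TARGET_HI` cells planted `NUCLEAR_PLA_POS`.
#' @param f_membranal,f_diffuse Within-population fractions of the two
#'   false-positive classes.
#' @param p_target_hi,p_target_lo,p_control Population proportions (must sum
#'   to 1 with each other).
#' @return Tibble with columns `population`, `class`, `prop` summing to 1.
#' @export
population_mix <- function(f_pos = 0.25, f_membranal = 0.05, f_diffuse = 0.05,
                           p_target_hi = 0.35, p_target_lo = 0.25,
                           p_control = 0.40) {
  pops <- c(TARGET_HI = p_target_hi, TARGET_LO = p_target_lo,
            CONTROL_POP = p_control)
  if (any(pops < 0) || abs(sum(pops) - 1) > 1e-8) {
    stop("population proportions must be nonnegative and sum to 1.",
         call. = FALSE)
  }
  if (f_membranal < 0 || f_diffuse < 0 || f_pos < 0 ||
      f_pos + f_membranal + f_diffuse > 1 || f_membranal + f_diffuse > 1) {
    stop("class fractions must be nonnegative and leave room for negatives.",
         call. = FALSE)
  }
  rows <- list()
  for (pop in names(pops)) {
    fp <- if (pop == "TARGET_HI") f_pos else 0
    cls <- c(NUCLEAR_PLA_POS = fp, MEMBRANAL_FP = f_membranal,
             DIFFUSE_AF = f_diffuse)
    cls <- c(cls, NEGATIVE = 1 - sum(cls))
    rows[[pop]] <- tibble::tibble(population = pop, class = names(cls),
                                  prop = unname(cls) * pops[[pop]])
  }
  out <- dplyr::bind_rows(rows)
  out[out$prop > 0, , drop = FALSE]
}

# Draw speckle centers uniformly in the compartment prescribed by the class.
# Retries rejected draws; placement failure after max_tries is an error, per
# the generator contract.
draw_speckle_centers <- function(n, class, p, max_tries = 200L) {
  side <- p$image_side
  ctr <- (side + 1) / 2
  margin <- p$speckle_radius
  if (class == "NUCLEAR_PLA_POS") {
    rmax <- p$cell_radius * p$nucleus_radius_fraction - margin
    rmin <- 0
  } else { # MEMBRANAL_FP or probes-only background ring
    rmax <- p$cell_radius
    rmin <- max(p$cell_radius - p$membrane_ring_width, 0)
  }
  if (rmax <= rmin && class == "NUCLEAR_PLA_POS") {
    stop("speckles of radius ", p$speckle_radius,
         " cannot be placed inside the nucleus; enlarge the nucleus or ",
         "shrink the puncta.", call. = FALSE)
  }
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- sqrt(stats::runif(1, rmin^2, rmax^2))
      th <- stats::runif(1, 0, 2 * pi)
      x <- ctr + r * cos(th); y <- ctr + r * sin(th)
      if (x >= 1 && x <= side && y >= 1 && y <= side) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) stop("failed to place a punctum in its compartment after ",
                  max_tries, " tries.", call. = FALSE)
  }
  list(x = xs, y = ys)
}

# Gaussian-profile punctum rendered on the full grid; sigma = radius / 2 so a
# radius-1.5 punctum survives the radius-3 white top-hat essentially intact.
render_speckles <- function(side, centers, amplitudes, radius) {
  g <- matrix(0, side, side)
  if (length(centers$x) == 0L) return(g)
  sigma <- radius / 2
  rows <- seq_len(side); cols <- seq_len(side)
  for (k in seq_along(centers$x)) {
    d2 <- outer((rows - centers$x[k])^2, (cols - centers$y[k])^2, "+")
    g <- g + amplitudes[k] * exp(-d2 / (2 * sigma^2))
  }
  g
}

rpois_positive <- function(n, lambda) {
  # zero-truncated Poisson by inverse CDF on a uniform restricted above P(0)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# Noise-free, unmixed channel grids + truth row for one cell. Randomness uses
# the caller's RNG state.
simulate_cell_core <- function(class, population, p, probes_background = FALSE) {
  side <- p$image_side
  d2 <- center_dist2(side)
  cell_disk <- d2 <= p$cell_radius^2
  chans <- stats::setNames(vector("list", length(p$channels)), names(p$channels))
  for (nm in names(p$channels)) chans[[nm]] <- matrix(0, side, side)

  bf <- names(p$channels)[p$channels == "brightfield"][1]
  chans[[bf]][cell_disk] <- p$bf_level

  marker_drawn <- stats::setNames(numeric(0), character(0))
  for (nm in names(p$channels)[p$channels == "marker"]) {
    mu <- p$marker_means[[nm]][[population]]
    lev <- stats::rlnorm(1, log(mu), p$marker_sdlog)
    chans[[nm]][cell_disk] <- lev
    marker_drawn[nm] <- lev
  }

  pla <- names(p$channels)[p$channels == "pla"][1]
  centers <- list(x = numeric(0), y = numeric(0))
  amps <- numeric(0)
  if (class %in% c("NUCLEAR_PLA_POS", "MEMBRANAL_FP")) {
    k <- rpois_positive(1, p$speckle_lambda)
    centers <- draw_speckle_centers(k, class, p)
    amps <- p$speckle_amplitude *
      stats::rlnorm(k, 0, p$speckle_amp_sdlog)
    chans[[pla]] <- chans[[pla]] +
      render_speckles(side, centers, amps, p$speckle_radius)
  } else if (class == "DIFFUSE_AF") {
    chans[[pla]][cell_disk] <- chans[[pla]][cell_disk] + p$diffuse_level
  }
  if (probes_background) {
    kb <- stats::rpois(1, p$probes_bg_lambda)
    if (kb > 0) {
      bc <- draw_speckle_centers(kb, "MEMBRANAL_FP", p)
      ba <- p$probes_bg_membrane * stats::rlnorm(kb, 0, p$speckle_amp_sdlog)
      chans[[pla]] <- chans[[pla]] +
        render_speckles(side, bc, ba, p$speckle_radius)
    }
    chans[[pla]][cell_disk] <- chans[[pla]][cell_disk] + p$probes_bg_diffuse
  }

  if (p$neighbor_mode != "none" && p$neighbor_channel %in% names(chans) &&
      class == "NUCLEAR_PLA_POS") {
    nb <- p$neighbor_channel
    if (p$neighbor_mode == "copy") {
      spk <- render_speckles(side, centers, amps * p$neighbor_scale,
                             p$speckle_radius)
    } else {
      k2 <- rpois_positive(1, p$speckle_lambda)
      c2 <- draw_speckle_centers(k2, "NUCLEAR_PLA_POS", p)
      a2 <- p$speckle_amplitude * p$neighbor_scale *
        stats::rlnorm(k2, 0, p$speckle_amp_sdlog)
      spk <- render_speckles(side, c2, a2, p$speckle_radius)
    }
    chans[[nb]] <- chans[[nb]] + spk
  }

  list(channels = chans, class = class, population = population,
       n_speckles = length(centers$x),
       speckles = list(x = centers$x, y = centers$y, amplitude = amps),
       markers = marker_drawn)
}

core_truth_row <- function(core) {
  tibble::tibble(
    class = core$class, population = core$population,
    n_speckles = core$n_speckles,
    speckles = list(tibble::as_tibble(core$speckles)),
    markers = list(tibble::as_tibble(as.list(core$markers))))
}

apply_spillover_noise <- function(chans, p) {
  nms <- names(chans)
  if (!is.null(p$spillover)) {
    S <- p$spillover[nms, nms, drop = FALSE]
    X <- vapply(chans, as.vector, numeric(length(chans[[1]])))
    X <- X %*% S
    for (j in seq_along(nms)) {
      chans[[nms[j]]] <- matrix(X[, j], nrow(chans[[1]]), ncol(chans[[1]]))
    }
  }
  if (p$noise_sd > 0) {
    for (nm in nms) {
      chans[[nm]] <- chans[[nm]] +
        matrix(stats::rnorm(length(chans[[nm]]), 0, p$noise_sd),
               nrow(chans[[nm]]))
    }
  }
  lapply(chans, function(g) pmax(g, 0))
}

#' Simulate one cell
#'
#' Generates the multichannel image of a single cellular event of the given
#' signal class and population, together with its ground-truth record. Uses
#' the current RNG state; seed the session (or use [simulate_sample()]) for
#' reproducibility.
#'
#' @param class One of `"NUCLEAR_PLA_POS"` (nuclear-speckle PLA signal),
#'   `"MEMBRANAL_FP"` (membrane-ring nonspecific binding), `"DIFFUSE_AF"`
#'   (uniform autofluorescent elevation), `"NEGATIVE"`.
#' @param population One of `"TARGET_HI"`, `"TARGET_LO"`, `"CONTROL_POP"`;
#'   sets marker staining levels.
#' @param params A [scene_params()] object.
#' @param keep_premix Keep the noise-free, unmixed grids as attribute
#'   `"premix"` of the returned image (used as the compensation oracle).
#' @return List with elements `image` (a [cell_image()]) and `truth` (a
#'   one-row tibble).
#' @export
simulate_cell <- function(class, population, params = scene_params(),
                          keep_premix = FALSE) {
  class <- match.arg(class, cell_classes)
  population <- match.arg(population, cell_populations)
  core <- simulate_cell_core(class, population, params)
  finish_cell(core, params, keep_premix)
}

finish_cell <- function(core, params, keep_premix = FALSE) {
  mixed <- apply_spillover_noise(core$channels, params)
  img <- cell_image(mixed, params$channels)
  if (keep_premix) attr(img, "premix") <- core$channels
  list(image = img, truth = core_truth_row(core))
}

#' Simulate a sample of cells
#'
#' Draws each cell's population and class independently from `mix` (so the
#' realised planted fraction is binomial around its expectation), simulates
#' every cell, and records the complete ground truth. Reproducible: a fixed
#' `seed` yields identical output.
#'
#' @param n Number of cells (`n = 0` gives an empty, flagged sample).
#' @param mix Tibble with columns `population`, `class`, `prop` (proportions
#'   summing to 1), e.g. from [population_mix()].
#' @param params A [scene_params()] object.
#' @param seed Integer seed.
#' @param keep_premix Retain noise-free unmixed grids per cell (oracle for
#'   compensation round-trip checks).
#' @param probes_background Plant the weak probes-only background (membranal
#'   puncta + diffuse floor) in every cell; used by [simulate_probes_only()].
#' @return A [plic_sample()] whose `truth` tibble has one row per cell
#'   (`cell_id`, `class`, `population`, `n_speckles`, `speckles`, `markers`)
#'   and attributes `n`, `seed` and `f` (the planted expected positive
#'   fraction).
#' @export
simulate_sample <- function(n, mix = population_mix(), params = scene_params(),
                            seed = 1L, keep_premix = FALSE,
                            probes_background = FALSE) {
  stopifnot(n >= 0, is.data.frame(mix),
            all(c("population", "class", "prop") %in% names(mix)))
  if (any(mix$prop < 0) || abs(sum(mix$prop) - 1) > 1e-8) {
    stop("`mix$prop` must be nonnegative and sum to 1.", call. = FALSE)
  }
  if (!all(mix$class %in% cell_classes) ||
      !all(mix$population %in% cell_populations)) {
    stop("unknown class or population in `mix`.", call. = FALSE)
  }
  if (n == 0L) {
    warning("empty sample requested (n = 0).", call. = FALSE)
    truth <- tibble::tibble(cell_id = integer(0), class = character(0),
                            population = character(0), n_speckles = integer(0),
                            speckles = list(), markers = list())
    attr(truth, "n") <- 0L; attr(truth, "seed") <- seed; attr(truth, "f") <- NA_real_
    return(plic_sample(list(), truth = truth, roles = params$channels))
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prop)
    cells <- vector("list", n)
    spk <- vector("list", n)
    mrk <- vector("list", n)
    n_spk <- integer(n)
    for (i in seq_len(n)) {
      core <- simulate_cell_core(mix$class[idx[i]], mix$population[idx[i]],
                                 params, probes_background = probes_background)
      mixed <- apply_spillover_noise(core$channels, params)
      img <- cell_image(mixed, params$channels)
      if (keep_premix) attr(img, "premix") <- core$channels
      cells[[i]] <- img
      spk[[i]] <- tibble::new_tibble(core$speckles, nrow = core$n_speckles)
      mrk[[i]] <- tibble::new_tibble(as.list(core$markers), nrow = 1L)
      n_spk[i] <- core$n_speckles
    }
  })
  truth <- tibble::tibble(cell_id = seq_len(n),
                          class = mix$class[idx],
                          population = mix$population[idx],
                          n_speckles = n_spk,
                          speckles = spk, markers = mrk)
  attr(truth, "n") <- n
  attr(truth, "seed") <- seed
  f_hi <- sum(mix$prop[mix$class == "NUCLEAR_PLA_POS" &
                         mix$population == "TARGET_HI"])
  p_hi <- sum(mix$prop[mix$population == "TARGET_HI"])
  attr(truth, "f") <- if (p_hi > 0) f_hi / p_hi else 0
  plic_sample(cells, truth = truth, roles = params$channels)
}

#' Simulate the probes-only background control
#'
#' The probes-only sample (PLA probes, no primary antibody) defines the PLA
#' gate. Every cell is `NEGATIVE` — no nuclear speckles — but carries the
#' low-level membranal and diffuse background nonspecific probe binding
#' produces, at the levels set in [scene_params()] (`probes_bg_*`).
#'
#' @inheritParams simulate_sample
#' @param mix Population proportions for the control (classes are forced to
#'   `NEGATIVE`).
#' @return A [plic_sample()]; its truth contains no `NUCLEAR_PLA_POS` cells.
#' @export
simulate_probes_only <- function(n, params = scene_params(), seed = 1L,
                                 mix = population_mix(f_pos = 0,
                                                      f_membranal = 0,
                                                      f_diffuse = 0)) {
  mix$class <- "NEGATIVE"
  mix <- dplyr::summarise(dplyr::group_by(mix, .data$population, .data$class),
                          prop = sum(.data$prop), .groups = "drop")
  simulate_sample(n, mix = mix, params = params, seed = seed,
                  probes_background = TRUE)
}

#' Simulate single-stain compensation controls
#'
#' One sample per channel; each cell has staining planted in exactly one
#' source channel (uniform over the cell disk, log-normal cell-to-cell level)
#' before spillover mixing and noise. Used by [estimate_spillover()].
#'
#' @param spillover A spillover matrix (see [spillover_matrix()]).
#' @param n Cells per control sample.
#' @param params A [scene_params()] object; its `spillover` field is ignored
#'   in favour of the `spillover` argument.
#' @param seed Integer seed.
#' @param level Mean per-pixel staining level of the planted channel.
#' @return Named list of [plic_sample()] objects, one per channel of
#'   `spillover`.
#' @export
simulate_single_stain_controls <- function(spillover, n,
                                           params = scene_params(),
                                           seed = 1L, level = 400) {
  chan <- names(params$channels)
  check_spillover(spillover, chan)
  out <- stats::setNames(vector("list", length(chan)), chan)
  d2 <- center_dist2(params$image_side)
  cell_disk <- d2 <= params$cell_radius^2
  p_mix <- params
  p_mix$spillover <- spillover
  for (j in seq_along(chan)) {
    withr::with_seed(seed + j - 1L, {
      cells <- vector("list", n)
      for (i in seq_len(n)) {
        chans <- stats::setNames(
          lapply(chan, function(x) matrix(0, params$image_side,
                                          params$image_side)), chan)
        lev <- stats::rlnorm(1, log(level), params$marker_sdlog)
        chans[[chan[j]]][cell_disk] <- lev
        mixed <- apply_spillover_noise(chans, p_mix)
        img <- cell_image(mixed, params$channels)
        attr(img, "premix") <- chans
        cells[[i]] <- img
      }
    })
    truth <- tibble::tibble(cell_id = seq_len(n), source_channel = chan[j])
    out[[chan[j]]] <- plic_sample(cells, truth = truth,
                                  roles = params$channels)
  }
  out
}
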