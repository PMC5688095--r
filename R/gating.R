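#' Assign cells to marker-defined populations
#'
#' Labels each cell `CONTROL_POP` (control-marker high), `TARGET_HI` /
#' `TARGET_LO` (target-marker intensity above / below the hi cutoff) or
#' `UNASSIGNED` (target marker below the assignment floor), using the
#' background-subtracted total marker intensities of the feature table.
#' Cutoff policies: `"fixed"` (given value), `"percentile"` (in-sample
#' quantile), `"split2"` (midpoint of a 2-means split of log10 intensity —
#' for bimodal marker distributions such as CD80 on thymic epithelium).
#'
#' @param features Feature tibble from [compute_features()].
#' @param config A [gating_config()]; its `population` element names the
#'   marker channels and policies.
#' @return The feature tibble with a `population` column prepended after
#'   `cell_id`.
#' @export
gate_population <- function(features, config = gating_config()) {
  p <- config$population
  ctrl_col <- paste0(p$control_channel, "_total")
  targ_col <- paste0(p$target_channel, "_total")
  if (!all(c(ctrl_col, targ_col) %in% names(features))) {
    stop("marker channel columns missing from the feature table: ",
         ctrl_col, ", ", targ_col, ".", call. = FALSE)
  }
  ctrl <- features[[ctrl_col]]
  targ <- features[[targ_col]]
  ctrl_cut <- resolve_cutoff(p$control_policy, ctrl)
  is_ctrl <- ctrl > ctrl_cut
  hi_cut <- resolve_cutoff(p$hi_policy, targ[!is_ctrl])
  pop <- ifelse(is_ctrl, "CONTROL_POP",
                ifelse(targ > hi_cut, "TARGET_HI",
                       ifelse(targ > p$target_floor, "TARGET_LO",
                              "UNASSIGNED")))
  dplyr::relocate(dplyr::mutate(features, population = pop),
                  "population", .after = "cell_id")
}

resolve_cutoff <- function(policy, values) {
  switch(policy$method,
         fixed = policy$cutoff,
         percentile = stats::quantile(values, policy$prob, names = FALSE,
                                      type = 7),
         split2 = split2_cutoff(values),
         stop("unknown cutoff policy '", policy$method, "'.", call. = FALSE))
}

# Midpoint (on the original scale) of a 1-D 2-means split of log10(x + 1).
split2_cutoff <- function(values) {
  v <- log10(values + 1)
  if (length(unique(v)) < 2L) return(Inf)
  km <- stats::kmeans(v, centers = range(v))
  10^mean(km$centers) - 1
}

#' PLA gate from the probes-only control
#'
#' The 2-D PLA-positivity gate is set from the background control: the stated
#' percentile (type-7 sample quantile) of the control's PLA-channel Bright
#' Detail Intensity and Max Pixel distributions. A cell is raw PLA-positive
#' iff both its BDI and Max Pixel strictly exceed their cutoffs (axis-aligned
#' conjunction).
#'
#' @param probes_features Feature tibble of the probes-only control.
#' @param config A [gating_config()] (supplies the percentile and PLA channel
#'   name); alternatively pass `percentile` / `pla_channel` directly.
#' @param percentile,pla_channel Overrides of the config values.
#' @return List with `bdi_cut`, `max_pixel_cut`, `percentile`, `n_control`.
#' @export
set_pla_threshold <- function(probes_features, config = gating_config(),
                              percentile = NULL, pla_channel = NULL) {
  percentile <- percentile %||% config$control_percentile
  stopifnot(percentile > 0, percentile < 100)
  if (is.null(pla_channel)) {
    # the channel carrying interior-mask features is the PLA channel
    cand <- grep("_bdi_erode$", names(probes_features), value = TRUE)
    pla_channel <- config$pla_channel %||% sub("_bdi_erode$", "", cand[1])
  }
  if (is.null(pla_channel) || is.na(pla_channel)) {
    stop("cannot identify the PLA channel in the feature table.",
         call. = FALSE)
  }
  bdi_col <- paste0(pla_channel, "_bdi")
  mp_col <- paste0(pla_channel, "_max_pixel")
  if (nrow(probes_features) == 0L ||
      !all(c(bdi_col, mp_col) %in% names(probes_features))) {
    stop("probes-only control is empty or lacks PLA features.", call. = FALSE)
  }
  q <- percentile / 100
  list(bdi_cut = max(stats::quantile(probes_features[[bdi_col]], q,
                                     names = FALSE, type = 7), 0),
       max_pixel_cut = max(stats::quantile(probes_features[[mp_col]], q,
                                           names = FALSE, type = 7), 0),
       percentile = percentile,
       n_control = nrow(probes_features),
       pla_channel = pla_channel)
}

raw_pla_positive <- function(features, threshold) {
  bdi <- features[[paste0(threshold$pla_channel, "_bdi")]]
  mp <- features[[paste0(threshold$pla_channel, "_max_pixel")]]
  bdi > threshold$bdi_cut & mp > threshold$max_pixel_cut
}

#' Subcellular-localization false-positive filter
#'
#' Removes raw PLA-positive cells whose signal is not compatible with the
#' expected localization: (i) the PLA BDI and Max Pixel recomputed on the
#' adaptive-erode interior mask must still exceed the PLA gate — membranal
#' signal sits outside the eroded mask and fails; (ii) when
#' `nuclear_required`, Max Contour Position must not exceed `mcp_max`;
#' (iii) the PLA staining area must fall inside the configured range —
#' diffuse autofluorescence fills the cell and fails the upper bound.
#'
#' @param features Feature tibble from [compute_features()].
#' @param config A [gating_config()].
#' @param threshold PLA gate from [set_pla_threshold()].
#' @return Tibble with logical columns `interior_pass`, `mcp_pass`,
#'   `area_pass` and their conjunction `localization_pass`.
#' @export
localization_filter <- function(features, config, threshold) {
  pla <- threshold$pla_channel
  bdi_e <- features[[paste0(pla, "_bdi_erode")]]
  mp_e <- features[[paste0(pla, "_max_pixel_erode")]]
  if (is.null(bdi_e) || is.null(mp_e)) {
    stop("adaptive-erode features missing; run compute_features() with the ",
         "same config.", call. = FALSE)
  }
  interior <- bdi_e > threshold$bdi_cut & mp_e > threshold$max_pixel_cut
  mcp <- features[[paste0(pla, "_mcp")]]
  mcp_pass <- if (config$nuclear_required) {
    !is.na(mcp) & mcp <= config$mcp_max
  } else {
    rep(TRUE, nrow(features))
  }
  area <- features[[paste0(pla, "_area")]]
  area_max <- config$area_max_frac * features$morph_area
  area_pass <- area >= config$area_min & area <= area_max
  tibble::tibble(interior_pass = interior, mcp_pass = mcp_pass,
                 area_pass = area_pass,
                 localization_pass = interior & mcp_pass & area_pass)
}

#' Bright-Detail-Similarity artifact filter
#'
#' Excludes cells whose bright detail is strongly correlated across the
#' configured channel pair (BDS above the cutoff, default 1.5) — the
#' signature of fluorescence penetrating from one channel into another, which
#' compensation cannot resolve. Missing BDS (mask too small) passes or fails
#' per the configured strictness, with a flag.
#'
#' @inheritParams localization_filter
#' @param cutoff BDS cutoff; overrides the config value. `Inf` disables the
#'   filter.
#' @return Logical vector: `TRUE` = retained.
#' @export
bds_filter <- function(features, config = gating_config(), cutoff = NULL) {
  cutoff <- cutoff %||% config$bds_cutoff
  bds_col <- grep("^bds_", names(features), value = TRUE)
  if (length(bds_col) == 0L) {
    stop("no BDS column in the feature table.", call. = FALSE)
  }
  bds <- features[[bds_col[1]]]
  pass <- bds <= cutoff
  pass[is.na(bds)] <- config$bds_missing == "pass"
  pass
}

#' Run the full gating pipeline
#'
#' Applies, in order: spillover compensation (when a matrix or single-stain
#' controls are given), feature extraction, population assignment, the PLA
#' gate set from the probes-only control, and — per the configured cascade —
#' the subcellular-localization and BDS false-positive filters. The final
#' PLA-positive call is the conjunction of the raw gate and every enabled
#' filter, so it does not depend on filter order; the per-cell audit trail
#' records each gate outcome and the reasons a cell was excluded.
#'
#' @param samples Named list of [plic_sample()] objects (or a single sample).
#' @param probes_only A [plic_sample()]: the probes-only background control.
#' @param config A [gating_config()].
#' @param spillover Optional spillover matrix to compensate with.
#' @param controls Optional named list of single-stain control samples; when
#'   given, the spillover matrix is estimated from them first.
#' @return Object of class `plic_result`: list with `calls` (per-cell tibble:
#'   sample, cell_id, population, gate booleans, `final_pla_pos`, `reasons`),
#'   `summary` (per sample x population: `n`, `n_pos`, `pct_pla_pos`),
#'   `threshold`, `spillover`, `config`.
#' @export
run_pipeline <- function(samples, probes_only, config = gating_config(),
                         spillover = NULL, controls = NULL) {
  if (inherits(samples, "plic_sample")) samples <- list(sample = samples)
  stopifnot(is.list(samples), length(samples) >= 1L,
            inherits(probes_only, "plic_sample"))
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  if (length(probes_only$cells) == 0L) {
    stop("probes-only control sample is empty.", call. = FALSE)
  }
  if (!is.null(controls)) spillover <- estimate_spillover(controls)
  if (!is.null(spillover)) {
    samples <- lapply(samples, compensate_sample, S = spillover)
    probes_only <- compensate_sample(probes_only, S = spillover)
  }

  probes_feat <- compute_features(probes_only, config)
  threshold <- set_pla_threshold(probes_feat, config)

  calls <- purrr::imap(samples, function(s, nm) {
    feat <- compute_features(s, config)
    feat <- gate_population(feat, config)
    gate_cells(feat, config, threshold, sample = nm)
  })
  calls <- dplyr::bind_rows(calls)

  summary <- calls |>
    dplyr::filter(.data$population != "UNASSIGNED") |>
    dplyr::group_by(.data$sample, .data$population) |>
    dplyr::summarise(n = dplyr::n(),
                     n_pos = sum(.data$final_pla_pos),
                     pct_pla_pos = 100 * .data$n_pos / .data$n,
                     .groups = "drop")

  structure(list(calls = calls, summary = summary, threshold = threshold,
                 spillover = spillover, config = config),
            class = "plic_result")
}

# Per-sample gate evaluation and audit trail.
gate_cells <- function(feat, config, threshold, sample) {
  n <- nrow(feat)
  raw <- raw_pla_positive(feat, threshold)
  use_loc <- "localization" %in% config$filters
  use_bds <- "bds" %in% config$filters
  loc <- if (use_loc) {
    localization_filter(feat, config, threshold)
  } else {
    tibble::tibble(interior_pass = rep(TRUE, n), mcp_pass = TRUE,
                   area_pass = TRUE, localization_pass = TRUE)
  }
  bds_pass <- if (use_bds) bds_filter(feat, config) else rep(TRUE, n)
  final <- raw & loc$localization_pass & bds_pass

  reasons <- character(n)
  add_reason <- function(reasons, fail, tag) {
    ifelse(fail, ifelse(nzchar(reasons), paste(reasons, tag, sep = ","), tag),
           reasons)
  }
  reasons <- add_reason(reasons, !raw, "pla_raw")
  if (use_loc) {
    reasons <- add_reason(reasons, !loc$interior_pass, "interior")
    if (config$nuclear_required) {
      reasons <- add_reason(reasons, !loc$mcp_pass, "mcp")
    }
    reasons <- add_reason(reasons, !loc$area_pass, "area")
  }
  if (use_bds) reasons <- add_reason(reasons, !bds_pass, "bds")
  unassigned <- feat$population == "UNASSIGNED"
  reasons[unassigned] <- "unassigned"

  tibble::tibble(sample = sample, cell_id = feat$cell_id,
                 population = feat$population,
                 pla_raw_pos = raw,
                 interior_pass = loc$interior_pass,
                 mcp_pass = loc$mcp_pass,
                 area_pass = loc$area_pass,
                 localization_pass = loc$localization_pass,
                 bds_pass = bds_pass,
                 final_pla_pos = ifelse(unassigned, NA, final),
                 reasons = reasons,
                 flags = feat$flags)
}

#' @export
print.plic_result <- function(x, ...) {
  cat("<plic_result> ", nrow(x$calls), " cells, ",
      length(unique(x$calls$sample)), " sample(s)\n", sep = "")
  cat("PLA gate (", x$threshold$percentile, "th pct of ",
      x$threshold$n_control, " probes-only cells): BDI > ",
      signif(x$threshold$bdi_cut, 4), ", Max Pixel > ",
      signif(x$threshold$max_pixel_cut, 4), "\n", sep = "")
  print(x$summary)
  invisible(x)
}
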