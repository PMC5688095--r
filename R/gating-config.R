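#' Gating configuration
#'
#' All thresholds, mask parameters and cascade switches of the PLA-positivity
#' gating pipeline. Two presets reflect the two analysis styles: `"tec"` (full
#' cascade: raw PLA gate, subcellular-localization filtering on the
#' adaptive-erode mask, Max Contour Position and staining-area gates, and the
#' Bright Detail Similarity artifact exclusion — appropriate for nuclear
#' targets in rare populations) and `"bmdm"` (raw PLA gate only).
#'
#' @param mode `"tec"` or `"bmdm"` preset (see above).
#' @param mask_channel Channel seeding the morphology mask; `NULL` resolves to
#'   the brightfield-proxy channel.
#' @param pla_channel PLA channel; `NULL` resolves by role.
#' @param bds_pair Character(2): the channels compared by the BDS artifact
#'   filter. `NULL` resolves to the PLA channel and its spectrally adjacent
#'   marker channel (first marker channel by convention).
#' @param bd_radius Bright-detail spot radius in pixels (default 3).
#' @param control_percentile Percentile of the probes-only control's BDI and
#'   Max Pixel distributions that defines the PLA gate (default 99.5).
#' @param adaptive_erode_percent Retained-area percent of the adaptive-erode
#'   interior mask (default 78).
#' @param mcp_n_rings Ring count for Max Contour Position (default 8).
#' @param mcp_max Largest MCP accepted as nuclear/interior when
#'   `nuclear_required` (default 0.6; 0 = center, 1 = perimeter).
#' @param area_min Minimum PLA staining area in pixels (default 2, about one
#'   punctum core).
#' @param area_max_frac Maximum PLA staining area as a fraction of the
#'   morphology-mask area (default 0.40; diffuse autofluorescence fills the
#'   mask and fails this bound).
#' @param area_frac Fraction of Max Pixel defining the staining-area cutoff
#'   (see [staining_area()]).
#' @param bds_cutoff Cells with BDS above this are excluded as channel-overlay
#'   artifacts (default 1.5).
#' @param nuclear_required Apply the MCP nuclear-localization gate (`TRUE` for
#'   the full cascade).
#' @param filters Character vector of enabled false-positive filters, in
#'   evaluation order, from `c("localization", "bds")`. The final call is the
#'   conjunction of the raw PLA gate with every enabled filter, so the
#'   positive set is order-invariant; the order only organises the audit
#'   trail.
#' @param bds_missing `"pass"` (default) or `"fail"`: strictness when BDS is
#'   missing (mask too small).
#' @param population Population-assignment settings: a list with
#'   `control_channel`, `target_channel`, `control_policy`, `hi_policy`
#'   (each policy a list with `method` in `"fixed"`/`"percentile"`/`"split2"`
#'   plus `cutoff` or `prob`), and `target_floor` (cells below it on the
#'   target marker, and not control, are UNASSIGNED).
#' @return A validated list of class `gating_config`.
#' @export
gating_config <- function(mode = c("tec", "bmdm"),
                          mask_channel = NULL,
                          pla_channel = NULL,
                          bds_pair = NULL,
                          bd_radius = 3,
                          control_percentile = 99.5,
                          adaptive_erode_percent = 78,
                          mcp_n_rings = 8,
                          mcp_max = 0.6,
                          area_min = 2,
                          area_max_frac = 0.40,
                          area_frac = 0.5,
                          bds_cutoff = 1.5,
                          nuclear_required = NULL,
                          filters = NULL,
                          bds_missing = c("pass", "fail"),
                          population = list(
                            control_channel = "CD45",
                            target_channel = "CD80",
                            control_policy = list(method = "fixed", cutoff = 3e4),
                            hi_policy = list(method = "fixed", cutoff = 6e4),
                            target_floor = 2e3)) {
  mode <- match.arg(mode)
  bds_missing <- match.arg(bds_missing)
  if (is.null(filters)) {
    filters <- if (mode == "tec") c("localization", "bds") else character(0)
  }
  if (is.null(nuclear_required)) nuclear_required <- mode == "tec"
  cfg <- list(mode = mode, mask_channel = mask_channel,
              pla_channel = pla_channel, bds_pair = bds_pair,
              bd_radius = bd_radius, control_percentile = control_percentile,
              adaptive_erode_percent = adaptive_erode_percent,
              mcp_n_rings = mcp_n_rings, mcp_max = mcp_max,
              area_min = area_min, area_max_frac = area_max_frac,
              area_frac = area_frac, bds_cutoff = bds_cutoff,
              nuclear_required = nuclear_required, filters = filters,
              bds_missing = bds_missing, population = population)
  validate_gating_config(cfg)
  structure(cfg, class = "gating_config")
}

validate_gating_config <- function(cfg) {
  stopifnot(cfg$control_percentile > 0, cfg$control_percentile < 100,
            cfg$adaptive_erode_percent >= 0, cfg$adaptive_erode_percent <= 100,
            cfg$mcp_n_rings >= 2, cfg$bd_radius >= 1,
            cfg$area_min >= 0, cfg$area_max_frac > 0, cfg$area_max_frac <= 1,
            is.finite(cfg$mcp_max) || cfg$mcp_max == Inf,
            all(cfg$filters %in% c("localization", "bds")))
  if (!is.finite(cfg$area_min)) stop("`area_min` must be finite.", call. = FALSE)
  invisible(cfg)
}

#' Read / write a gating configuration as YAML
#'
#' @param path File path.
#' @return `read_gating_config()` returns a validated `gating_config`;
#'   `write_gating_config()` returns `path` invisibly.
#' @export
read_gating_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(gating_config)))]
  do.call(gating_config, args)
}

#' @rdname read_gating_config
#' @param config A `gating_config`.
#' @export
write_gating_config <- function(config, path) {
  stopifnot(inherits(config, "gating_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Resolve channel names against a sample's roles.
resolve_channels <- function(config, roles) {
  mask_ch <- config$mask_channel %||% names(roles)[roles == "brightfield"][1]
  pla_ch <- config$pla_channel %||% names(roles)[roles == "pla"][1]
  if (is.na(mask_ch) || is.null(mask_ch)) {
    stop("no brightfield-proxy channel to seed the morphology mask.",
         call. = FALSE)
  }
  if (is.na(pla_ch) || is.null(pla_ch)) {
    stop("no PLA channel found.", call. = FALSE)
  }
  bds_pair <- config$bds_pair
  if (is.null(bds_pair)) {
    markers <- names(roles)[roles == "marker"]
    bds_pair <- c(pla_ch, markers[1])
  }
  if (anyNA(bds_pair) || length(bds_pair) != 2L) bds_pair <- NULL
  list(mask = mask_ch, pla = pla_ch, bds_pair = bds_pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
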