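#' Physical constants of the running buffer and magnetic labels
#'
#' Bundles the fluid and magnetic-nanoparticle (MNP) parameters every force
#' computation consumes. The per-MNP magnetic coupling is a single calibrated
#' coefficient `force_scale_A` (N m^2): all material constants of the guide
#' alloy, the permanent-magnet stack and the MNP moment are folded into it by
#' [calibrate_force_scale()], so it starts out as `NA`.
#'
#' @param viscosity Dynamic viscosity of the running buffer (Pa s).
#' @param mnp_radius MNP radius (m); default 5e-9 (10 nm diameter iron-oxide
#'   particles).
#' @param reference_radius Vesicle radius (m) used for the calibration anchor
#'   and the lateral force balance; default 50 nm, the centre of the
#'   30--160 nm sEV diameter range.
#' @param vertical_coupling Dimensionless factor scaling the vertical
#'   (floor-ward) magnetic force component relative to the lateral edge
#'   attraction. The default 6 is the smallest round value for which
#'   essentially all (>= 99.5\%) singly-labeled vesicles settle within the
#'   pre-junction length of the default device.
#' @param extra_drag_radius Additive term (m) on the hydrodynamic radius to
#'   account for bound MNPs if desired; default 0 (bare vesicle radius).
#' @param force_scale_A Calibrated edge-force coefficient per MNP (N m^2);
#'   leave `NA` and call [calibrate_force_scale()].
#'
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(viscosity = 1.0e-3,
                               mnp_radius = 5e-9,
                               reference_radius = 5e-8,
                               vertical_coupling = 6,
                               extra_drag_radius = 0,
                               force_scale_A = NA_real_) {
  for (f in c("viscosity", "mnp_radius", "reference_radius",
              "vertical_coupling")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("physical_constants: field '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (extra_drag_radius < 0) {
    stop("physical_constants: field 'extra_drag_radius' must be >= 0", call. = FALSE)
  }
  structure(
    list(viscosity = viscosity,
         mnp_radius = mnp_radius,
         reference_radius = reference_radius,
         vertical_coupling = vertical_coupling,
         extra_drag_radius = extra_drag_radius,
         force_scale_A = force_scale_A,
         calibration = NULL),
    class = "physical_constants"
  )
}

#' Device geometry: channel, guides, outlets
#'
#' Describes the sorting channel and the angled ferromagnetic guides beneath
#' it. Coordinates: x streamwise, y lateral (centreline 0), z height above the
#' channel floor. All lengths are SI metres internally; the configuration
#' reader accepts micrometre-suffixed keys.
#'
#' @param channel_height Channel height h (m); default 30 um, the optimal
#'   sorting height.
#' @param channel_width Channel width w (m); default 1 mm. Only enters through
#'   the mean velocity, so any consistent value works once forces are
#'   calibrated.
#' @param guide_angles Strictly increasing guide angles (degrees), one per
#'   deflected outlet; default `c(3, 5, 10)` for the low/medium/high outlets.
#'   One- or two-guide devices are allowed (single-angle design studies).
#' @param guide_gap Vertical distance from the channel floor to the guide
#'   plane (m); regularises the edge field. Default 20 um.
#' @param pre_junction_length Streamwise settling length before the first
#'   sorting junction (m); default 5 mm.
#' @param z_settle Transport height of settled vesicles above the floor (m);
#'   default 2 um. Enters only through the calibration anchor, so results are
#'   insensitive to its exact value.
#' @param sort_length Streamwise length of the sorting section (m), used by
#'   the trajectory oracle; default 10 mm.
#' @param branch_spacing Streamwise spacing between successive guide branch
#'   points (m) in the abstracted branching layout; default 1 mm.
#'
#' @return An object of class `device_geometry`, with `outlet_labels`
#'   (`negative` plus one label per guide).
#' @export
device_geometry <- function(channel_height = 30e-6,
                            channel_width = 1e-3,
                            guide_angles = c(3, 5, 10),
                            guide_gap = 20e-6,
                            pre_junction_length = 5e-3,
                            z_settle = 2e-6,
                            sort_length = 10e-3,
                            branch_spacing = 1e-3) {
  if (!is.numeric(channel_height) || channel_height <= 0) {
    stop("device_geometry: field 'channel_height' must be > 0", call. = FALSE)
  }
  if (!is.numeric(channel_width) || channel_width <= 0) {
    stop("device_geometry: field 'channel_width' must be > 0", call. = FALSE)
  }
  if (!is.numeric(guide_gap) || guide_gap < 0) {
    stop("device_geometry: field 'guide_gap' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(pre_junction_length) || pre_junction_length < 0) {
    stop("device_geometry: field 'pre_junction_length' must be >= 0", call. = FALSE)
  }
  if (z_settle < 0 || z_settle >= channel_height) {
    stop("device_geometry: field 'z_settle' must lie in [0, channel_height)", call. = FALSE)
  }
  if (!is.numeric(guide_angles) || length(guide_angles) < 1L ||
      length(guide_angles) > 3L) {
    stop("device_geometry: field 'guide_angles' must hold 1 to 3 angles", call. = FALSE)
  }
  if (any(guide_angles <= 0) || any(guide_angles >= 90)) {
    stop("device_geometry: field 'guide_angles' must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  if (length(guide_angles) > 1L && any(diff(guide_angles) <= 0)) {
    stop("device_geometry: guide_angles not strictly increasing", call. = FALSE)
  }
  deflected <- c("low", "medium", "high")[seq_along(guide_angles)]
  structure(
    list(channel_height = channel_height,
         channel_width = channel_width,
         guide_angles = guide_angles,
         guide_gap = guide_gap,
         pre_junction_length = pre_junction_length,
         z_settle = z_settle,
         sort_length = sort_length,
         branch_spacing = branch_spacing,
         outlet_labels = c("negative", deflected)),
    class = "device_geometry"
  )
}

#' Flow condition
#'
#' Volumetric flow rate and the derived mean velocity of plane channel flow.
#'
#' @param flow_rate_ul_h Volumetric flow rate in uL/h (the bench unit);
#'   default 200, the optimal sorting flow rate.
#' @param device A [device_geometry()] supplying the cross-section.
#'
#' @return An object of class `flow_condition` with `Q` (m^3/s),
#'   `flow_rate_ul_h` and `v_mean` (m/s).
#' @export
flow_condition <- function(flow_rate_ul_h = 200, device = device_geometry()) {
  if (!is.numeric(flow_rate_ul_h) || flow_rate_ul_h <= 0) {
    stop("flow_condition: field 'flow_rate_ul_h' must be > 0", call. = FALSE)
  }
  Q <- flow_rate_ul_h * 1e-9 / 3600
  structure(
    list(flow_rate_ul_h = flow_rate_ul_h,
         Q = Q,
         v_mean = Q / (device$channel_width * device$channel_height)),
    class = "flow_condition"
  )
}

## unit-suffixed config keys -> SI constructor arguments
.cfg_num <- function(section, key, default) {
  v <- section[[key]]
  if (is.null(v)) return(default)
  if (!is.numeric(v)) {
    stop(sprintf("build_device: config field '%s' must be numeric", key), call. = FALSE)
  }
  v
}

#' Build a validated device + constants + flow triple from configuration
#'
#' Accepts a YAML file path or a nested list with sections `device`,
#' `physics`, `flow` (and optionally `population`, which is passed through
#' untouched for the sampler). Every numeric field is unit-suffixed, e.g.
#' `channel_height_um: 30`, `flow_rate_ul_h: 200`. Missing fields fall back
#' to the defaults of [device_geometry()], [physical_constants()] and
#' [flow_condition()].
#'
#' @param config `NULL` (all defaults), a path to a YAML file, or a list.
#' @return A list of class `nanoepic_system` with elements `device`,
#'   `constants`, `flow` and `population` (the untouched population section,
#'   or `NULL`).
#' @export
build_device <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("build_device: config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) {
    stop("build_device: config must be NULL, a file path, or a list", call. = FALSE)
  }
  dev <- config$device %||% list()
  phy <- config$physics %||% list()
  flo <- config$flow %||% list()

  device <- device_geometry(
    channel_height = .cfg_num(dev, "channel_height_um", 30) * 1e-6,
    channel_width = .cfg_num(dev, "channel_width_um", 1000) * 1e-6,
    guide_angles = .cfg_num(dev, "guide_angles_deg", c(3, 5, 10)),
    guide_gap = .cfg_num(dev, "guide_gap_um", 20) * 1e-6,
    pre_junction_length = .cfg_num(dev, "pre_junction_length_mm", 5) * 1e-3,
    z_settle = .cfg_num(dev, "z_settle_um", 2) * 1e-6,
    sort_length = .cfg_num(dev, "sort_length_mm", 10) * 1e-3,
    branch_spacing = .cfg_num(dev, "branch_spacing_mm", 1) * 1e-3
  )
  constants <- physical_constants(
    viscosity = .cfg_num(phy, "viscosity_pa_s", 1.0e-3),
    mnp_radius = .cfg_num(phy, "mnp_radius_nm", 5) * 1e-9,
    reference_radius = .cfg_num(phy, "reference_radius_nm", 50) * 1e-9,
    vertical_coupling = .cfg_num(phy, "vertical_coupling", 6),
    extra_drag_radius = .cfg_num(phy, "extra_drag_radius_nm", 0) * 1e-9
  )
  flow <- flow_condition(
    flow_rate_ul_h = .cfg_num(flo, "flow_rate_ul_h", 200),
    device = device
  )
  structure(list(device = device, constants = constants, flow = flow,
                 population = config$population),
            class = "nanoepic_system")
}

#' Build and calibrate a complete system in one call
#'
#' Convenience wrapper: [build_device()] followed by
#' [calibrate_force_scale()] with the standard anchor (4 MNPs marginally
#' deflected at the shallowest guide angle).
#'
#' @inheritParams build_device
#' @param calibrate If `TRUE` (default) calibrate the force scale.
#' @return A `nanoepic_system` list whose `constants` carry the calibrated
#'   `force_scale_A`.
#' @export
nanoepic_system <- function(config = NULL, calibrate = TRUE) {
  sys <- build_device(config)
  if (calibrate) {
    sys$constants <- calibrate_force_scale(sys$device, sys$constants, sys$flow)
  }
  sys
}

#' Cross-check a built system for physical consistency
#'
#' Returns character warnings rather than failing: an empty vector means the
#' configuration is self-consistent. Checks the settling requirement (the
#' worst-case vesicle -- one MNP, largest sEV radius, entering at the channel
#' ceiling -- must reach the transport height within the pre-junction length)
#' and degenerate geometry.
#'
#' @param device A [device_geometry()].
#' @param constants A [physical_constants()], calibrated or not (an
#'   uncalibrated system is calibrated on the fly for the check).
#' @param flow A [flow_condition()].
#' @return Character vector of warnings (possibly empty).
#' @export
validate_consistency <- function(device, constants, flow) {
  warnings <- character(0)
  if (device$pre_junction_length <= 0) {
    warnings <- c(warnings, "no settling length (pre_junction_length = 0)")
    return(warnings)
  }
  cst <- constants
  if (is.null(cst$calibration)) {
    cst <- calibrate_force_scale(device, cst, flow)
  }
  r_max <- 80e-9  # largest sEV radius admitted by the generator
  t_worst <- settle_time(device$channel_height, 1L, device, cst, flow,
                         radius = r_max)
  if (t_worst > residence_time(device, flow)) {
    warnings <- c(warnings, "incomplete settling expected")
  }
  rel <- abs(flow$v_mean - flow$Q / (device$channel_width * device$channel_height)) /
    flow$v_mean
  if (rel > 1e-12) {
    warnings <- c(warnings, "flow condition inconsistent with geometry")
  }
  warnings
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("<device_geometry> h = %.1f um, w = %.0f um, angles = [%s] deg, gap = %.1f um, L_pre = %.1f mm\n",
              x$channel_height * 1e6, x$channel_width * 1e6,
              paste(x$guide_angles, collapse = ", "),
              x$guide_gap * 1e6, x$pre_junction_length * 1e3))
  invisible(x)
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf("<flow_condition> Q = %.0f uL/h (%.3e m^3/s), v_mean = %.3e m/s\n",
              x$flow_rate_ul_h, x$Q, x$v_mean))
  invisible(x)
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("<physical_constants> eta = %.2e Pa s, r_MNP = %.1f nm, A = %s N m^2%s\n",
              x$viscosity, x$mnp_radius * 1e9,
              if (is.na(x$force_scale_A)) "uncalibrated" else
                sprintf("%.3e", x$force_scale_A),
              if (is.null(x$calibration)) "" else " (calibrated)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## seed-scoped evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
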