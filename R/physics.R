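#' Stokes drag on a small sphere
#'
#' F_d = 6 pi eta r v, the low-Reynolds drag on a sphere of radius `r` moving
#' at speed `v` through fluid of viscosity `eta`. Vesicle Reynolds numbers in
#' this device are ~1e-7, far inside the Stokes regime.
#'
#' @param radius Particle radius (m), > 0.
#' @param speed Relative speed (m/s), >= 0.
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @return Drag force magnitude (N).
#' @export
stokes_drag <- function(radius, speed, viscosity) {
  if (any(radius <= 0)) stop("stokes_drag: radius must be > 0", call. = FALSE)
  if (any(speed < 0)) stop("stokes_drag: speed must be >= 0", call. = FALSE)
  if (any(viscosity <= 0)) stop("stokes_drag: viscosity must be > 0", call. = FALSE)
  6 * pi * viscosity * radius * speed
}

#' Streamwise velocity of plane-Poiseuille channel flow
#'
#' v_x(z) = 6 v_mean (z/h)(1 - z/h): parabolic laminar profile with no-slip
#' floor and ceiling, normalised so its channel average is `v_mean`.
#'
#' @param z Height above the channel floor (m), in `[0, h]`. Vectorised.
#' @param h Channel height (m).
#' @param v_mean Mean (superficial) velocity (m/s).
#' @return Local streamwise velocity (m/s).
#' @export
local_velocity <- function(z, h, v_mean) {
  if (any(z < 0 | z > h)) {
    stop("local_velocity: z must lie within [0, h]", call. = FALSE)
  }
  6 * v_mean * (z / h) * (1 - z / h)
}

#' Edge-gradient attraction per bound MNP
#'
#' Each guide edge is modelled as a line of magnetic charge: |B| ~ 1/r, so
#' the gradient force on a saturated dipole scales as A / r^2, pointing
#' toward the edge. `A` absorbs every material constant (guide magnetisation,
#' MNP moment, permeability) and is fixed by [calibrate_force_scale()].
#'
#' @param distance_r Distance from the guide-edge line (m), > 0. In practice
#'   the field is regularised by the floor-to-guide gap.
#' @param force_scale_A Calibrated edge-force coefficient (N m^2), >= 0.
#' @return Attractive force magnitude for one MNP (N).
#' @export
edge_gradient_force_per_mnp <- function(distance_r, force_scale_A) {
  if (any(distance_r <= 0)) {
    stop("edge_gradient_force_per_mnp: distance_r must be > 0", call. = FALSE)
  }
  if (any(force_scale_A < 0) || anyNA(force_scale_A)) {
    stop("edge_gradient_force_per_mnp: force_scale_A must be a non-negative number (calibrate first)",
         call. = FALSE)
  }
  force_scale_A / distance_r^2
}

#' Magnetic force on a vesicle carrying n MNPs
#'
#' Linear in the MNP load: binding more label particles raises the magnetic
#' susceptibility of the vesicle proportionally, which is the physical basis
#' of expression-ranked sorting.
#'
#' @param n_mnps Number of bound MNPs (>= 0). Vectorised.
#' @param distance_r Distance from the guide edge (m).
#' @param constants A calibrated [physical_constants()].
#' @return Force magnitude (N).
#' @export
mnp_force <- function(n_mnps, distance_r, constants) {
  if (any(n_mnps < 0)) stop("mnp_force: n_mnps must be >= 0", call. = FALSE)
  n_mnps * edge_gradient_force_per_mnp(distance_r, constants$force_scale_A)
}

#' Calibrate the per-MNP force scale to the design anchor
#'
#' The design anchor states that a vesicle carrying exactly `anchor_n` MNPs
#' (default 4) is marginally deflected at the shallowest guide angle
#' (default the device's first angle, 3 degrees): F_m = F_d(z_settle) sin
#' theta_1 for the reference vesicle transported at the settled height.
#' Closed form:
#'
#'   A = F_d(z_settle) sin(theta_1) (z_settle + z_gap)^2 / anchor_n
#'
#' The returned constants also store the calibration reference state (the
#' settled-height drag and flow rate of the calibration geometry). The
#' lateral capture balance of the sorter uses that reference drag scaled
#' linearly with the operating flow rate, so the load thresholds respond to
#' flow rate while channel height acts through vertical settling -- see the
#' methods vignette for the rationale.
#'
#' @param device,constants,flow The system to calibrate at (defaults:
#'   default geometry and 200 uL/h).
#' @param anchor_n MNP count of the marginal vesicle (default 4).
#' @param anchor_angle_deg Guide angle it marginally holds (default the
#'   device's shallowest angle).
#' @return `constants` with `force_scale_A` set and a `calibration` record.
#' @export
calibrate_force_scale <- function(device = device_geometry(),
                                  constants = physical_constants(),
                                  flow = flow_condition(device = device),
                                  anchor_n = 4,
                                  anchor_angle_deg = device$guide_angles[1]) {
  if (anchor_n <= 0 || anchor_angle_deg <= 0) {
    stop("calibrate_force_scale: degenerate anchor (anchor_n and anchor_angle_deg must be > 0)",
         call. = FALSE)
  }
  r_ref <- constants$reference_radius + constants$extra_drag_radius
  v_settle <- local_velocity(device$z_settle, device$channel_height, flow$v_mean)
  F_d <- stokes_drag(r_ref, v_settle, constants$viscosity)
  r_edge <- device$z_settle + device$guide_gap
  A <- F_d * sin(anchor_angle_deg * pi / 180) * r_edge^2 / anchor_n
  constants$force_scale_A <- A
  constants$calibration <- list(
    anchor_n = anchor_n,
    anchor_angle_deg = anchor_angle_deg,
    F_d_ref = F_d,
    Q_ref = flow$Q,
    z_settle = device$z_settle,
    guide_gap = device$guide_gap
  )
  constants
}
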