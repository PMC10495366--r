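## Per-MNP capture ratio F_m(1)/F_d of the lateral balance. The drag side is
## the settled-height drag recorded at calibration, scaled linearly with the
## operating flow rate; the magnetic side uses the current device's
## floor-to-guide distance. Channel height therefore acts on routing through
## vertical settling only (see methods vignette).
.capture_ratio_per_mnp <- function(device, constants, flow) {
  cal <- constants$calibration
  if (is.null(cal)) {
    stop("sorter: constants are uncalibrated; run calibrate_force_scale() first",
         call. = FALSE)
  }
  r_edge <- device$z_settle + device$guide_gap
  F_d <- cal$F_d_ref * (flow$Q / cal$Q_ref)
  (constants$force_scale_A / r_edge^2) / F_d
}

#' Critical deflection angle of a vesicle carrying n MNPs
#'
#' The largest guide angle a settled vesicle can follow: the normal component
#' of the drag, F_d sin(theta), must not exceed the edge attraction F_m(n).
#' Hence theta_c = asin(clamp(F_m/F_d, 0, 1)); 90 degrees when the magnetic
#' force dominates outright.
#'
#' @param n MNP count (>= 0). Vectorised.
#' @param device,constants,flow A calibrated system.
#' @return Critical angle in degrees.
#' @export
critical_angle <- function(n, device = device_geometry(),
                           constants = physical_constants(),
                           flow = flow_condition(device = device)) {
  if (any(n < 0)) stop("critical_angle: n must be >= 0", call. = FALSE)
  ratio <- pmin(pmax(n * .capture_ratio_per_mnp(device, constants, flow), 0), 1)
  asin(ratio) * 180 / pi
}

#' Minimum MNP load deflected at a given guide angle
#'
#' Smallest integer n with `critical_angle(n) >= theta`; closed form
#' `ceiling(sin(theta)/ratio_1)` with a tolerance guard for exact anchors.
#'
#' @param theta Guide angle in degrees, in (0, 90).
#' @inheritParams critical_angle
#' @return Integer MNP count.
#' @export
min_mnp_count <- function(theta, device = device_geometry(),
                          constants = physical_constants(),
                          flow = flow_condition(device = device)) {
  if (any(theta <= 0 | theta >= 90)) {
    stop("min_mnp_count: theta must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  r1 <- .capture_ratio_per_mnp(device, constants, flow)
  x <- sin(theta * pi / 180) / r1
  # route-to-higher tie break: n exactly at threshold counts as deflected
  as.integer(ceiling(x - 1e-9))
}

#' Residence time in the settling section
#'
#' Streamwise transit time of the pre-junction length at the mean velocity.
#'
#' @param device,flow Built system components.
#' @return Seconds.
#' @export
residence_time <- function(device, flow) {
  device$pre_junction_length / flow$v_mean
}

#' Closed-form settling time onto the guide plane
#'
#' Overdamped vertical descent under the kappa_z-scaled edge attraction:
#' v_z(z) = kappa_z n A / ((z + z_gap)^2 6 pi eta r), integrated from `z0`
#' down to the transport height gives
#' t = 6 pi eta r [(z0 + z_gap)^3 - (z_settle + z_gap)^3] / (3 kappa_z n A).
#' Unlabeled vesicles (n = 0) never settle: +Inf.
#'
#' @param z0 Starting height (m), in `[0, h]`. Vectorised (with `n`,
#'   `radius`).
#' @param n MNP count (>= 0).
#' @inheritParams critical_angle
#' @param radius Hydrodynamic radius (m); defaults to the reference radius.
#' @return Seconds (0 if already at or below the transport height).
#' @export
settle_time <- function(z0, n, device = device_geometry(),
                        constants = physical_constants(),
                        flow = flow_condition(device = device),
                        radius = constants$reference_radius) {
  if (any(z0 < 0 | z0 > device$channel_height)) {
    stop("settle_time: z0 must lie within [0, channel_height]", call. = FALSE)
  }
  if (any(n < 0)) stop("settle_time: n must be >= 0", call. = FALSE)
  if (is.na(constants$force_scale_A)) {
    stop("settle_time: constants are uncalibrated; run calibrate_force_scale() first",
         call. = FALSE)
  }
  r <- radius + constants$extra_drag_radius
  zg <- device$guide_gap
  num <- 6 * pi * constants$viscosity * r *
    (pmax(z0 + zg, device$z_settle + zg)^3 - (device$z_settle + zg)^3)
  den <- 3 * constants$vertical_coupling * n * constants$force_scale_A
  t <- ifelse(n == 0, Inf, num / den)
  ifelse(z0 <= device$z_settle, 0, t)
}

.outlet_levels <- function(device) device$outlet_labels

## vectorised outlet decision for mnp counts / settle gate
.route_vec <- function(mnp_count, z0, radius, device, constants, flow) {
  ts <- settle_time(z0, mnp_count, device, constants, flow, radius = radius)
  tr <- residence_time(device, flow)
  theta_c <- critical_angle(mnp_count, device, constants, flow)
  # outlet rank: 0 = negative, k = deflected by guide k (1-based); the 1e-9
  # degree tolerance enforces the route-to-higher tie break at exactly
  # marginal loads regardless of floating-point rounding
  rank <- rowSums(outer(theta_c, device$guide_angles - 1e-9, `>=`) + 0)
  rank[ts > tr] <- 0
  .outlet_levels(device)[rank + 1L]
}

#' Route one vesicle to an outlet by the angle-threshold rule
#'
#' A vesicle is deflected only if it settles onto the guide plane within the
#' pre-junction length; a settled vesicle follows the steepest guide whose
#' angle does not exceed its critical angle. Ties at a threshold route to the
#' higher outlet, matching the 4-MNP/3-degree anchor.
#'
#' @param vesicle A list or one-row data.frame with `mnp_count`, `z0` and
#'   (optionally) `radius`.
#' @inheritParams critical_angle
#' @param crosstalk Probability of reassigning the vesicle to an adjacent
#'   outlet (default 0, the ideal device).
#' @return Outlet label, one of the device's `outlet_labels`.
#' @export
route <- function(vesicle, device = device_geometry(),
                  constants = physical_constants(),
                  flow = flow_condition(device = device),
                  crosstalk = 0) {
  if (is.null(vesicle$mnp_count) || is.null(vesicle$z0) ||
      anyNA(vesicle$mnp_count) || anyNA(vesicle$z0)) {
    stop("route: vesicle must carry mnp_count and z0", call. = FALSE)
  }
  radius <- vesicle$radius %||% constants$reference_radius
  out <- .route_vec(vesicle$mnp_count, vesicle$z0, radius,
                    device, constants, flow)
  if (crosstalk > 0) out <- .apply_crosstalk(out, device, crosstalk)
  out
}

.apply_crosstalk <- function(outlets, device, eps) {
  lev <- .outlet_levels(device)
  rank <- match(outlets, lev) - 1L
  n <- length(rank)
  flip <- stats::runif(n) < eps
  step <- sample(c(-1L, 1L), n, replace = TRUE)
  rank[flip] <- pmin(pmax(rank[flip] + step[flip], 0L), length(lev) - 1L)
  lev[rank + 1L]
}

#' Route a whole population (vectorised)
#'
#' @param population Data.frame from [sample_population()].
#' @inheritParams route
#' @param seed Seed for the crosstalk draws (ignored when `crosstalk = 0`).
#' @return The population with its `outlet` column filled.
#' @export
route_population <- function(population, device = device_geometry(),
                             constants = physical_constants(),
                             flow = flow_condition(device = device),
                             crosstalk = 0, seed = NULL) {
  out <- .route_vec(population$mnp_count, population$z0, population$radius,
                    device, constants, flow)
  if (crosstalk > 0) {
    out <- with_seed(seed, .apply_crosstalk(out, device, crosstalk))
  }
  population$outlet <- out
  population
}

#' Run a full sorting experiment
#'
#' Samples nothing itself: takes a population (or a fixture name, which is
#' sampled with `seed`), routes every vesicle, and tallies outlet counts.
#'
#' @param population Population data.frame, [population_model()] or fixture
#'   name.
#' @inheritParams route
#' @param seed Seed used if the population still needs sampling (and for
#'   crosstalk).
#' @param sample_label Sample name for the counts row.
#' @return List with `counts` (one-row data.frame: sample, negative, low,
#'   medium, high) and `population` (routed records).
#' @export
run_experiment <- function(population, device = device_geometry(),
                           constants = physical_constants(),
                           flow = flow_condition(device = device),
                           seed = NULL, crosstalk = 0,
                           sample_label = NULL) {
  if (is.character(population) || inherits(population, "population_model")) {
    model <- if (is.character(population)) make_fixture(population) else population
    sample_label <- sample_label %||% model$name
    population <- sample_population(model, device, constants, seed = seed)
  }
  if (!is.data.frame(population) || nrow(population) == 0) {
    stop("run_experiment: empty population", call. = FALSE)
  }
  routed <- route_population(population, device, constants, flow,
                             crosstalk = crosstalk, seed = seed)
  lev <- .outlet_levels(device)
  tab <- table(factor(routed$outlet, levels = lev))
  counts <- as.data.frame(as.list(as.integer(tab)))
  names(counts) <- lev
  for (lab in c("low", "medium", "high")) {
    if (is.null(counts[[lab]])) counts[[lab]] <- 0L
  }
  counts <- cbind(sample = sample_label %||% "sample1",
                  counts[c("negative", "low", "medium", "high")],
                  stringsAsFactors = FALSE)
  stopifnot(sum(tab) == nrow(routed))
  list(counts = counts, population = routed)
}

#' Integrate a single vesicle trajectory (validation oracle)
#'
#' Independent check on the threshold router: explicit time-stepping of the
#' overdamped vertical descent with streamwise advection through the
#' parabolic flow profile, followed by event-driven transport through the
#' branching guide layout. At each branch point the capture decision is made
#' from the instantaneous force balance (edge attraction vs. the normal
#' drag component); a captured vesicle slides along its guide, transferring
#' to the steeper branch whenever the balance still holds.
#'
#' @param vesicle List or one-row data.frame with `mnp_count`, `y0`, `z0`
#'   and optionally `radius`.
#' @inheritParams critical_angle
#' @param dt Time step for the descent integration (s); default 10 us. The
#'   routed outlet should be stable under halving `dt`.
#' @param max_steps Abort limit for the descent loop.
#' @return List: `outlet`, `settle_time` (s, NA if never settled), `exit_y`
#'   (m), `guide` (0 = none), `time` (s), `path` (decimated x/y/z matrix).
#' @export
simulate_trajectory <- function(vesicle, device = device_geometry(),
                                constants = physical_constants(),
                                flow = flow_condition(device = device),
                                dt = 1e-5, max_steps = 5e6) {
  if (dt <= 0) stop("simulate_trajectory: dt must be > 0", call. = FALSE)
  if (is.null(vesicle$mnp_count) || is.null(vesicle$z0)) {
    stop("simulate_trajectory: vesicle must carry mnp_count and z0", call. = FALSE)
  }
  cal <- constants$calibration
  if (is.null(cal)) {
    stop("simulate_trajectory: constants are uncalibrated", call. = FALSE)
  }
  radius <- (vesicle$radius %||% constants$reference_radius) +
    constants$extra_drag_radius
  res <- traj_integrate(
    y0 = vesicle$y0 %||% 0,
    z0 = vesicle$z0,
    radius = radius,
    n_mnps = as.integer(vesicle$mnp_count),
    h = device$channel_height,
    v_mean = flow$v_mean,
    z_gap = device$guide_gap,
    z_settle = device$z_settle,
    L_pre = device$pre_junction_length,
    branch_spacing = device$branch_spacing,
    sort_length = device$sort_length,
    guide_angles_rad = device$guide_angles * pi / 180,
    eta = constants$viscosity,
    kappa_z = constants$vertical_coupling,
    A = constants$force_scale_A,
    F_d_bal = cal$F_d_ref * (flow$Q / cal$Q_ref),
    dt = dt,
    max_steps = as.integer(max_steps),
    path_stride = 1000L
  )
  if (res$status != 0L) {
    stop(sprintf(paste0("simulate_trajectory: integration did not reach the outlet ",
                        "plane within max_steps (last state x=%.3e, z=%.3e)"),
                 res$x, res$z), call. = FALSE)
  }
  res$outlet <- .outlet_levels(device)[res$guide + 1L]
  res
}
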