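#include <Rcpp.h>
using namespace Rcpp;

// Explicit integrator for one vesicle: overdamped vertical descent under the
// 1/(z+z_gap)^2 edge attraction with streamwise advection through the
// parabolic profile, then event-driven transport through the branching guide
// layout. Capture at each branch point is decided from the instantaneous
// force balance: n * A / (z_settle+z_gap)^2 >= F_d_bal * sin(theta_k).
// [[Rcpp::export]]
List traj_integrate(double y0, double z0, double radius, int n_mnps,
                    double h, double v_mean, double z_gap, double z_settle,
                    double L_pre, double branch_spacing, double sort_length,
                    NumericVector guide_angles_rad,
                    double eta, double kappa_z, double A, double F_d_bal,
                    double dt, int max_steps, int path_stride) {
  const double drag6 = 6.0 * M_PI * eta * radius;
  const double x_end = L_pre + sort_length;
  const int K = guide_angles_rad.size();

  double x = 0.0, y = y0, z = z0, t = 0.0;
  double settle_t = NA_REAL;
  int guide = 0;              // 0 = unattached/negative, k = guide k
  int status = 1;             // 1 = still running, 0 = reached outlet plane

  std::vector<double> px, py, pz;
  px.push_back(x); py.push_back(y); pz.push_back(z);

  // magnetic-to-drag ratio of the lateral balance at the transport height
  const double r_edge = z_settle + z_gap;
  const double ratio = (F_d_bal > 0.0) ? n_mnps * A / (r_edge * r_edge * F_d_bal)
                                       : 0.0;

  // --- phase 1: descent (time-stepped; the only nonlinear dynamics) -------
  int step = 0;
  bool settled = (z <= z_settle);
  if (settled) { z = z_settle; settle_t = 0.0; }
  while (!settled && step < max_steps) {
    double vx = 6.0 * v_mean * (z / h) * (1.0 - z / h);
    double vz = 0.0;
    if (n_mnps > 0) {
      double d = z + z_gap;
      vz = kappa_z * n_mnps * A / (d * d * drag6);
    }
    z -= vz * dt;
    x += vx * dt;
    t += dt;
    ++step;
    if (z <= z_settle) {
      z = z_settle;
      settled = true;
      settle_t = t;
    }
    if (step % path_stride == 0) { px.push_back(x); py.push_back(y); pz.push_back(z); }
    if (x >= x_end) break;   // swept out before settling
    if (n_mnps == 0 && x < x_end) {
      // straight streamline: advance analytically to the outlet plane
      double vx0 = 6.0 * v_mean * (z / h) * (1.0 - z / h);
      if (vx0 <= 0.0) { status = 2; break; }  // stuck on a no-slip wall
      t += (x_end - x) / vx0;
      x = x_end;
      break;
    }
  }
  if (step >= max_steps && !settled && x < x_end) {
    status = 2;  // did not converge
  }

  // --- phase 2: settled transport through the branch points (event-driven)
  if (status != 2 && settled && x < x_end) {
    double vs = 6.0 * v_mean * (z_settle / h) * (1.0 - z_settle / h);
    if (vs <= 0.0) {
      status = 2;
    } else {
      for (int k = 0; k < K; ++k) {
        double xb = L_pre + k * branch_spacing;
        if (xb >= x_end) break;
        if (x < xb) {
          // advance to the branch point along the current guide (or straight)
          double run = xb - x;
          if (guide > 0) {
            double th = guide_angles_rad[guide - 1];
            y += run * tan(th);
            t += run / (vs * cos(th) * cos(th)); // dx = v_s cos^2(th) dt
          } else {
            t += run / vs;
          }
          x = xb;
          px.push_back(x); py.push_back(y); pz.push_back(z);
        }
        // only vesicles settled before this branch can engage it, and the
        // branching layout hands a vesicle from guide k-1 to guide k
        bool reachable = (guide == k) && (x <= xb + 1e-12);
        // 1e-12 relative tolerance: marginal loads hold the guide (the
        // route-to-higher tie break of the threshold router)
        if (reachable && ratio >= sin(guide_angles_rad[k]) * (1.0 - 1e-12)) {
          guide = k + 1;
        }
      }
      // final run to the outlet plane
      double run = x_end - x;
      if (run > 0) {
        if (guide > 0) {
          double th = guide_angles_rad[guide - 1];
          y += run * tan(th);
          t += run / (vs * cos(th) * cos(th));
        } else {
          t += run / vs;
        }
        x = x_end;
      }
      px.push_back(x); py.push_back(y); pz.push_back(z);
    }
  }
  if (x >= x_end) status = 0;

  NumericMatrix path(px.size(), 3);
  for (size_t i = 0; i < px.size(); ++i) {
    path(i, 0) = px[i]; path(i, 1) = py[i]; path(i, 2) = pz[i];
  }
  colnames(path) = CharacterVector::create("x", "y", "z");

  return List::create(
    _["guide"] = guide,
    _["settle_time"] = settle_t,
    _["exit_y"] = y,
    _["time"] = t,
    _["x"] = x,
    _["z"] = z,
    _["status"] = status,
    _["path"] = path
  );
}
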