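#include <Rcpp.h>
using namespace Rcpp;

// Specular reflection of the segment p -> q at the cylinder rho = r,
// repeated until the endpoint lies inside. p is assumed inside on entry.
// Near-tangential chords legitimately bounce many times (the consumed chord
// is 2 sqrt(r^2 - b^2) per bounce, vanishing at grazing incidence), so the
// cap is generous; past it the residual path is terminated on the wall,
// which only ever discards a float-scale grazing remainder. A gross excess
// at the cap indicates a genuine geometry failure and stops.
static inline void reflect_cylinder(double &px, double &py,
                                    double &qx, double &qy, double r) {
  const double r2 = r * r;
  int bounce = 0;
  while (qx * qx + qy * qy > r2) {
    if (++bounce > 512) {
      const double qn = std::sqrt(qx * qx + qy * qy);
      if (qn > 1.1 * r) stop("reflection loop did not converge (>512 bounces)");
      const double s = r * (1.0 - 1e-12) / qn;
      qx *= s; qy *= s;
      return;
    }
    const double ux = qx - px, uy = qy - py;
    const double A = ux * ux + uy * uy;
    if (A <= 0.0) {  // no residual displacement: clamp inside
      const double qn = std::sqrt(qx * qx + qy * qy);
      const double s = r * (1.0 - 1e-12) / qn;
      qx *= s; qy *= s;
      return;
    }
    const double B = 2.0 * (px * ux + py * uy);
    double C = px * px + py * py - r2;
    if (C > 0.0) C = 0.0;  // p may sit epsilon outside after a bounce
    double disc = B * B - 4.0 * A * C;
    if (disc < 0.0) disc = 0.0;
    double t = (-B + std::sqrt(disc)) / (2.0 * A);
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    // hit point, renormalised onto the wall, and its outward normal
    double hx = px + t * ux, hy = py + t * uy;
    const double hn = std::sqrt(hx * hx + hy * hy);
    if (hn > 0.0) { hx *= r / hn; hy *= r / hn; }
    const double nx = hx / r, ny = hy / r;
    // reflect the residual displacement about the tangent plane
    const double wx = qx - hx, wy = qy - hy;
    const double wn = wx * nx + wy * ny;
    qx = hx + (wx - 2.0 * wn * nx);
    qy = hy + (wy - 2.0 * wn * ny);
    px = hx;
    py = hy;
  }
}

// Brownian / Langevin particle tracing in a cylinder of accessible radius
// r_acc and axial extent [0, absorb_plane]: reflecting top (z = 0) and side
// wall, absorbing bottom. Returns per-particle absorption times (NA if the
// particle is still active at n_steps * dt). Particles are simulated in a
// fixed order, each consuming RNG draws sequentially, so results are
// reproducible bit-for-bit from R's seed.
//
// step_rms      : per-axis RMS displacement sqrt(2 D dt) (overdamped scheme)
// langevin      : if true, integrate velocity with drag (semi-implicit Euler)
// v_kick        : sigma_F * dt / m_p  (velocity increment scale per step)
// damp          : 1 + dt / tau        (implicit drag divisor)
// lateral_walls : if false, the cylindrical wall is ignored (diagnostic mode)
// [[Rcpp::export]]
NumericVector cpp_simulate_fpt(int n_particles, double r_acc, double z0,
                               double absorb_plane, double dt, double n_steps,
                               double step_rms, bool langevin, double v_kick,
                               double damp, bool lateral_walls) {
  NumericVector out(n_particles, NA_REAL);
  const long long ns = (long long)n_steps;
  for (int i = 0; i < n_particles; ++i) {
    // uniform release over the accessible disk, centre at z0
    const double rr = r_acc * std::sqrt(unif_rand());
    const double th = 2.0 * M_PI * unif_rand();
    double x = rr * std::cos(th), y = rr * std::sin(th), z = z0;
    double vx = 0.0, vy = 0.0, vz = 0.0;
    for (long long k = 1; k <= ns; ++k) {
      double dx, dy, dz;
      if (langevin) {
        vx = (vx + v_kick * norm_rand()) / damp;
        vy = (vy + v_kick * norm_rand()) / damp;
        vz = (vz + v_kick * norm_rand()) / damp;
        dx = vx * dt; dy = vy * dt; dz = vz * dt;
      } else {
        dx = step_rms * norm_rand();
        dy = step_rms * norm_rand();
        dz = step_rms * norm_rand();
      }
      double zn = z + dz;
      // absorption is tested on the straight pre-reflection segment
      if (zn >= absorb_plane) {
        out[i] = (double)k * dt;
        break;
      }
      if (zn < 0.0) zn = -zn;  // specular top wall
      double xn = x + dx, yn = y + dy;
      if (lateral_walls && (xn * xn + yn * yn > r_acc * r_acc)) {
        double px = x, py = y;
        reflect_cylinder(px, py, xn, yn, r_acc);
      }
      x = xn; y = yn; z = zn;
      if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
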