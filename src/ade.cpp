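#include <Rcpp.h>
using namespace Rcpp;

// Alternating Direction Explicit (Barakat-Clark / Saul'yev two-sweep) update
// of one diffusion step on a masked 3D lattice.
//
// Each sweep solves, in place,
//   u'(1+3L) = u(1-3L) + L * (sum of "new" upstream neighbours
//                              + sum of "old" downstream neighbours)
// with L = D*dt/dh^2; the upward sweep traverses indices in increasing
// order (so lower-index neighbours are freshly updated), the downward sweep
// in decreasing order, and the two results are averaged. The pairing of an
// implicit-in-sweep term with each explicit term makes the scheme
// unconditionally stable despite being explicit to evaluate.
//
// Boundary handling at masked-to-unmasked (or out-of-lattice) faces:
//   no-flux:   mirrored ghost equal to the centre value at the sweep's time
//              level (the flux term vanishes);
//   Dirichlet: ghost = 2*pb - u_centre, placing the boundary value pb exactly
//              on the face of the boundary voxel (second-order accurate).
// Face selection by direction: -z -> base, +z -> top, lateral -> sides.
//
// bc codes: 0 = no_flux, 1 = dirichlet.

static inline int face_bc(int dx, int dy, int dz,
                          int bc_base, int bc_side, int bc_top) {
  if (dz < 0) return bc_base;
  if (dz > 0) return bc_top;
  (void)dx; (void)dy;
  return bc_side;
}

static void sweep(std::vector<double>& w, const LogicalVector& mask,
                  int nx, int ny, int nz, double lam,
                  int bc_base, int bc_side, int bc_top, double pb,
                  bool upward) {
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  int i0 = upward ? 0 : nx - 1, istep = upward ? 1 : -1;
  int j0 = upward ? 0 : ny - 1, jstep = upward ? 1 : -1;
  int k0 = upward ? 0 : nz - 1, kstep = upward ? 1 : -1;

  for (int k = k0; k >= 0 && k < nz; k += kstep) {
    for (int j = j0; j >= 0 && j < ny; j += jstep) {
      for (int i = i0; i >= 0 && i < nx; i += istep) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        double uc = w[idx];            // still the old value at this voxel
        double denom = 1.0 + 3.0 * lam;
        double num = (1.0 - 3.0 * lam) * uc;
        for (int d = 0; d < 6; ++d) {
          int dx = dirs[d][0], dy = dirs[d][1], dz = dirs[d][2];
          // "new" side: the direction the sweep has already visited
          bool new_side = upward ? (dx + dy + dz < 0) : (dx + dy + dz > 0);
          int ii = i + dx, jj = j + dy, kk = k + dz;
          bool inside = ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                        kk >= 0 && kk < nz;
          R_xlen_t nidx = inside ?
            (R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk) : 0;
          if (inside && mask[nidx]) {
            num += lam * w[nidx];      // updated if new side, old otherwise
          } else {
            int bc = face_bc(dx, dy, dz, bc_base, bc_side, bc_top);
            if (bc == 0) {             // no-flux mirror
              if (new_side) denom -= lam; else num += lam * uc;
            } else {                   // Dirichlet ghost = 2*pb - u_centre
              if (new_side) { num += 2.0 * lam * pb; denom += lam; }
              else          { num += lam * (2.0 * pb - uc); }
            }
          }
        }
        w[idx] = num / denom;
      }
    }
  }
}

// Precomputed neighbour table: for each masked voxel (ascending linear
// index), the linear index of each of its 6 neighbours, or -1 (no-flux
// face) / -2 (Dirichlet face) where the neighbour leaves the mask.
struct NbrTable {
  std::vector<R_xlen_t> vox;    // masked voxel indices, ascending
  std::vector<R_xlen_t> nbr;    // 6 entries per voxel
};

static NbrTable build_table(const LogicalVector& mask, int nx, int ny,
                            int nz, int bc_base, int bc_side, int bc_top) {
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  NbrTable tb;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        tb.vox.push_back(idx);
        for (int d = 0; d < 6; ++d) {
          int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
          bool inside = ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                        kk >= 0 && kk < nz;
          R_xlen_t nidx = inside ?
            (R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk) : -1;
          if (inside && mask[nidx]) tb.nbr.push_back(nidx);
          else {
            int bc = face_bc(dirs[d][0], dirs[d][1], dirs[d][2],
                             bc_base, bc_side, bc_top);
            tb.nbr.push_back(bc == 0 ? -1 : -2);
          }
        }
      }
  return tb;
}

// One Saul'yev sweep using the precomputed table. Directions 0,2,4 point
// to lower indices ("new" side in the upward sweep), 1,3,5 to higher.
static void sweep_fast(std::vector<double>& w, const NbrTable& tb,
                       double lam, double pb, bool upward) {
  R_xlen_t nvox = (R_xlen_t)tb.vox.size();
  for (R_xlen_t v0 = 0; v0 < nvox; ++v0) {
    R_xlen_t v = upward ? v0 : nvox - 1 - v0;
    R_xlen_t idx = tb.vox[v];
    const R_xlen_t* nb = &tb.nbr[v * 6];
    double uc = w[idx];
    double denom = 1.0 + 3.0 * lam;
    double num = (1.0 - 3.0 * lam) * uc;
    for (int d = 0; d < 6; ++d) {
      bool new_side = upward ? (d % 2 == 0) : (d % 2 == 1);
      R_xlen_t nidx = nb[d];
      if (nidx >= 0) num += lam * w[nidx];
      else if (nidx == -1) {                 // no-flux mirror
        if (new_side) denom -= lam; else num += lam * uc;
      } else {                               // Dirichlet face ghost
        if (new_side) { num += 2.0 * lam * pb; denom += lam; }
        else          { num += lam * (2.0 * pb - uc); }
      }
    }
    w[idx] = num / denom;
  }
}

// Full time march of one species: n_steps ADE steps with per-step
// Dirichlet boundary values and an optional Michaelis-Menten sink
// (sink_coef = V_max * sigma / k_h in mmHg/s; sink_coef <= 0 disables).
// Snapshots of the field (or, if window_idx is non-empty, the mean over
// those voxels) are recorded after the step counts listed in snap_steps
// (0 = initial state).
// [[Rcpp::export]]
List march_species_cpp(NumericVector u0, LogicalVector mask,
                       IntegerVector dims, double lam,
                       int bc_base, int bc_side, int bc_top,
                       NumericVector boundary_pp_per_step,
                       double sink_coef, double K_m, double dt,
                       IntegerVector snap_steps,
                       IntegerVector window_idx) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (u0.size() != n || mask.size() != n)
    stop("field/mask size does not match dims");
  int n_steps = boundary_pp_per_step.size();
  NbrTable tb = build_table(mask, nx, ny, nz, bc_base, bc_side, bc_top);
  R_xlen_t nvox = (R_xlen_t)tb.vox.size();
  for (R_xlen_t v = 0; v < nvox; ++v)
    if (!R_finite(u0[tb.vox[v]])) stop("non-finite value in field");

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> w1(n), w2(n);
  List snaps(snap_steps.size());
  int next_snap = 0;
  auto record = [&](int pos) {
    if (window_idx.size() > 0) {
      double s = 0.0;
      for (int q = 0; q < window_idx.size(); ++q)
        s += u[window_idx[q] - 1];          // R 1-based indices
      snaps[pos] = s / window_idx.size();
    } else {
      NumericVector out(u.begin(), u.end());
      out.attr("dim") = dims;
      snaps[pos] = out;
    }
  };
  while (next_snap < snap_steps.size() && snap_steps[next_snap] == 0)
    record(next_snap++);
  for (int s = 1; s <= n_steps; ++s) {
    double pb = boundary_pp_per_step[s - 1];
    std::copy(u.begin(), u.end(), w1.begin());
    std::copy(u.begin(), u.end(), w2.begin());
    sweep_fast(w1, tb, lam, pb, true);
    sweep_fast(w2, tb, lam, pb, false);
    for (R_xlen_t v = 0; v < nvox; ++v) {
      R_xlen_t idx = tb.vox[v];
      double val = 0.5 * (w1[idx] + w2[idx]);
      if (sink_coef > 0.0) {
        double up = u[idx];
        val -= dt * sink_coef * up / (up + K_m);
      }
      u[idx] = val > 0.0 ? val : 0.0;
    }
    while (next_snap < snap_steps.size() && snap_steps[next_snap] == s)
      record(next_snap++);
  }
  return snaps;
}

// [[Rcpp::export]]
NumericVector ade_step_cpp(NumericVector u, LogicalVector mask,
                           IntegerVector dims, double lam,
                           int bc_base, int bc_side, int bc_top,
                           double boundary_pp,
                           NumericVector sink, double dt) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (u.size() != n || mask.size() != n)
    stop("field/mask size does not match dims");
  for (R_xlen_t t = 0; t < n; ++t)
    if (mask[t] && !R_finite(u[t])) stop("non-finite value in field");
  bool has_sink = sink.size() == n;
  if (!has_sink && sink.size() != 1)
    stop("sink must have length 1 or match the field");

  std::vector<double> w1(u.begin(), u.end());
  std::vector<double> w2(u.begin(), u.end());
  sweep(w1, mask, nx, ny, nz, lam, bc_base, bc_side, bc_top, boundary_pp, true);
  sweep(w2, mask, nx, ny, nz, lam, bc_base, bc_side, bc_top, boundary_pp, false);

  NumericVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!mask[t]) { out[t] = 0.0; continue; }
    double v = 0.5 * (w1[t] + w2[t]);
    v -= (has_sink ? sink[t] : sink[0]) * dt;
    out[t] = v > 0.0 ? v : 0.0;
  }
  return out;
}
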