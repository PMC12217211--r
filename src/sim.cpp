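#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Single-tip trajectory: fixed-dt Monte Carlo of the 3-state chain.
// rates = (kGS,kGP,kSG,kSP,kPG,kPS), vels = (vG, -vS, 0).
// States: 0 = G, 1 = S, 2 = P.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List tip_trajectory_cpp(NumericVector rates, NumericVector vels,
                        double t_max, double dt, int record_every) {
  const double ktot[3] = {rates[0] + rates[1], rates[2] + rates[3],
                          rates[4] + rates[5]};
  // transition probability per step and branch ratios
  double ptrans[3], pfirst[3];
  int dest1[3] = {1, 0, 0}, dest2[3] = {2, 2, 1};
  // from G: S w.p. kGS/ktot else P; from S: G else P; from P: G else S
  double num1[3] = {rates[0], rates[2], rates[4]};
  for (int i = 0; i < 3; ++i) {
    ptrans[i] = (ktot[i] > 0) ? 1.0 - std::exp(-ktot[i] * dt) : 0.0;
    pfirst[i] = (ktot[i] > 0) ? num1[i] / ktot[i] : 0.0;
  }
  long nstep = (long)std::ceil(t_max / dt);
  long nrec = nstep / record_every + 1;
  NumericVector pos(nrec), steps(nrec);
  IntegerVector states(nrec);
  std::vector<double> dwell;
  dwell.reserve(1024);
  std::vector<int> dwell_state;
  dwell_state.reserve(1024);
  double occ[3] = {0, 0, 0};
  int s = 0;
  double x = 0.0, sojourn = 0.0;
  long ir = 0;
  pos[0] = 0.0; states[0] = 1; steps[0] = 0; ir = 1;
  for (long i = 1; i <= nstep; ++i) {
    if (ptrans[s] > 0 && unif_rand() < ptrans[s]) {
      dwell.push_back(sojourn + dt); // transition occurs within this step
      dwell_state.push_back(s + 1);
      s = (unif_rand() < pfirst[s]) ? dest1[s] : dest2[s];
      sojourn = 0.0;
    } else {
      sojourn += dt;
    }
    x += vels[s] * dt;
    occ[s] += dt;
    if (i % record_every == 0 && ir < nrec) {
      pos[ir] = x; states[ir] = s + 1; steps[ir] = (double)i; ++ir;
    }
  }
  return List::create(_["steps"] = steps[Range(0, ir - 1)],
                      _["positions"] = pos[Range(0, ir - 1)],
                      _["states"] = states[Range(0, ir - 1)],
                      _["dwell_times"] = NumericVector(dwell.begin(), dwell.end()),
                      _["dwell_states"] = IntegerVector(dwell_state.begin(), dwell_state.end()),
                      _["occupancy_time"] = NumericVector::create(occ[0], occ[1], occ[2]));
}

// ---------------------------------------------------------------------------
// Directed-rod simulator.
// ---------------------------------------------------------------------------

struct Rods {
  std::vector<double> xb, yb, th, len;
  std::vector<int> st; // 0 G, 1 S, 2 P
  size_t n() const { return xb.size(); }
  void add(double x, double y, double t, double l, int s) {
    xb.push_back(x); yb.push_back(y); th.push_back(t);
    len.push_back(l); st.push_back(s);
  }
  void remove_marked(const std::vector<char> &dead) {
    size_t j = 0;
    for (size_t i = 0; i < n(); ++i) {
      if (!dead[i]) {
        if (j != i) {
          xb[j] = xb[i]; yb[j] = yb[i]; th[j] = th[i];
          len[j] = len[i]; st[j] = st[i];
        }
        ++j;
      }
    }
    xb.resize(j); yb.resize(j); th.resize(j); len.resize(j); st.resize(j);
  }
};

// proper segment-segment intersection (inclusive of touching)
static inline bool seg_intersect(double ax, double ay, double bx, double by,
                                 double cx, double cy, double dx, double dy) {
  double d1x = bx - ax, d1y = by - ay, d2x = dx - cx, d2y = dy - cy;
  double denom = d1x * d2y - d1y * d2x;
  double ex = cx - ax, ey = cy - ay;
  double tnum = ex * d2y - ey * d2x;
  double unum = ex * d1y - ey * d1x;
  if (std::fabs(denom) < 1e-14) return false; // parallel: measure-zero, ignore
  double t = tnum / denom, u = unum / denom;
  return t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0;
}

struct Grid {
  double h, x0, y0;
  int ncx, ncy;
  bool periodic;
  double L;
  std::vector<std::vector<int> > cells;
  void init(double h_, double x0_, double y0_, int ncx_, int ncy_,
            bool per, double L_) {
    h = h_; x0 = x0_; y0 = y0_; ncx = ncx_; ncy = ncy_;
    periodic = per; L = L_;
    cells.assign((size_t)ncx * ncy, std::vector<int>());
  }
  inline int cix(double x) const {
    int i = (int)std::floor((x - x0) / h);
    if (periodic) { i %= ncx; if (i < 0) i += ncx; }
    else { if (i < 0) i = 0; if (i >= ncx) i = ncx - 1; }
    return i;
  }
  inline int ciy(double y) const {
    int i = (int)std::floor((y - y0) / h);
    if (periodic) { i %= ncy; if (i < 0) i += ncy; }
    else { if (i < 0) i = 0; if (i >= ncy) i = ncy - 1; }
    return i;
  }
  inline int idx(int ix, int iy) const { return iy * ncx + ix; }
  void clear() {
    for (size_t i = 0; i < cells.size(); ++i) cells[i].clear();
  }
  // register rod i by sampling its segment every h/2
  void add_rod(int i, double xb, double yb, double th, double len) {
    double c = std::cos(th), s = std::sin(th);
    int nsamp = (int)std::floor(len / (h / 2)) + 2;
    int last = -1;
    for (int k = 0; k < nsamp; ++k) {
      double f = (nsamp == 1) ? 0.0 : (double)k / (nsamp - 1);
      double x = xb + f * len * c, y = yb + f * len * s;
      int id = idx(cix(x), ciy(y));
      if (id != last) {
        if (cells[id].empty() || cells[id].back() != i) cells[id].push_back(i);
        last = id;
      }
    }
  }
};

// [[Rcpp::export]]
List rod_sim_cpp(NumericVector rates, double vG, double vS,
                 double kb, double beta, bool one_state,
                 int mode, double L, double ext,
                 double dt, long n_steps,
                 int record_every, int snapshot_every,
                 NumericMatrix init, bool rebranch_on, bool log_events,
                 int max_rods) {
  const bool periodic = (mode == 0);
  Rods R;
  for (int i = 0; i < init.nrow(); ++i)
    R.add(init(i, 0), init(i, 1), init(i, 2), init(i, 3),
          (int)init(i, 4) - 1);

  const double ktot[3] = {rates[0] + rates[1], rates[2] + rates[3],
                          rates[4] + rates[5]};
  double ptrans[3], pfirst[3];
  int dest1[3] = {1, 0, 0}, dest2[3] = {2, 2, 1};
  double num1[3] = {rates[0], rates[2], rates[4]};
  for (int i = 0; i < 3; ++i) {
    ptrans[i] = (ktot[i] > 0) ? 1.0 - std::exp(-ktot[i] * dt) : 0.0;
    pfirst[i] = (ktot[i] > 0) ? num1[i] / ktot[i] : 0.0;
  }
  const double vstate[3] = {vG, -vS, 0.0};

  Grid grid;
  const double hcell = 5.0;
  if (periodic) {
    int nc = std::max(1, (int)std::floor(L / hcell));
    grid.init(L / nc, 0.0, 0.0, nc, nc, true, L);
  } else {
    int nc = std::max(1, (int)std::floor(2.0 * ext / hcell));
    grid.init(2.0 * ext / nc, -ext, -ext, nc, nc, false, 0.0);
  }

  long cum_branch = 0, cum_debranch = 0, cum_rebranch = 0, cum_collision = 0;
  std::vector<double> rec_t, rec_len;
  std::vector<long> rec_n, rec_ng, rec_br, rec_db, rec_rb, rec_col;
  List snapshots;
  std::vector<double> snap_t;
  std::vector<double> ev_t, ev_x, ev_y;
  std::vector<int> ev_type; // 1 branch, 2 debranch(gone), 3 rebranch, 4 collision

  std::vector<double> len_old;
  std::vector<char> dead, newborn;

  auto record = [&](double t) {
    double tot = 0.0; long ng = 0;
    for (size_t i = 0; i < R.n(); ++i) {
      tot += R.len[i];
      if (R.st[i] == 0) ++ng;
    }
    rec_t.push_back(t); rec_n.push_back((long)R.n()); rec_ng.push_back(ng);
    rec_len.push_back(tot);
    rec_br.push_back(cum_branch); rec_db.push_back(cum_debranch);
    rec_rb.push_back(cum_rebranch); rec_col.push_back(cum_collision);
  };
  auto snapshot = [&]() {
    NumericMatrix m((int)R.n(), 5);
    for (size_t i = 0; i < R.n(); ++i) {
      m(i, 0) = R.xb[i]; m(i, 1) = R.yb[i]; m(i, 2) = R.th[i];
      m(i, 3) = R.len[i]; m(i, 4) = R.st[i] + 1;
    }
    return m;
  };

  record(0.0);
  bool blew_up = false;

  for (long step = 1; step <= n_steps; ++step) {
    double t = step * dt;
    size_t n0 = R.n();
    newborn.assign(n0, 0);

    // 1. state transitions
    if (!one_state) {
      for (size_t i = 0; i < n0; ++i) {
        int s = R.st[i];
        if (ptrans[s] > 0 && unif_rand() < ptrans[s])
          R.st[i] = (unif_rand() < pfirst[s]) ? dest1[s] : dest2[s];
      }
    }

    // 2. motion
    len_old.assign(R.len.begin(), R.len.end());
    for (size_t i = 0; i < n0; ++i) R.len[i] += vstate[R.st[i]] * dt;

    // 3. debranching (length hits zero)
    dead.assign(n0, 0);
    for (size_t i = 0; i < n0; ++i) {
      if (R.len[i] <= 0.0 && R.st[i] == 1) {
        ++cum_debranch;
        if (rebranch_on && beta > 0 && unif_rand() < beta) {
          ++cum_rebranch;
          R.len[i] = 0.0; R.st[i] = 0;
          R.th[i] = unif_rand() * 2.0 * M_PI;
          newborn[i] = 1;
          if (log_events) {
            ev_t.push_back(t); ev_x.push_back(R.xb[i]); ev_y.push_back(R.yb[i]);
            ev_type.push_back(3);
          }
        } else {
          dead[i] = 1;
          if (log_events) {
            ev_t.push_back(t); ev_x.push_back(R.xb[i]); ev_y.push_back(R.yb[i]);
            ev_type.push_back(2);
          }
        }
      } else if (R.len[i] < 0.0) {
        R.len[i] = 0.0; // paused/growing cannot go negative; numerical guard
      }
    }
    R.remove_marked(dead);
    { // keep auxiliary arrays aligned after compaction
      size_t j = 0;
      for (size_t i = 0; i < n0; ++i)
        if (!dead[i]) { len_old[j] = len_old[i]; newborn[j] = newborn[i]; ++j; }
      len_old.resize(j); newborn.resize(j);
    }

    // 4. collisions: swept tip segment of each rod that grew this step
    //    against every other rod (spatial hash, min-image when periodic)
    size_t n1 = R.n();
    if (n1 > 1) {
      grid.clear();
      for (size_t i = 0; i < n1; ++i)
        grid.add_rod((int)i, R.xb[i], R.yb[i], R.th[i], R.len[i]);
      dead.assign(n1, 0);
      std::vector<int> stamp(n1, -1);
      for (size_t i = 0; i < n1; ++i) {
        if (R.st[i] != 0 || newborn[i] || R.len[i] <= len_old[i]) continue;
        double c = std::cos(R.th[i]), s = std::sin(R.th[i]);
        double p0x = R.xb[i] + len_old[i] * c, p0y = R.yb[i] + len_old[i] * s;
        double p1x = R.xb[i] + R.len[i] * c, p1y = R.yb[i] + R.len[i] * s;
        double mx = 0.5 * (p0x + p1x), my = 0.5 * (p0y + p1y);
        int ix = grid.cix(mx), iy = grid.ciy(my);
        bool hit = false;
        for (int ddy = -1; ddy <= 1 && !hit; ++ddy) {
          for (int ddx = -1; ddx <= 1 && !hit; ++ddx) {
            int jx = ix + ddx, jy = iy + ddy;
            if (periodic) {
              jx = (jx % grid.ncx + grid.ncx) % grid.ncx;
              jy = (jy % grid.ncy + grid.ncy) % grid.ncy;
            } else {
              if (jx < 0 || jx >= grid.ncx || jy < 0 || jy >= grid.ncy)
                continue;
            }
            const std::vector<int> &cell = grid.cells[grid.idx(jx, jy)];
            for (size_t q = 0; q < cell.size(); ++q) {
              int j = cell[q];
              if ((size_t)j == i || stamp[j] == (int)i) continue;
              stamp[j] = (int)i;
              if (R.len[j] <= 0.0) continue;
              double cj = std::cos(R.th[j]), sj = std::sin(R.th[j]);
              double ax = R.xb[j], ay = R.yb[j];
              double bx = ax + R.len[j] * cj, by = ay + R.len[j] * sj;
              if (periodic) {
                // shift target rod to the image nearest the swept tip
                double ox = L * std::floor((mx - 0.5 * (ax + bx)) / L + 0.5);
                double oy = L * std::floor((my - 0.5 * (ay + by)) / L + 0.5);
                for (int u = -1; u <= 1 && !hit; ++u)
                  for (int w = -1; w <= 1 && !hit; ++w)
                    if (seg_intersect(p0x, p0y, p1x, p1y,
                                      ax + ox + u * L, ay + oy + w * L,
                                      bx + ox + u * L, by + oy + w * L))
                      hit = true;
              } else {
                if (seg_intersect(p0x, p0y, p1x, p1y, ax, ay, bx, by))
                  hit = true;
              }
              if (hit) break;
            }
          }
        }
        if (hit) {
          dead[i] = 1;
          ++cum_collision;
          if (log_events) {
            ev_t.push_back(t); ev_x.push_back(p1x); ev_y.push_back(p1y);
            ev_type.push_back(4);
          }
        }
      }
      R.remove_marked(dead);
      {
        size_t j = 0;
        for (size_t i = 0; i < n1; ++i)
          if (!dead[i]) { len_old[j] = len_old[i]; ++j; }
      }
    }

    // 5. branching: each rod nucleates with prob 1 - exp(-l * kb * dt)
    size_t n2 = R.n();
    for (size_t i = 0; i < n2; ++i) {
      if (R.len[i] <= 0.0) continue;
      double pb = 1.0 - std::exp(-R.len[i] * kb * dt);
      if (pb > 0 && unif_rand() < pb) {
        double nx, ny;
        if (periodic) {
          nx = unif_rand() * L; ny = unif_rand() * L;
        } else {
          // random point on the circle through the mother branch midpoint
          double c = std::cos(R.th[i]), s = std::sin(R.th[i]);
          double mx = R.xb[i] + 0.5 * R.len[i] * c;
          double my = R.yb[i] + 0.5 * R.len[i] * s;
          double rm = std::sqrt(mx * mx + my * my);
          double phi = unif_rand() * 2.0 * M_PI;
          nx = rm * std::cos(phi); ny = rm * std::sin(phi);
        }
        R.add(nx, ny, unif_rand() * 2.0 * M_PI, 0.0, 0);
        ++cum_branch;
        if (log_events) {
          ev_t.push_back(t); ev_x.push_back(nx); ev_y.push_back(ny);
          ev_type.push_back(1);
        }
      }
    }

    if ((int)R.n() > max_rods) { blew_up = true; record(t); break; }
    if (record_every > 0 && step % record_every == 0) record(t);
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snapshots.push_back(snapshot());
      snap_t.push_back(t);
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix record_m((int)rec_t.size(), 8);
  for (size_t i = 0; i < rec_t.size(); ++i) {
    record_m(i, 0) = rec_t[i];   record_m(i, 1) = (double)rec_n[i];
    record_m(i, 2) = rec_len[i]; record_m(i, 3) = (double)rec_ng[i];
    record_m(i, 4) = (double)rec_br[i]; record_m(i, 5) = (double)rec_db[i];
    record_m(i, 6) = (double)rec_rb[i]; record_m(i, 7) = (double)rec_col[i];
  }
  colnames(record_m) = CharacterVector::create(
      "time", "n_rods", "total_length", "n_growing",
      "cum_branch", "cum_debranch", "cum_rebranch", "cum_collision");

  NumericMatrix events_m((int)ev_t.size(), 4);
  for (size_t i = 0; i < ev_t.size(); ++i) {
    events_m(i, 0) = ev_t[i]; events_m(i, 1) = (double)ev_type[i];
    events_m(i, 2) = ev_x[i]; events_m(i, 3) = ev_y[i];
  }
  colnames(events_m) = CharacterVector::create("time", "type", "x", "y");

  return List::create(_["record"] = record_m,
                      _["final"] = snapshot(),
                      _["snapshots"] = snapshots,
                      _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
                      _["events"] = events_m,
                      _["blew_up"] = blew_up);
}
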