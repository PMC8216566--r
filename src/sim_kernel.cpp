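// Discrete stochastic agent-based simulation of axonal mitochondrial
// maintenance (CoG and SS exchange mechanisms, optional mitophagy and
// local translation).
//
// Fixed time step dt; per-step rule order: move -> stop/fuse -> restart ->
// decay -> engulf -> produce.
//
// Two representation choices keep the per-step cost low without changing
// the realized per-step rules:
//  * Health decay is uniform across agents, so health is stored on an
//    inflated scale h = health * exp(+k_d t); decay costs no per-agent
//    work, fusion averages stay valid (both partners share the scale),
//    and the mitophagy comparison health < phi becomes h < phi*exp(k_d t)
//    against a global threshold. Requires k_d*dt*n_steps < 600 (checked
//    by the R wrapper).
//  * Between site crossings, boundary hits and threshold crossings,
//    motile agents evolve deterministically, and stationary agents have
//    geometric restart waits and deterministic engulfment times. Each
//    agent therefore carries the precomputed step of its next event
//    (crossing, reflection, exit, engulfment, restart); in between it is
//    only ticked past. The event steps are computed exactly as the first
//    step at which the per-step rule would fire, so results follow the
//    same distributions as a naive per-step implementation.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

namespace {

const int ST_ANT = 0, ST_RET = 1, ST_STAT = 2, ST_ENG = 3;
const int EV_WAKE = 0, EV_SENGULF = 1;              // stationary queue
const int MV_CROSS = 0, MV_REFLECT = 1, MV_EXIT = 2, MV_ENGULF = 3;

struct StatAgent {
  double h;
  int site;     // 1..n
  int slot;     // SS slot (0-based), -1 for CoG
  int version;
  int gid;      // stable id for trajectory output
  bool alive;
};

struct Event {
  int step;
  int type;     // wake before engulf within a step
  long seq;     // insertion order for determinism
  int idx;      // registry index
  int version;
};
struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.step != b.step) return a.step > b.step;
    if (a.type != b.type) return a.type > b.type;
    return a.seq > b.seq;
  }
};

inline int geom_steps(double p, int cap) {
  // failures before the first success of a per-step Bernoulli(p); capped
  if (p <= 0.0) return cap;
  if (p >= 1.0) return 0;
  double g = R::rgeom(p);
  if (!R_finite(g) || g > cap) return cap;
  return (int)g;
}

} // namespace

// [[Rcpp::export(name = ".sim_kernel")]]
List sim_kernel(std::string model, double L, double v, double kd, double kp,
                double kw, double ps, double pf, int S, double phi,
                double r_trans, int n_sites, double dt, int n_steps,
                bool fixed_M, int M_init, bool forbid_retro_fusion,
                bool random_placement, int record_stride, bool record_traj) {
  const bool is_ss = (model == "ss");
  const int n = n_sites;
  const double g = L / (n + 1);
  const double vdt = v * dt;
  const double inv_g = 1.0 / g;
  const double inv_d = std::exp(kd * dt);
  const double qw = (kw > 0) ? -std::expm1(-kw * dt) : 0.0;
  const double qp = (kp > 0) ? -std::expm1(-kp * dt) : 0.0;
  const int FAR = INT_MAX / 2;
  const bool stat_loop = (r_trans > 0.0);   // local translation path
  const double kddt = kd * dt;

  std::vector<double> site_x(n + 1);
  for (int j = 1; j <= n; ++j) site_x[j] = j * g;

  // moving agents (anterograde / retrograde / engulfed), contiguous SoA;
  // position is implicit: pos(s) = mx [+/-] vdt * (s - mref)
  std::vector<double> mx, mh;
  std::vector<int> mref, mnext, mtype, mevsite, mstate, mskip, mgid;

  // stationary agents
  std::vector<StatAgent> statv;
  std::vector<int> freelist;
  std::vector<int> stat_ids;                // used only when stat_loop
  statv.reserve(1024);

  std::priority_queue<Event, std::vector<Event>, EventCmp> evq;
  long seq = 0;
  int next_gid = 1;

  std::vector<std::vector<int> > res;       // SS resident registry per site
  std::vector<int> vac;
  if (is_ss) { res.assign(n + 1, std::vector<int>()); vac.assign(n + 1, 0); }

  double inv_G = 1.0;                       // exp(+kd t)
  double thresh = phi;                      // engulfment threshold, scaled

  auto engulf_after = [&](double h, int now) -> int {
    // first step t >= now with h * exp(-kd dt t) < phi
    if (phi <= 0.0 || kd <= 0.0) return FAR;
    if (h <= 0.0) return now;
    double t = std::log(h / phi) / kddt;
    int st = (t < 0) ? now : (int)std::floor(t) + 1;
    return st < now ? now : st;
  };

  // next motile event for agent i located at mx[i] at the end of step mref[i].
  // `target` is the next site index in the direction of travel (anterograde:
  // site to cross, n+1 = distal reflection; retrograde: site to cross, 0 =
  // somal exit; -1 = derive from the position). Passing the target
  // explicitly keeps the site chain exact even when an event lands a
  // position exactly on a site boundary in floating point.
  auto compute_next = [&](size_t i, int target) {
    double x = mx[i];
    int s0 = mref[i];
    int mstep; int mtp; int msite = 0;
    if (mstate[i] == ST_ENG) {
      mstep = s0 + (int)std::ceil(x / vdt); mtp = MV_EXIT;
    } else if (mstate[i] == ST_ANT) {
      if (target < 0) { int k = (int)(x * inv_g); if (k > n) k = n; target = k + 1; }
      if (target <= n) {
        mstep = s0 + (int)std::floor((site_x[target] - x) / vdt) + 1;
        mtp = MV_CROSS; msite = target;
      } else {
        mstep = s0 + (int)std::floor((L - x) / vdt) + 1;
        mtp = MV_REFLECT;
      }
    } else { // ST_RET
      if (target < 0) { int k = (int)(x * inv_g); if (k > n) k = n; target = k; }
      if (target >= 1) {
        mstep = s0 + (int)std::floor((x - site_x[target]) / vdt) + 1;
        mtp = MV_CROSS; msite = target;
      } else {
        mstep = s0 + (int)std::ceil(x / vdt);
        mtp = MV_EXIT;
      }
    }
    int es = engulf_after(mh[i], s0 + 1);
    if (es < mstep) { mstep = es; mtp = MV_ENGULF; }
    if (mstep <= s0) mstep = s0 + 1;  // events strictly advance
    mnext[i] = mstep; mtype[i] = mtp; mevsite[i] = msite;
  };

  auto push_motile = [&](double x, int state, double h, int skip, int gid,
                         int s, int target) {
    mx.push_back(x); mh.push_back(h); mref.push_back(s);
    mnext.push_back(0); mtype.push_back(0); mevsite.push_back(0);
    mstate.push_back(state); mskip.push_back(skip); mgid.push_back(gid);
    compute_next(mx.size() - 1, target);
  };

  auto drop_motile = [&](size_t i) {
    mx[i] = mx.back(); mx.pop_back();
    mh[i] = mh.back(); mh.pop_back();
    mref[i] = mref.back(); mref.pop_back();
    mnext[i] = mnext.back(); mnext.pop_back();
    mtype[i] = mtype.back(); mtype.pop_back();
    mevsite[i] = mevsite.back(); mevsite.pop_back();
    mstate[i] = mstate.back(); mstate.pop_back();
    mskip[i] = mskip.back(); mskip.pop_back();
    mgid[i] = mgid.back(); mgid.pop_back();
  };

  auto alloc_stat = [&](double h, int site, int slot, int gid) -> int {
    int idx;
    if (!freelist.empty()) {
      idx = freelist.back(); freelist.pop_back();
      ++statv[idx].version;
    } else {
      StatAgent a; a.version = 0;
      statv.push_back(a);
      idx = (int)statv.size() - 1;
    }
    StatAgent& a = statv[idx];
    a.h = h; a.site = site; a.slot = slot; a.gid = gid; a.alive = true;
    return idx;
  };

  auto free_stat = [&](int idx) {
    statv[idx].alive = false;
    ++statv[idx].version;
    freelist.push_back(idx);
  };

  auto schedule_stat = [&](int idx, int now) {
    StatAgent& a = statv[idx];
    int nw = FAR;
    if (!is_ss && kw > 0) nw = now + 1 + geom_steps(qw, n_steps + 1);
    int se = stat_loop ? FAR : engulf_after(a.h, now);
    int step = std::min(nw, se);
    if (step > n_steps) return;
    Event e; e.step = step; e.type = (nw <= se) ? EV_WAKE : EV_SENGULF;
    e.seq = seq++; e.idx = idx; e.version = a.version;
    evq.push(e);
  };

  // --- initial condition ---
  if (is_ss) {
    std::vector<int> per_site(n + 1, S);
    if (random_placement) {
      // distribute the n*S residents over the sites uniformly at random
      std::fill(per_site.begin(), per_site.end(), 0);
      for (int m = 0; m < n * S; ++m) {
        int j = 1 + (int)(R::unif_rand() * n);
        if (j > n) j = n;
        ++per_site[j];
      }
    }
    for (int j = 1; j <= n; ++j) {
      res[j].assign(per_site[j], -1);
      for (int k = 0; k < per_site[j]; ++k) {
        int idx = alloc_stat(1.0, j, k, next_gid++);
        res[j][k] = idx;
        if (stat_loop) stat_ids.push_back(idx);
        else schedule_stat(idx, 0);
      }
    }
  }
  if (fixed_M) {
    for (int m = 0; m < M_init; ++m) {
      double x = R::unif_rand() * L;
      int st = (R::unif_rand() < 0.5) ? ST_ANT : ST_RET;
      push_motile(x, st, 1.0, 0, next_gid++, 0, -1);
    }
  }
  int next_birth = fixed_M ? FAR : 1 + geom_steps(qp, n_steps + 1);

  // --- recording buffers ---
  int n_rec = (record_stride > 0) ? n_steps / record_stride : 0;
  NumericMatrix rec_health(n_rec, n);
  NumericMatrix rec_counts(n_rec, 5); // step, motile, stationary, engulfed, total
  std::vector<double> tr_step, tr_id, tr_x, tr_state, tr_health;
  int rec_row = 0;

  auto cur_pos = [&](size_t i, int s) -> double {
    double sgn = (mstate[i] == ST_ANT) ? 1.0 : -1.0;
    return mx[i] + sgn * vdt * (s - mref[i]);
  };

  auto record_frame = [&](int s, double G) {
    for (size_t i = 0; i < mx.size(); ++i) {
      tr_step.push_back(s); tr_id.push_back(mgid[i]);
      tr_x.push_back(cur_pos(i, s)); tr_state.push_back(mstate[i]);
      tr_health.push_back(mh[i] * G);
    }
    for (size_t i = 0; i < statv.size(); ++i) {
      if (!statv[i].alive) continue;
      tr_step.push_back(s); tr_id.push_back(statv[i].gid);
      tr_x.push_back(site_x[statv[i].site]); tr_state.push_back(ST_STAT);
      tr_health.push_back(statv[i].h * G);
    }
  };
  if (record_traj) record_frame(0, 1.0);

  // --- main loop ---
  for (int s = 1; s <= n_steps; ++s) {
    inv_G *= inv_d;
    if (phi > 0.0) thresh = phi * inv_G;

    // move / stop / fuse phase: only agents whose event falls on this step
    const size_t n_before = mx.size();  // agents pushed later this step start at s
    for (size_t i = 0; i < mx.size() && i < n_before;) {
      if (mnext[i] != s) { ++i; continue; }
      int tp = mtype[i];
      if (tp == MV_ENGULF) {
        mx[i] = cur_pos(i, s); mref[i] = s;
        mstate[i] = ST_ENG;
        compute_next(i, -1);
        ++i; continue;
      }
      if (tp == MV_EXIT) {
        if (fixed_M) {
          double np = cur_pos(i, s);       // <= 0
          mx[i] = -np; mref[i] = s; mstate[i] = ST_ANT; mh[i] = inv_G; mskip[i] = 0;
          compute_next(i, 1);
          ++i; continue;
        }
        drop_motile(i);
        continue;                          // re-examine swapped-in agent
      }
      if (tp == MV_REFLECT) {
        double np = cur_pos(i, s);         // >= L - vdt
        mx[i] = 2.0 * L - np; mref[i] = s; mstate[i] = ST_RET;
        if (phi > 0.0 && mh[i] < thresh) mstate[i] = ST_ENG;
        compute_next(i, n);
        ++i; continue;
      }
      // MV_CROSS
      int j = mevsite[i];
      double np = cur_pos(i, s);
      bool stopped = false;
      if (mskip[i] == j) {
        mskip[i] = 0;
      } else {
        mskip[i] = 0;
        if (!is_ss) {
          if (ps > 0 && R::unif_rand() < ps) {
            int idx = alloc_stat(mh[i], j, -1, mgid[i]);
            if (stat_loop) stat_ids.push_back(idx);
            else schedule_stat(idx, s);
            drop_motile(i);
            stopped = true;
          }
        } else {
          if (vac[j] > 0) {
            int slot = 0; while (res[j][slot] != -1) ++slot;
            int idx = alloc_stat(mh[i], j, slot, mgid[i]);
            res[j][slot] = idx; --vac[j];
            if (stat_loop) stat_ids.push_back(idx);
            else schedule_stat(idx, s);
            drop_motile(i);
            stopped = true;
          } else if (pf > 0 && !(forbid_retro_fusion && mstate[i] == ST_RET)) {
            const int Sj = (int)res[j].size();
            if (mstate[i] == ST_ANT) {     // proximal slot first
              int cur = 0;
              while (cur < Sj) {
                cur += geom_steps(pf, Sj);
                if (cur >= Sj) break;
                StatAgent& rmt = statv[res[j][cur]];
                double avg = 0.5 * (mh[i] + rmt.h);
                mh[i] = avg; rmt.h = avg; ++rmt.version;
                if (!stat_loop) schedule_stat(res[j][cur], s);
                ++cur;
              }
            } else {                        // distal slot first
              int cur = Sj - 1;
              while (cur >= 0) {
                cur -= geom_steps(pf, Sj);
                if (cur < 0) break;
                StatAgent& rmt = statv[res[j][cur]];
                double avg = 0.5 * (mh[i] + rmt.h);
                mh[i] = avg; rmt.h = avg; ++rmt.version;
                if (!stat_loop) schedule_stat(res[j][cur], s);
                --cur;
              }
            }
          }
        }
      }
      if (stopped) continue;
      mx[i] = np; mref[i] = s;
      if (phi > 0.0 && mh[i] < thresh) mstate[i] = ST_ENG;
      compute_next(i, (mstate[i] == ST_ANT) ? j + 1 : j - 1);
      ++i;
    }

    // restart / stationary-engulfment events
    while (!evq.empty() && evq.top().step == s) {
      Event e = evq.top(); evq.pop();
      if (e.idx >= (int)statv.size()) continue;
      StatAgent& a = statv[e.idx];
      if (!a.alive || a.version != e.version) continue;
      if (e.type == EV_WAKE) {
        int dir = (R::unif_rand() < 0.5) ? ST_ANT : ST_RET;
        if (phi > 0.0 && a.h < thresh) dir = ST_ENG;  // engulf phase of this step
        // a restarted mitochondrion is not re-evaluated at its own site
        int target = (dir == ST_ANT) ? a.site + 1 : a.site - 1;
        push_motile(site_x[a.site], dir, a.h, 0, a.gid, s, target);
        free_stat(e.idx);
      } else {
        if (is_ss && a.slot >= 0) { res[a.site][a.slot] = -1; ++vac[a.site]; }
        push_motile(site_x[a.site], ST_ENG, a.h, 0, a.gid, s, -1);
        free_stat(e.idx);
      }
    }

    // local translation increments + explicit engulfment scan
    if (stat_loop) {
      double add = r_trans * dt * inv_G;
      for (size_t k = 0; k < stat_ids.size();) {
        int idx = stat_ids[k];
        StatAgent& a = statv[idx];
        if (!a.alive) { stat_ids[k] = stat_ids.back(); stat_ids.pop_back(); continue; }
        a.h += add;
        if (phi > 0.0 && a.h < thresh) {
          if (is_ss && a.slot >= 0) { res[a.site][a.slot] = -1; ++vac[a.site]; }
          push_motile(site_x[a.site], ST_ENG, a.h, 0, a.gid, s, -1);
          free_stat(idx);
          stat_ids[k] = stat_ids.back(); stat_ids.pop_back(); continue;
        }
        ++k;
      }
    }

    // production
    if (s == next_birth) {
      push_motile(0.0, ST_ANT, inv_G, 0, next_gid++, s, 1);
      next_birth = s + 1 + geom_steps(qp, n_steps + 1);
    }

    // recording
    if (record_stride > 0 && s % record_stride == 0) {
      double G = 1.0 / inv_G;
      std::vector<double> sh(n + 1, 0.0);
      int c_stat = 0, c_eng = 0, c_mot = 0;
      for (size_t i = 0; i < statv.size(); ++i)
        if (statv[i].alive) { sh[statv[i].site] += statv[i].h * G; ++c_stat; }
      for (size_t i = 0; i < mx.size(); ++i)
        if (mstate[i] == ST_ENG) ++c_eng; else ++c_mot;
      for (int j = 1; j <= n; ++j) rec_health(rec_row, j - 1) = sh[j];
      rec_counts(rec_row, 0) = s; rec_counts(rec_row, 1) = c_mot;
      rec_counts(rec_row, 2) = c_stat; rec_counts(rec_row, 3) = c_eng;
      rec_counts(rec_row, 4) = c_mot + c_stat + c_eng;
      ++rec_row;
      if (record_traj) record_frame(s, G);
    }
  }

  // --- final snapshot ---
  double G = 1.0 / inv_G;
  NumericVector site_health(n), site_count(n);
  int c_ant = 0, c_ret = 0, c_stat = 0, c_eng = 0;
  for (size_t i = 0; i < statv.size(); ++i) {
    if (!statv[i].alive) continue;
    ++c_stat;
    site_health[statv[i].site - 1] += statv[i].h * G;
    site_count[statv[i].site - 1] += 1;
  }
  for (size_t i = 0; i < mx.size(); ++i) {
    if (mstate[i] == ST_ENG) ++c_eng;
    else if (mstate[i] == ST_ANT) ++c_ant;
    else ++c_ret;
  }

  List out = List::create(
    _["site_health"] = site_health,
    _["site_count"] = site_count,
    _["n_anterograde"] = c_ant,
    _["n_retrograde"] = c_ret,
    _["n_stationary"] = c_stat,
    _["n_engulfed"] = c_eng,
    _["M_final"] = c_ant + c_ret + c_stat + c_eng);
  if (record_stride > 0) {
    out["rec_site_health"] = rec_health;
    out["rec_counts"] = rec_counts;
  }
  if (record_traj) {
    out["trajectory"] = DataFrame::create(
      _["step"] = tr_step, _["id"] = tr_id, _["x"] = tr_x,
      _["state"] = tr_state, _["health"] = tr_health);
  }
  return out;
}
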