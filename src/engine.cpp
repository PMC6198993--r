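// Discrete-time engines for the narrow (1-D) and wide (2-D) trail models.
// All randomness goes through R's RNG (via Rcpp's RNGScope), so a set.seed()
// at the R level makes whole runs bit-reproducible.
//
// Arrival semantics: `mu_step` is the Poisson mean per endpoint per time
// step (the R wrapper converts the user-facing rate). On the narrow trail
// spawned particles step onto the trail immediately; on the wide trail they
// wait in a FIFO queue until the entry point is clear of same-direction
// particles they would have to give way to.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cmath>

using namespace Rcpp;

namespace {

const int T_O = 0, T_U = 1, T_L = 2;
const int S_MOVING = 0, S_STOPPED = 1, S_YIELDING = 2, S_TURNING = 3;

// GIVES[actor][other] == 1 when the actor gives way (stops / turns) on
// encountering the other; 0 means it keeps walking. Priority order L > O > U.
const int GIVES[3][3] = {
  // other:  O  U  L
  /* O */ { 1, 0, 1 },
  /* U */ { 1, 1, 1 },
  /* L */ { 0, 0, 1 }
};

inline int heading_of(int type) { return type == T_O ? 1 : -1; }

// inverse-CDF draw from the cooperative-passage distribution over n = 0..15
inline int sample_coop(const std::vector<double>& cum) {
  double u = R::unif_rand();
  for (size_t k = 0; k < cum.size(); ++k)
    if (u <= cum[k]) return static_cast<int>(k);
  return static_cast<int>(cum.size()) - 1;
}

struct EntryQueue {
  std::vector<int> id;
  std::vector<int> type;
  std::vector<double> w;
  size_t head = 0;
  size_t size() const { return id.size() - head; }
  bool empty() const { return head >= id.size(); }
};

struct Crossings {
  std::vector<double> time;
  std::vector<int> id;
  std::vector<int> type;
  std::vector<int> dir;
  std::vector<double> w;
  bool has_w = false;
  void add(double t, int i, int ty, int h, double wv = NA_REAL) {
    time.push_back(t); id.push_back(i); type.push_back(ty); dir.push_back(h);
    if (has_w) w.push_back(wv);
  }
};

struct Trajectory {
  std::vector<double> time;
  std::vector<int> id;
  std::vector<int> type;
  std::vector<double> x;
  std::vector<double> w;
  std::vector<int> state;
  std::vector<int> moved;
  bool has_w = false;
};

CharacterVector type_labels(const std::vector<int>& t) {
  CharacterVector out(t.size());
  for (size_t i = 0; i < t.size(); ++i)
    out[i] = (t[i] == T_O) ? "O" : (t[i] == T_U) ? "U" : "L";
  return out;
}

} // namespace

// [[Rcpp::export]]
List narrow_engine_cpp(List cfg, DataFrame init, int n_steps, bool record_traj) {
  const double trail_length = as<double>(cfg["trail_length"]);
  const double dt = as<double>(cfg["dt"]);
  const double mu_step = as<double>(cfg["mu_step"]);
  const double p_laden = as<double>(cfg["p_laden"]);
  const double s_OU = as<double>(cfg["s_OU"]);
  const double s_L = as<double>(cfg["s_L"]);
  const double radius = as<double>(cfg["interaction_radius"]);
  const double coop_time = as<double>(cfg["coop_time_per_passer"]);
  NumericVector coop = as<NumericVector>(cfg["coop_dist"]);
  std::vector<double> coop_cum(coop.size());
  std::partial_sum(coop.begin(), coop.end(), coop_cum.begin());

  const double mid = trail_length / 2.0;
  const double eps = 1e-9;

  // particle state (parallel vectors)
  std::vector<int> pid, ptype, pstate, pytrig;
  std::vector<double> px, pyuntil, ptentry;

  int next_id = 0;
  std::vector<long> spawned(3, 0), exited(3, 0);

  {
    IntegerVector iid = init["id"], ity = init["type"], ist = init["state"],
      iyt = init["yield_trigger"];
    NumericVector ix = init["x"], iyu = init["yield_until"], ite = init["t_entry"];
    for (int i = 0; i < init.nrows(); ++i) {
      pid.push_back(iid[i]); ptype.push_back(ity[i]); pstate.push_back(ist[i]);
      pytrig.push_back(iyt[i]); px.push_back(ix[i]); pyuntil.push_back(iyu[i]);
      ptentry.push_back(ite[i]);
      spawned[ity[i]]++;
      if (iid[i] >= next_id) next_id = iid[i] + 1;
    }
  }

  Crossings cross;
  Trajectory traj;

  // per-step spawn buffer (placed on the trail at the end of the step)
  std::vector<int> buf_id, buf_type;

  RNGScope rngscope;

  for (int step = 1; step <= n_steps; ++step) {
    const double t0 = (step - 1) * dt;
    const double t1 = step * dt;
    const size_t n = pid.size();

    // Poisson arrivals (nest first, then leaf source)
    buf_id.clear(); buf_type.clear();
    int kn = static_cast<int>(R::rpois(mu_step));
    for (int k = 0; k < kn; ++k) {
      buf_id.push_back(next_id++); buf_type.push_back(T_O);
      spawned[T_O]++;
    }
    int ks = static_cast<int>(R::rpois(mu_step));
    for (int k = 0; k < ks; ++k) {
      int ty = (R::unif_rand() < p_laden) ? T_L : T_U;
      buf_id.push_back(next_id++); buf_type.push_back(ty);
      spawned[ty]++;
    }

    // expired yields revert to MOVING (the same laden particle cannot
    // re-trigger a fresh yield; pytrig remembers it)
    for (size_t i = 0; i < n; ++i)
      if (pstate[i] == S_YIELDING && t0 >= pyuntil[i] - eps)
        pstate[i] = S_MOVING;

    // start-of-step snapshot for synchronous decisions
    std::vector<int> st0(pstate);

    // sort particles by x for neighbour scans
    std::vector<int> order(n);
    std::iota(order.begin(), order.end(), 0);
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return px[a] < px[b]; });
    std::vector<int> rank(n);
    for (size_t q = 0; q < n; ++q) rank[order[q]] = q;

    std::vector<char> delta(n, 0);

    for (size_t i = 0; i < n; ++i) {
      if (st0[i] == S_YIELDING) { delta[i] = 0; continue; }
      const int h = heading_of(ptype[i]);

      // governing particle: nearest ahead within the interaction radius,
      // inbound actors treating yielding outbound particles as transparent
      int gov = -1;
      double best = 0.0;
      const int dir = (h > 0) ? 1 : -1;
      for (int q = rank[i] + dir; q >= 0 && q < static_cast<int>(n); q += dir) {
        const int j = order[q];
        const double dx = (px[j] - px[i]) * h;
        if (dx > radius + eps) break;
        if (dx <= 0.0) continue;
        if (ptype[i] != T_O && ptype[j] == T_O && st0[j] == S_YIELDING)
          continue;
        if (gov < 0 || dx < best - eps) { gov = j; best = dx; }
        else if (dx <= best + eps && pid[j] < pid[gov]) gov = j;
      }

      if (gov < 0 || !GIVES[ptype[i]][ptype[gov]]) {
        delta[i] = 1; pstate[i] = S_MOVING; continue;
      }

      if (ptype[i] == T_O && ptype[gov] == T_L) {
        // cooperative rule: step aside for tau = coop_time * n seconds
        if (pytrig[i] == pid[gov]) {
          pstate[i] = S_STOPPED;        // same L: plain stop, no new timer
        } else {
          int nu = sample_coop(coop_cum);
          pyuntil[i] = t0 + coop_time * nu;
          pytrig[i] = pid[gov];
          pstate[i] = S_YIELDING;
        }
      } else {
        pstate[i] = S_STOPPED;
      }
      delta[i] = 0;
    }

    // synchronous move + midpoint-crossing detection
    for (size_t i = 0; i < n; ++i) {
      if (!delta[i]) continue;
      const int h = heading_of(ptype[i]);
      const double s = (ptype[i] == T_L) ? s_L : s_OU;
      const double xb = px[i];
      px[i] += s * h * dt;
      if ((xb - mid) * (px[i] - mid) < 0.0 || px[i] == mid)
        cross.add(t1, pid[i], ptype[i], h);
    }

    if (record_traj) {
      for (size_t i = 0; i < n; ++i) {
        traj.time.push_back(t1); traj.id.push_back(pid[i]);
        traj.type.push_back(ptype[i]); traj.x.push_back(px[i]);
        traj.state.push_back(pstate[i]); traj.moved.push_back(delta[i]);
      }
    }

    // remove particles that reached the far end
    {
      size_t keep = 0;
      for (size_t i = 0; i < pid.size(); ++i) {
        const int h = heading_of(ptype[i]);
        if ((h < 0 && px[i] <= 0.0) || (h > 0 && px[i] >= trail_length)) {
          exited[ptype[i]]++;
          continue;
        }
        pid[keep] = pid[i]; ptype[keep] = ptype[i]; pstate[keep] = pstate[i];
        pytrig[keep] = pytrig[i]; px[keep] = px[i]; pyuntil[keep] = pyuntil[i];
        ptentry[keep] = ptentry[i];
        keep++;
      }
      pid.resize(keep); ptype.resize(keep); pstate.resize(keep);
      pytrig.resize(keep); px.resize(keep); pyuntil.resize(keep);
      ptentry.resize(keep);
    }

    // this step's arrivals step onto the trail at their endpoint
    for (size_t k = 0; k < buf_id.size(); ++k) {
      const bool outbound = buf_type[k] == T_O;
      pid.push_back(buf_id[k]); ptype.push_back(buf_type[k]);
      pstate.push_back(S_MOVING); pytrig.push_back(-1);
      px.push_back(outbound ? 0.0 : trail_length);
      pyuntil.push_back(-1.0); ptentry.push_back(t1);
    }
  }

  std::vector<long> on_trail(3, 0);
  for (size_t i = 0; i < pid.size(); ++i) on_trail[ptype[i]]++;

  IntegerVector dirv(cross.dir.begin(), cross.dir.end());
  List out = List::create(
    _["crossings"] = DataFrame::create(
      _["time_s"] = cross.time,
      _["particle_id"] = cross.id,
      _["type"] = type_labels(cross.type),
      _["direction"] = dirv,
      _["stringsAsFactors"] = false),
    _["particles"] = DataFrame::create(
      _["id"] = pid, _["type"] = type_labels(ptype), _["x"] = px,
      _["state"] = pstate, _["yield_until"] = pyuntil,
      _["yield_trigger"] = pytrig, _["t_entry"] = ptentry,
      _["stringsAsFactors"] = false),
    _["spawned"] = NumericVector::create(spawned[0], spawned[1], spawned[2]),
    _["exited"] = NumericVector::create(exited[0], exited[1], exited[2]),
    _["queued"] = NumericVector::create(0.0, 0.0, 0.0),
    _["on_trail"] = NumericVector::create(on_trail[0], on_trail[1], on_trail[2]),
    _["queue_nest"] = 0.0,
    _["queue_source"] = 0.0);
  if (record_traj) {
    out["trajectory"] = DataFrame::create(
      _["time_s"] = traj.time, _["particle_id"] = traj.id,
      _["type"] = type_labels(traj.type), _["x"] = traj.x,
      _["state"] = traj.state, _["moved"] = traj.moved,
      _["stringsAsFactors"] = false);
  }
  return out;
}

// [[Rcpp::export]]
List wide_engine_cpp(List cfg, DataFrame init, int n_steps, bool record_traj) {
  const double trail_length = as<double>(cfg["trail_length"]);
  const double trail_width = as<double>(cfg["trail_width"]);
  const double dt = as<double>(cfg["dt"]);
  const double mu_step = as<double>(cfg["mu_step"]);
  const double p_laden = as<double>(cfg["p_laden"]);
  const double s_OU = as<double>(cfg["s_OU"]);
  const double s_L = as<double>(cfg["s_L"]);
  const double radius = as<double>(cfg["interaction_radius"]);
  const double entry_mean = as<double>(cfg["entry_w_mean"]);
  const double entry_sd = as<double>(cfg["entry_w_sd"]);
  const double clamp_lo = as<double>(cfg["entry_w_clamp_lo"]);
  const double clamp_hi = as<double>(cfg["entry_w_clamp_hi"]);
  const bool stop_rule = as<std::string>(cfg["avoidance_rule"]) == "stop";

  const double mid = trail_length / 2.0;
  const double r2 = radius * radius;
  const double eps = 1e-9;

  std::vector<int> pid, ptype, pstate;
  std::vector<double> px, pw, ptentry;

  int next_id = 0;
  std::vector<long> spawned(3, 0), exited(3, 0);

  {
    IntegerVector iid = init["id"], ity = init["type"], ist = init["state"];
    NumericVector ix = init["x"], iw = init["w"], ite = init["t_entry"];
    for (int i = 0; i < init.nrows(); ++i) {
      pid.push_back(iid[i]); ptype.push_back(ity[i]); pstate.push_back(ist[i]);
      px.push_back(ix[i]); pw.push_back(iw[i]); ptentry.push_back(ite[i]);
      spawned[ity[i]]++;
      if (iid[i] >= next_id) next_id = iid[i] + 1;
    }
  }

  EntryQueue nestq, srcq;
  Crossings cross; cross.has_w = true;
  Trajectory traj; traj.has_w = true;

  RNGScope rngscope;

  auto draw_entry_w = [&]() {
    double wv = entry_mean + entry_sd * R::norm_rand();
    if (wv > trail_width) wv = clamp_hi;
    else if (wv < 0.0) wv = clamp_lo;
    return wv;
  };

  for (int step = 1; step <= n_steps; ++step) {
    const double t1 = step * dt;
    const size_t n = pid.size();

    int kn = static_cast<int>(R::rpois(mu_step));
    for (int k = 0; k < kn; ++k) {
      nestq.id.push_back(next_id); nestq.type.push_back(T_O);
      nestq.w.push_back(draw_entry_w());
      spawned[T_O]++; next_id++;
    }
    int ks = static_cast<int>(R::rpois(mu_step));
    for (int k = 0; k < ks; ++k) {
      int ty = (R::unif_rand() < p_laden) ? T_L : T_U;
      srcq.id.push_back(next_id); srcq.type.push_back(ty);
      srcq.w.push_back(draw_entry_w());
      spawned[ty]++; next_id++;
    }

    std::vector<int> order(n);
    std::iota(order.begin(), order.end(), 0);
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return px[a] < px[b]; });
    std::vector<int> rank(n);
    for (size_t q = 0; q < n; ++q) rank[order[q]] = q;

    // action per particle: 0 walk, 1 stop, +2 turn up, -2 turn down
    std::vector<int> act(n, 0);
    std::vector<double> w0(pw);  // snapshot of lateral positions

    for (size_t i = 0; i < n; ++i) {
      const int h = heading_of(ptype[i]);
      int gov = -1;
      double best = 0.0;
      const int dir = (h > 0) ? 1 : -1;
      for (int q = rank[i] + dir; q >= 0 && q < static_cast<int>(n); q += dir) {
        const int j = order[q];
        const double dx = (px[j] - px[i]) * h;
        if (dx > radius + eps) break;
        if (dx <= 0.0) continue;
        const double dw = w0[j] - w0[i];
        const double d2 = dx * dx + dw * dw;
        if (d2 > r2 + eps) continue;
        if (gov < 0 || d2 < best - eps) { gov = j; best = d2; }
        else if (d2 <= best + eps && pid[j] < pid[gov]) gov = j;
      }

      if (gov < 0 || !GIVES[ptype[i]][ptype[gov]]) {
        act[i] = 0; pstate[i] = S_MOVING; continue;
      }
      if (stop_rule) { act[i] = 1; pstate[i] = S_STOPPED; continue; }

      // turning angle theta_I = +pi/2 when w_i < w_j (else -pi/2), applied
      // through the heading decomposition theta = theta_d + theta_I: the
      // lateral step is s*sin(theta)*dt, which sends an outbound avoider
      // toward the governor's side and an inbound avoider away from it
      int sign;
      if (w0[i] == w0[gov] && ptype[i] == ptype[gov])
        sign = (pid[i] < pid[gov]) ? 1 : -1;  // break same-type lockstep
      else
        sign = (w0[i] >= w0[gov]) ? 1 : -1;
      if (h > 0) sign = -sign;
      // a turn fully blocked by a wall cannot be executed: walk instead
      if ((sign > 0 && w0[i] >= trail_width) || (sign < 0 && w0[i] <= 0.0)) {
        act[i] = 0; pstate[i] = S_MOVING; continue;
      }
      act[i] = 2 * sign;
      pstate[i] = S_TURNING;
    }

    for (size_t i = 0; i < n; ++i) {
      const int h = heading_of(ptype[i]);
      const double s = (ptype[i] == T_L) ? s_L : s_OU;
      if (act[i] == 0) {
        const double xb = px[i];
        px[i] += s * h * dt;
        if ((xb - mid) * (px[i] - mid) < 0.0 || px[i] == mid)
          cross.add(t1, pid[i], ptype[i], h, pw[i]);
      } else if (act[i] == 2 || act[i] == -2) {
        pw[i] += (act[i] > 0 ? 1.0 : -1.0) * s * dt;
        if (pw[i] > trail_width) pw[i] = trail_width;
        if (pw[i] < 0.0) pw[i] = 0.0;
      }
    }

    if (record_traj) {
      for (size_t i = 0; i < n; ++i) {
        traj.time.push_back(t1); traj.id.push_back(pid[i]);
        traj.type.push_back(ptype[i]); traj.x.push_back(px[i]);
        traj.w.push_back(pw[i]); traj.state.push_back(pstate[i]);
        traj.moved.push_back(act[i] == 0 ? 1 : 0);
      }
    }

    {
      size_t keep = 0;
      for (size_t i = 0; i < pid.size(); ++i) {
        const int h = heading_of(ptype[i]);
        if ((h < 0 && px[i] <= 0.0) || (h > 0 && px[i] >= trail_length)) {
          exited[ptype[i]]++;
          continue;
        }
        pid[keep] = pid[i]; ptype[keep] = ptype[i]; pstate[keep] = pstate[i];
        px[keep] = px[i]; pw[keep] = pw[i]; ptentry[keep] = ptentry[i];
        keep++;
      }
      pid.resize(keep); ptype.resize(keep); pstate.resize(keep);
      px.resize(keep); pw.resize(keep); ptentry.resize(keep);
    }

    // entry queues: the front enters when no same-direction particle it
    // would give way to sits within the interaction radius of its entry
    // position (oncoming particles there are leaving and do not occupy it)
    auto entry_blocked = [&](double ex, int h, int etype, double ew) {
      for (size_t j = 0; j < pid.size(); ++j) {
        if (heading_of(ptype[j]) != h) continue;
        const double dx = (px[j] - ex) * h;
        if (dx < 0.0 || dx > radius + eps) continue;
        const double dw = pw[j] - ew;
        if (dx * dx + dw * dw > r2 + eps) continue;
        if (GIVES[etype][ptype[j]]) return true;
      }
      return false;
    };

    while (!nestq.empty()) {
      if (entry_blocked(0.0, 1, T_O, nestq.w[nestq.head])) break;
      pid.push_back(nestq.id[nestq.head]); ptype.push_back(T_O);
      pstate.push_back(S_MOVING); px.push_back(0.0);
      pw.push_back(nestq.w[nestq.head]); ptentry.push_back(t1);
      nestq.head++;
    }
    while (!srcq.empty()) {
      const int etype = srcq.type[srcq.head];
      if (entry_blocked(trail_length, -1, etype, srcq.w[srcq.head])) break;
      pid.push_back(srcq.id[srcq.head]); ptype.push_back(etype);
      pstate.push_back(S_MOVING); px.push_back(trail_length);
      pw.push_back(srcq.w[srcq.head]); ptentry.push_back(t1);
      srcq.head++;
    }
  }

  std::vector<long> queued(3, 0), on_trail(3, 0);
  for (size_t k = nestq.head; k < nestq.id.size(); ++k) queued[nestq.type[k]]++;
  for (size_t k = srcq.head; k < srcq.id.size(); ++k) queued[srcq.type[k]]++;
  for (size_t i = 0; i < pid.size(); ++i) on_trail[ptype[i]]++;

  IntegerVector dirv(cross.dir.begin(), cross.dir.end());
  List out = List::create(
    _["crossings"] = DataFrame::create(
      _["time_s"] = cross.time,
      _["particle_id"] = cross.id,
      _["type"] = type_labels(cross.type),
      _["direction"] = dirv,
      _["w_cm"] = cross.w,
      _["stringsAsFactors"] = false),
    _["particles"] = DataFrame::create(
      _["id"] = pid, _["type"] = type_labels(ptype), _["x"] = px,
      _["w"] = pw, _["state"] = pstate, _["t_entry"] = ptentry,
      _["stringsAsFactors"] = false),
    _["spawned"] = NumericVector::create(spawned[0], spawned[1], spawned[2]),
    _["exited"] = NumericVector::create(exited[0], exited[1], exited[2]),
    _["queued"] = NumericVector::create(queued[0], queued[1], queued[2]),
    _["on_trail"] = NumericVector::create(on_trail[0], on_trail[1], on_trail[2]),
    _["queue_nest"] = static_cast<double>(nestq.size()),
    _["queue_source"] = static_cast<double>(srcq.size()));
  if (record_traj) {
    out["trajectory"] = DataFrame::create(
      _["time_s"] = traj.time, _["particle_id"] = traj.id,
      _["type"] = type_labels(traj.type), _["x"] = traj.x,
      _["w"] = traj.w, _["state"] = traj.state, _["moved"] = traj.moved,
      _["stringsAsFactors"] = false);
  }
  return out;
}
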