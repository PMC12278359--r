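// Tick-based closed-loop engine: Markov SN spike generators, IFU network
// with difference-of-exponentials synapses, spike-triggered stimulation
// with per-IFU delays, stimulation-response model (evoked + rebound), and
// 1 ms stimulation artifacts with staggering and obstruction marking.
//
// Time is integer ticks (default 0.1 ms, 10 kHz). Event ordering within a
// tick: deliver stimuli -> emit SN spikes -> obstruction marking -> IFU
// update (arrivals are the previous tick's visible spikes: one-tick
// conduction delay).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

const long long NEVER = std::numeric_limits<long long>::max();

inline int sample_index(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct MarkovChain {
  std::vector<int> keys;        // sorted unique ISI1 (ms)
  std::vector<int> off;         // size keys+1, offsets into succ
  std::vector<int> succ;        // concatenated successor multisets
  std::vector<int> obs;         // all ISI1 observations (seed pool)

  // nearest stored key, ties toward the smaller key
  int key_index(int ctx) const {
    size_t lo = std::lower_bound(keys.begin(), keys.end(), ctx) - keys.begin();
    if (lo == 0) return 0;
    if (lo >= keys.size()) return static_cast<int>(keys.size()) - 1;
    if (keys[lo] == ctx) return static_cast<int>(lo);
    int d_lo = ctx - keys[lo - 1], d_hi = keys[lo] - ctx;
    return d_lo <= d_hi ? static_cast<int>(lo) - 1 : static_cast<int>(lo);
  }
  int draw(int ctx) const {
    int k = key_index(ctx);
    return succ[off[k] + sample_index(off[k + 1] - off[k])];
  }
  int seed() const { return obs[sample_index(static_cast<int>(obs.size()))]; }
};

struct Library {
  std::vector<double> p;        // p_evoke at dt_prev = 1..100 ms
  double plateau;
  std::vector<double> latency;  // ms
  std::vector<double> rebound;  // ms
  bool present = false;

  double prob(long long dt_ms) const {
    if (dt_ms > 100) return plateau;
    long long d = dt_ms < 1 ? 1 : dt_ms;
    return p[static_cast<size_t>(d) - 1];
  }
};

struct Synapse {
  int src;      // 0-based SN or IFU index
  int dst;      // 0-based IFU index
  bool from_sn;
  double c_slow, c_fast, inc;
  double S = 0.0, F = 0.0;
};

struct PendingStim {
  long long due, orig;
  int target, source_ifu, ifu_spike_id;
  long long seq;
};
struct StimLater {
  bool operator()(const PendingStim& a, const PendingStim& b) const {
    return a.due != b.due ? a.due > b.due : a.seq > b.seq;
  }
};

struct Arrival {
  int src;      // SN or IFU index
  bool from_sn;
  int spike_id; // SN spike id or IFU spike id
};

} // namespace

// [[Rcpp::export(name = ".cl_engine")]]
List cl_engine(List net, List markov, List libs, List cfg) {
  const int n_sn = as<int>(net["n_sn"]);
  const int n_ifu = as<int>(net["n_ifu"]);
  NumericMatrix W = net["W"];
  NumericVector thresholds = net["thresholds"];
  IntegerVector stim_delay_ticks = net["stim_delay_ticks"]; // -1 = hidden
  IntegerVector stim_target = net["stim_target"];           // 0-based, -1
  NumericVector kern_exc = net["kern_exc"]; // c_slow, c_fast, gain
  NumericVector kern_inh = net["kern_inh"];

  const double tick_ms = as<double>(cfg["tick_ms"]);
  const long long n_ticks =
    static_cast<long long>(std::llround(as<double>(cfg["duration_ms"]) / tick_ms));
  const long long artifact_ticks = as<int>(cfg["artifact_ticks"]);
  const bool evoke_on = as<bool>(cfg["evoke_enabled"]);
  const bool inhibit_on = as<bool>(cfg["inhibit_enabled"]);
  const bool artifacts_on = as<bool>(cfg["artifacts_enabled"]);
  const bool obstructed_resets = as<bool>(cfg["obstructed_resets_dtprev"]);
  const bool evoked_exempt = as<bool>(cfg["evoked_exempt"]);
  const double ticks_per_ms = 1.0 / tick_ms;

  // ---- synapses -----------------------------------------------------------
  std::vector<Synapse> syn;
  auto add_syn = [&](int src, int dst, double w, bool from_sn) {
    if (w == 0.0) return;
    const NumericVector& kk = (w > 0) ? kern_exc : kern_inh;
    Synapse s;
    s.src = src; s.dst = dst; s.from_sn = from_sn;
    s.c_slow = kk[0]; s.c_fast = kk[1];
    s.inc = w * thresholds[dst] / kk[2];
    syn.push_back(s);
  };
  for (int i = 0; i < n_sn; ++i)
    for (int j = 0; j < n_ifu; ++j) add_syn(i, j, W(i, j), true);
  if (!Rf_isNull(net["Wh"])) {
    NumericMatrix Wh = net["Wh"];
    for (int m = 0; m < n_ifu; ++m)
      for (int j = 0; j < n_ifu; ++j) add_syn(m, j, Wh(m, j), false);
  }
  const int n_syn = static_cast<int>(syn.size());
  double c_slow_max = 0.0;
  for (const Synapse& s : syn) c_slow_max = std::max(c_slow_max, s.c_slow);

  // index synapses by source and by destination
  std::vector<std::vector<int>> syn_by_sn(n_sn), syn_by_ifu_src(n_ifu),
      syn_by_dst(n_ifu);
  for (int s = 0; s < n_syn; ++s) {
    if (syn[s].from_sn) syn_by_sn[syn[s].src].push_back(s);
    else syn_by_ifu_src[syn[s].src].push_back(s);
    syn_by_dst[syn[s].dst].push_back(s);
  }

  // ---- per-SN models ------------------------------------------------------
  std::vector<MarkovChain> chains(n_sn);
  for (int k = 0; k < n_sn; ++k) {
    List mk = markov[k];
    chains[k].keys = as<std::vector<int>>(mk["keys"]);
    chains[k].off = as<std::vector<int>>(mk["off"]);
    chains[k].succ = as<std::vector<int>>(mk["succ"]);
    chains[k].obs = as<std::vector<int>>(mk["obs"]);
  }
  std::vector<Library> lib(n_sn);
  for (int k = 0; k < n_sn; ++k) {
    if (Rf_isNull(libs[k])) continue;
    List lk = libs[k];
    lib[k].p = as<std::vector<double>>(lk["p"]);
    lib[k].plateau = as<double>(lk["plateau"]);
    lib[k].latency = as<std::vector<double>>(lk["latency"]);
    lib[k].rebound = as<std::vector<double>>(lk["rebound"]);
    lib[k].present = true;
  }

  // ---- state --------------------------------------------------------------
  std::vector<long long> next_spont(n_sn), last_spike(n_sn, -1);
  std::vector<int> ctx(n_sn);
  for (int k = 0; k < n_sn; ++k) {
    int seed = chains[k].seed();
    ctx[k] = seed;
    next_spont[k] = static_cast<long long>(std::llround(seed * ticks_per_ms));
  }
  std::vector<std::vector<std::pair<long long, int>>> pending_evoked(n_sn);
  std::vector<long long> pending_rebound(n_sn, NEVER);
  std::vector<int> rebound_stim(n_sn, NA_INTEGER);

  std::priority_queue<PendingStim, std::vector<PendingStim>, StimLater> stim_q;
  long long stim_seq = 0;
  long long last_deliv_tick = -(artifact_ticks + 1);
  int last_deliv_id = -1, last_deliv_target = -1;

  std::vector<int> trig_id[2], trig_kind[2];
  for (int h = 0; h < 2; ++h) {
    trig_id[h].assign(n_ifu, NA_INTEGER);
    trig_kind[h].assign(n_ifu, NA_INTEGER);
  }
  auto push_trig = [&](int j, int id, int kind) {
    trig_id[0][j] = trig_id[1][j]; trig_kind[0][j] = trig_kind[1][j];
    trig_id[1][j] = id; trig_kind[1][j] = kind;
  };
  auto clear_trig = [&](int j) {
    trig_id[0][j] = trig_id[1][j] = NA_INTEGER;
    trig_kind[0][j] = trig_kind[1][j] = NA_INTEGER;
  };

  std::vector<Arrival> arrivals_now, arrivals_next;
  double energy = 0.0; // upper bound on total trace magnitude (skip quiet ticks)

  // ---- event storage ------------------------------------------------------
  std::vector<double> sp_time; std::vector<int> sp_sn, sp_label, sp_stim;
  std::vector<int> sp_obstructed; // logical
  std::vector<double> st_time, st_sched; std::vector<int> st_target,
      st_source, st_ifu_spike;
  std::vector<double> if_time; std::vector<int> if_unit, if_t1, if_k1,
      if_t2, if_k2;

  struct Emitted { int spike_id, sn, label, stim_id; long long prev_last; };
  std::vector<Emitted> emitted;

  for (long long t = 0; t <= n_ticks; ++t) {
    // (1) deliver due stimuli (with staggering)
    while (!stim_q.empty() && stim_q.top().due <= t) {
      PendingStim ps = stim_q.top(); stim_q.pop();
      if (artifacts_on && t - last_deliv_tick < artifact_ticks) {
        ps.due = last_deliv_tick + artifact_ticks;
        ps.seq = stim_seq++;
        stim_q.push(ps);
        continue;
      }
      int sid = static_cast<int>(st_time.size()) + 1; // 1-based stim id
      st_time.push_back(t * tick_ms);
      st_sched.push_back(ps.orig * tick_ms);
      st_target.push_back(ps.target + 1);
      st_source.push_back(ps.source_ifu + 1);
      st_ifu_spike.push_back(ps.ifu_spike_id);
      last_deliv_tick = t; last_deliv_id = sid; last_deliv_target = ps.target;

      const int k = ps.target;
      const Library& L = lib[k];
      long long dt_ms = last_spike[k] < 0 ? 101
        : std::llround((t - last_spike[k]) * tick_ms);
      if (evoke_on && unif_rand() < L.prob(dt_ms)) {
        double lat = L.latency[sample_index(static_cast<int>(L.latency.size()))];
        long long et = t + std::llround(lat * ticks_per_ms);
        pending_evoked[k].push_back(std::make_pair(et, sid));
      }
      if (inhibit_on) {
        double reb = L.rebound[sample_index(static_cast<int>(L.rebound.size()))];
        long long rt = t + std::max(1LL, std::llround(reb * ticks_per_ms));
        pending_rebound[k] = rt;   // a newer stimulus cancels and redraws
        rebound_stim[k] = sid;
        next_spont[k] = NEVER;     // spontaneous spike cancelled
      }
    }

    // (2) emit SN spikes due this tick
    emitted.clear();
    for (int k = 0; k < n_sn; ++k) {
      if (next_spont[k] == t) {
        emitted.push_back(Emitted{static_cast<int>(sp_time.size()) + 1, k, 0,
                                  NA_INTEGER, last_spike[k]});
        sp_time.push_back(t * tick_ms); sp_sn.push_back(k + 1);
        sp_label.push_back(0); sp_stim.push_back(NA_INTEGER);
        sp_obstructed.push_back(0);
        last_spike[k] = t;
        int isi = chains[k].draw(ctx[k]);
        ctx[k] = isi;
        next_spont[k] = t + std::llround(isi * ticks_per_ms);
      }
      if (!pending_evoked[k].empty()) {
        for (size_t q = 0; q < pending_evoked[k].size();) {
          if (pending_evoked[k][q].first == t) {
            emitted.push_back(Emitted{static_cast<int>(sp_time.size()) + 1, k, 1,
                                      pending_evoked[k][q].second, last_spike[k]});
            sp_time.push_back(t * tick_ms); sp_sn.push_back(k + 1);
            sp_label.push_back(1);
            sp_stim.push_back(pending_evoked[k][q].second);
            sp_obstructed.push_back(0);
            last_spike[k] = t;
            pending_evoked[k].erase(pending_evoked[k].begin() + q);
          } else if (pending_evoked[k][q].first < t) {
            pending_evoked[k].erase(pending_evoked[k].begin() + q);
          } else ++q;
        }
      }
      if (pending_rebound[k] == t) {
        long long prev = 0;
        for (size_t e = 0; e < emitted.size(); ++e)
          if (emitted[e].sn == k) prev = -2; // spike emitted this same tick
        long long base = (prev == -2) ? t : last_spike[k];
        long long realized = base < 0 ? ctx[k]
          : std::max(1LL, std::llround((t - base) * tick_ms));
        emitted.push_back(Emitted{static_cast<int>(sp_time.size()) + 1, k, 2,
                                  rebound_stim[k], last_spike[k]});
        sp_time.push_back(t * tick_ms); sp_sn.push_back(k + 1);
        sp_label.push_back(2); sp_stim.push_back(rebound_stim[k]);
        sp_obstructed.push_back(0);
        last_spike[k] = t;
        pending_rebound[k] = NEVER;
        rebound_stim[k] = NA_INTEGER;
        // resume the Markov chain from the realized post-stimulus interval
        int isi = chains[k].draw(static_cast<int>(realized));
        ctx[k] = isi;
        next_spont[k] = t + std::llround(isi * ticks_per_ms);
      }
    }

    // (3) obstruction marking; visible spikes become next-tick arrivals
    for (size_t e = 0; e < emitted.size(); ++e) {
      const Emitted& em = emitted[e];
      bool obstructed = artifacts_on &&
        (t - last_deliv_tick) >= 0 && (t - last_deliv_tick) < artifact_ticks;
      if (obstructed && evoked_exempt && em.label == 1 &&
          em.stim_id == last_deliv_id && em.sn == last_deliv_target)
        obstructed = false; // target SN's own evoked spike stays detectable
      if (obstructed) {
        sp_obstructed[em.spike_id - 1] = 1;
        if (!obstructed_resets) last_spike[em.sn] = em.prev_last;
      } else {
        Arrival a; a.src = em.sn; a.from_sn = true; a.spike_id = em.spike_id;
        arrivals_next.push_back(a);
      }
    }

    // (4) IFU update: decay, arrivals (from previous tick), threshold/reset
    std::swap(arrivals_now, arrivals_next);
    arrivals_next.clear();
    bool any_arrival = !arrivals_now.empty();
    if (energy > 1e-14 || any_arrival) {
      for (int s = 0; s < n_syn; ++s) {
        syn[s].S *= syn[s].c_slow;
        syn[s].F *= syn[s].c_fast;
      }
      energy *= c_slow_max;
      for (size_t a = 0; a < arrivals_now.size(); ++a) {
        const Arrival& ar = arrivals_now[a];
        const std::vector<int>& idx =
          ar.from_sn ? syn_by_sn[ar.src] : syn_by_ifu_src[ar.src];
        for (size_t q = 0; q < idx.size(); ++q) {
          Synapse& s = syn[idx[q]];
          s.S += s.inc; s.F += s.inc;
          energy += 2.0 * std::fabs(s.inc);
          if (s.inc > 0) push_trig(s.dst, ar.spike_id, ar.from_sn ? 0 : 1);
        }
      }
      for (int j = 0; j < n_ifu; ++j) {
        double v = 0.0;
        const std::vector<int>& idx = syn_by_dst[j];
        for (size_t q = 0; q < idx.size(); ++q)
          v += syn[idx[q]].S - syn[idx[q]].F;
        if (v >= thresholds[j]) {
          int iid = static_cast<int>(if_time.size()) + 1; // 1-based IFU spike id
          if_time.push_back(t * tick_ms); if_unit.push_back(j + 1);
          if_t1.push_back(trig_id[0][j]); if_k1.push_back(trig_kind[0][j]);
          if_t2.push_back(trig_id[1][j]); if_k2.push_back(trig_kind[1][j]);
          for (size_t q = 0; q < idx.size(); ++q) {
            syn[idx[q]].S = 0.0; syn[idx[q]].F = 0.0;
          }
          clear_trig(j);
          if (stim_delay_ticks[j] >= 0) {
            PendingStim ps;
            ps.due = ps.orig = t + stim_delay_ticks[j];
            ps.target = stim_target[j]; ps.source_ifu = j;
            ps.ifu_spike_id = iid; ps.seq = stim_seq++;
            stim_q.push(ps);
          } else {
            Arrival a; a.src = j; a.from_sn = false; a.spike_id = iid;
            arrivals_next.push_back(a);
          }
        }
      }
    }
  }

  return List::create(
    _["spikes"] = List::create(
      _["time_ms"] = sp_time, _["sn"] = sp_sn, _["label"] = sp_label,
      _["obstructed"] = sp_obstructed, _["stim_id"] = sp_stim),
    _["stims"] = List::create(
      _["time_ms"] = st_time, _["scheduled_ms"] = st_sched,
      _["target_sn"] = st_target, _["source_ifu"] = st_source,
      _["ifu_spike_id"] = st_ifu_spike),
    _["ifu_spikes"] = List::create(
      _["time_ms"] = if_time, _["ifu"] = if_unit,
      _["trig1_id"] = if_t1, _["trig1_kind"] = if_k1,
      _["trig2_id"] = if_t2, _["trig2_kind"] = if_k2));
}
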