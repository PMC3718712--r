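#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <climits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

// uniform integer on [0, n)
static inline int ui_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// selection coefficient draw; fitness factor is 1 - s (deleterious s > 0).
// type 0: fixed magnitude a, beneficial (s = -a) with probability b
// type 1: fitness effect e ~ N(a, b), s = -e, redrawn while s >= 1
static inline double draw_s(int type, double a, double b) {
  if (type == 0) {
    return (unif_rand() < b) ? -a : a;
  }
  double s;
  do {
    s = -(a + b * norm_rand());
  } while (s >= 1.0);
  return s;
}

// derived base draw: bases coded 0 (reference) .. 3; a new derived base is
// uniform over {1,2,3} minus the current derived base (never the reference,
// so derived-state polarity stays well defined)
static inline int draw_base(int current) {
  if (current == 0) return 1 + ui_int(3);
  int k = ui_int(2); // two derived alternatives remain
  int b = 0;
  for (int cand = 1; cand <= 3; ++cand) {
    if (cand == current && b <= k) continue;
    if (b == k && cand != current) return cand;
    if (cand != current) ++b;
  }
  // unreachable fallback
  return current == 1 ? 2 : 1;
}

// splice sorted-by-position mutation-id lists: segments [0,b1), [b1,b2), ...
// alternate donors A, B; output stays position sorted
static void splice_haps(const std::vector<int>& A, const std::vector<int>& B,
                        const std::vector<int>& bps, const std::vector<int>& mpos,
                        std::vector<int>& out) {
  out.clear();
  int start = 0;
  size_t nseg = bps.size() + 1;
  for (size_t seg = 0; seg < nseg; ++seg) {
    int end = (seg < bps.size()) ? bps[seg] : INT_MAX;
    const std::vector<int>& S = (seg % 2 == 0) ? A : B;
    auto lo = std::lower_bound(S.begin(), S.end(), start,
                               [&](int id, int v) { return mpos[id] < v; });
    auto hi = std::lower_bound(S.begin(), S.end(), end,
                               [&](int id, int v) { return mpos[id] < v; });
    out.insert(out.end(), lo, hi);
    start = end;
  }
}

// insert mutation id into a position-sorted list; a repeat hit at an already
// segregating position overwrites toward the new derived state
static void insert_mut(std::vector<int>& hap, int id, const std::vector<int>& mpos) {
  int p = mpos[id];
  auto it = std::lower_bound(hap.begin(), hap.end(), id,
                             [&](int a, int b) { return mpos[a] < mpos[b]; });
  if (it != hap.end() && mpos[*it] == p) {
    *it = id;
  } else {
    hap.insert(it, id);
  }
}

// ---------------------------------------------------------------------------
// Forward Wright-Fisher engine
// ---------------------------------------------------------------------------

// pop_sizes: diploid size per generation, length G+1 (index 0 = founders)
// locus_lengths: bp per unlinked locus
// fwd_neutral_frac: fraction of neutral mutations handled forward in time
//   (1 in AF_FOR, 0 in AF_ANC, intermediate in AF_MIX)
// [[Rcpp::export]]
List cpp_run_forward(IntegerVector pop_sizes, IntegerVector locus_lengths,
                     double mu, double r, double neutral_fraction,
                     double fwd_neutral_frac, int sel_type, double sel_a,
                     double sel_b, int cleanup_interval) {
  const int G = pop_sizes.size() - 1;
  const int n_loci = locus_lengths.size();
  const bool any_selection = neutral_fraction < 1.0;

  // mutation registry
  std::vector<int> m_locus, m_pos, m_gen, m_hap, m_base, m_fixed_gen;
  std::vector<double> m_s;
  std::vector<char> m_neutral;

  // recombination event log
  std::vector<int> rec_locus, rec_gen, rec_hap;
  std::vector<std::vector<int>> rec_bps;

  // ancestry: parent individual per child haplotype; homolog bit per locus
  std::vector<std::vector<int>> anc_parent(G + 1);
  std::vector<std::vector<std::vector<char>>> anc_bits(n_loci);
  for (int l = 0; l < n_loci; ++l) anc_bits[l].resize(G + 1);

  // population: per locus, per haplotype, sorted mutation-id list
  std::vector<std::vector<std::vector<int>>> cur(n_loci), nxt(n_loci);
  int N0 = pop_sizes[0];
  for (int l = 0; l < n_loci; ++l) cur[l].assign(2 * N0, std::vector<int>());

  std::vector<double> hapfit(2 * N0, 1.0); // per-haplotype product over loci
  std::vector<double> fit, cumfit;
  std::vector<int> bps_buf;

  // helper state for derived-base draws: current base at a position on a hap
  auto current_base_at = [&](const std::vector<int>& hap, int pos) -> int {
    auto it = std::lower_bound(hap.begin(), hap.end(), pos,
                               [&](int id, int v) { return m_pos[id] < v; });
    if (it != hap.end() && m_pos[*it] == pos) return m_base[*it];
    return 0;
  };

  for (int g = 1; g <= G; ++g) {
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
    int Nprev = pop_sizes[g - 1], Ncur = pop_sizes[g];

    // fitness of previous generation's individuals
    bool weighted = false;
    double total = 0.0;
    if (any_selection) {
      fit.assign(Nprev, 1.0);
      for (int k = 0; k < Nprev; ++k)
        fit[k] = hapfit[2 * k] * hapfit[2 * k + 1];
      double mn = fit[0], mx = fit[0];
      for (int k = 1; k < Nprev; ++k) {
        if (fit[k] < mn) mn = fit[k];
        if (fit[k] > mx) mx = fit[k];
      }
      weighted = mx > mn;
      if (weighted) {
        cumfit.resize(Nprev);
        double acc = 0.0;
        for (int k = 0; k < Nprev; ++k) { acc += fit[k]; cumfit[k] = acc; }
        total = acc;
        if (!(total > 0.0))
          stop("degenerate population: total fitness is zero");
      }
    }

    anc_parent[g].resize(2 * Ncur);
    for (int l = 0; l < n_loci; ++l) {
      anc_bits[l][g].resize(2 * Ncur);
      nxt[l].assign(2 * Ncur, std::vector<int>());
    }
    std::vector<double> hapfit_next(2 * Ncur, 1.0);

    for (int k = 0; k < Ncur; ++k) {
      int par[2];
      for (int m = 0; m < 2; ++m) {
        if (weighted) {
          double u = unif_rand() * total;
          int idx = (int)(std::upper_bound(cumfit.begin(), cumfit.end(), u) -
                          cumfit.begin());
          par[m] = idx >= Nprev ? Nprev - 1 : idx;
        } else {
          par[m] = ui_int(Nprev);
        }
      }
      for (int m = 0; m < 2; ++m) { // m=0 maternal gamete -> hap 2k, m=1 -> 2k+1
        int j = 2 * k + m;
        anc_parent[g][j] = par[m];
        double hf = 1.0;
        for (int l = 0; l < n_loci; ++l) {
          int L = locus_lengths[l];
          int bit = unif_rand() < 0.5 ? 0 : 1;
          anc_bits[l][g][j] = (char)bit;
          int seed = 2 * par[m] + bit;
          std::vector<int>& child = nxt[l][j];

          int nrec = (L >= 2 && r > 0) ? (int)R::rpois(r * (double)L) : 0;
          if (nrec > 0) {
            bps_buf.clear();
            for (int t = 0; t < nrec; ++t) bps_buf.push_back(1 + ui_int(L - 1));
            std::sort(bps_buf.begin(), bps_buf.end());
            bps_buf.erase(std::unique(bps_buf.begin(), bps_buf.end()),
                          bps_buf.end());
            splice_haps(cur[l][seed], cur[l][seed ^ 1], bps_buf, m_pos, child);
            rec_locus.push_back(l);
            rec_gen.push_back(g);
            rec_hap.push_back(j);
            rec_bps.push_back(bps_buf);
          } else {
            child = cur[l][seed];
          }

          // non-neutral mutations
          double lam_sel = mu * (double)L * (1.0 - neutral_fraction);
          int nsel = lam_sel > 0 ? (int)R::rpois(lam_sel) : 0;
          for (int t = 0; t < nsel; ++t) {
            int pos = ui_int(L);
            int base = draw_base(current_base_at(child, pos));
            double s = draw_s(sel_type, sel_a, sel_b);
            int id = (int)m_pos.size();
            m_locus.push_back(l); m_pos.push_back(pos); m_gen.push_back(g);
            m_hap.push_back(j); m_base.push_back(base); m_s.push_back(s);
            m_neutral.push_back(0); m_fixed_gen.push_back(-1);
            insert_mut(child, id, m_pos);
          }

          // neutral mutations handled forward (AF_FOR / forward share of AF_MIX)
          double lam_neu = mu * (double)L * neutral_fraction * fwd_neutral_frac;
          int nneu = lam_neu > 0 ? (int)R::rpois(lam_neu) : 0;
          for (int t = 0; t < nneu; ++t) {
            int pos = ui_int(L);
            int base = draw_base(current_base_at(child, pos));
            int id = (int)m_pos.size();
            m_locus.push_back(l); m_pos.push_back(pos); m_gen.push_back(g);
            m_hap.push_back(j); m_base.push_back(base); m_s.push_back(0.0);
            m_neutral.push_back(1); m_fixed_gen.push_back(-1);
            insert_mut(child, id, m_pos);
          }

          if (any_selection) {
            for (int id : child)
              if (!m_neutral[id]) hf *= (1.0 - m_s[id]);
          }
        }
        hapfit_next[j] = hf;
      }
    }

    for (int l = 0; l < n_loci; ++l) cur[l].swap(nxt[l]);
    hapfit.swap(hapfit_next);

    // fixed-mutation cleanup (consumes no randomness)
    if (cleanup_interval > 0 && g % cleanup_interval == 0 && !m_pos.empty()) {
      std::vector<int> cnt(m_pos.size(), 0);
      int nh = 2 * Ncur;
      for (int l = 0; l < n_loci; ++l)
        for (int j = 0; j < nh; ++j)
          for (int id : cur[l][j]) ++cnt[id];
      bool any_fixed = false;
      std::vector<char> fixed(m_pos.size(), 0);
      for (size_t id = 0; id < cnt.size(); ++id)
        if (cnt[id] == nh && m_fixed_gen[id] < 0) {
          fixed[id] = 1;
          m_fixed_gen[id] = g;
          any_fixed = true;
        }
      if (any_fixed) {
        for (int l = 0; l < n_loci; ++l)
          for (int j = 0; j < nh; ++j) {
            std::vector<int>& h = cur[l][j];
            h.erase(std::remove_if(h.begin(), h.end(),
                                   [&](int id) { return fixed[id] != 0; }),
                    h.end());
          }
        if (any_selection) { // refresh cached per-hap fitness after removal
          for (int j = 0; j < nh; ++j) {
            double hf = 1.0;
            for (int l = 0; l < n_loci; ++l)
              for (int id : cur[l][j])
                if (!m_neutral[id]) hf *= (1.0 - m_s[id]);
            hapfit[j] = hf;
          }
        }
      }
    }
  }

  // package results
  List final_haps(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    int nh = 2 * pop_sizes[G];
    List hl(nh);
    for (int j = 0; j < nh; ++j)
      hl[j] = IntegerVector(cur[l][j].begin(), cur[l][j].end());
    final_haps[l] = hl;
  }
  List parents(G + 1), bits(n_loci);
  parents[0] = IntegerVector(0);
  for (int g = 1; g <= G; ++g)
    parents[g] = IntegerVector(anc_parent[g].begin(), anc_parent[g].end());
  for (int l = 0; l < n_loci; ++l) {
    List bl(G + 1);
    bl[0] = IntegerVector(0);
    for (int g = 1; g <= G; ++g)
      bl[g] = IntegerVector(anc_bits[l][g].begin(), anc_bits[l][g].end());
    bits[l] = bl;
  }
  List rbps(rec_bps.size());
  for (size_t i = 0; i < rec_bps.size(); ++i)
    rbps[i] = IntegerVector(rec_bps[i].begin(), rec_bps[i].end());

  return List::create(
      _["registry"] = List::create(
          _["locus"] = IntegerVector(m_locus.begin(), m_locus.end()),
          _["position"] = IntegerVector(m_pos.begin(), m_pos.end()),
          _["origin_generation"] = IntegerVector(m_gen.begin(), m_gen.end()),
          _["hap_index"] = IntegerVector(m_hap.begin(), m_hap.end()),
          _["base"] = IntegerVector(m_base.begin(), m_base.end()),
          _["s"] = NumericVector(m_s.begin(), m_s.end()),
          _["is_neutral"] = LogicalVector(m_neutral.begin(), m_neutral.end()),
          _["fixed_generation"] =
              IntegerVector(m_fixed_gen.begin(), m_fixed_gen.end())),
      _["final_haps"] = final_haps,
      _["parents"] = parents,
      _["homolog_bits"] = bits,
      _["rec"] = List::create(
          _["locus"] = IntegerVector(rec_locus.begin(), rec_locus.end()),
          _["generation"] = IntegerVector(rec_gen.begin(), rec_gen.end()),
          _["hap_index"] = IntegerVector(rec_hap.begin(), rec_hap.end()),
          _["breakpoints"] = rbps),
      _["hap_fitness"] = NumericVector(hapfit.begin(), hapfit.end()));
}

// ---------------------------------------------------------------------------
// Surviving-region propagation and backtracking
// ---------------------------------------------------------------------------

// Closed integer super-regions (r_S, r_E); empty region is (INT_MAX, 0).
// Child segments [0,b1), [b1,b2), ... alternate donor parent / homolog.
// Returns keep flag: true iff some breakpoint splits the child's region
// (both donors then receive material); otherwise the event is transparent.
// donor_parity reports, for a transparent event (no breakpoint splits the
// child's region), which donor received the material: 0 = mapped parent,
// 1 = homolog; -1 when both donors received material (kept event).
static bool propagate_region_core(int c_rs, int c_re,
                                  const std::vector<int>& bps,
                                  int& p_rs, int& p_re, int& h_rs, int& h_re,
                                  int& donor_parity) {
  donor_parity = 0;
  if (c_rs > c_re) return false; // empty child region: no-op
  if (bps.empty()) {
    if (c_rs < p_rs) p_rs = c_rs;
    if (c_re > p_re) p_re = c_re;
    return false;
  }
  int start = 0;
  int hits = 0;
  size_t nseg = bps.size() + 1;
  for (size_t seg = 0; seg < nseg; ++seg) {
    int end = (seg < bps.size()) ? bps[seg] : INT_MAX; // segment [start, end)
    int lo = std::max(start, c_rs);
    int hi = std::min(end - 1, c_re);
    if (lo <= hi) {
      ++hits;
      donor_parity = (int)(seg % 2);
      if (seg % 2 == 0) {
        if (lo < p_rs) p_rs = lo;
        if (hi > p_re) p_re = hi;
      } else {
        if (lo < h_rs) h_rs = lo;
        if (hi > h_re) h_re = hi;
      }
    }
    start = end;
    if (start > c_re) break;
  }
  if (hits >= 2) { donor_parity = -1; return true; }
  return false;
}

// single-step wrapper (unit tests / exported op)
// [[Rcpp::export]]
List cpp_propagate_region(int child_rs, int child_re, IntegerVector breakpoints,
                          int parent_rs, int parent_re, int hom_rs, int hom_re) {
  std::vector<int> bps(breakpoints.begin(), breakpoints.end());
  int p_rs = parent_rs, p_re = parent_re, h_rs = hom_rs, h_re = hom_re;
  int dp = 0;
  bool keep = propagate_region_core(child_rs, child_re, bps, p_rs, p_re,
                                    h_rs, h_re, dp);
  return List::create(_["parent_rs"] = p_rs, _["parent_re"] = p_re,
                      _["hom_rs"] = h_rs, _["hom_re"] = h_re,
                      _["keep"] = keep, _["donor"] = dp);
}

// parent_map: per generation 1..G, haplotype-level parent index (0-based,
// into generation g-1); element 0 unused. n_haps: haplotype count per
// generation 0..G. init_idx: present haplotypes seeding the backtrack
// (0-based); their regions start at [0, L].
// [[Rcpp::export]]
List cpp_backtrack(List parent_map, IntegerVector n_haps,
                   IntegerVector rec_gen, IntegerVector rec_hap, List rec_bps,
                   int L, IntegerVector init_idx) {
  const int G = n_haps.size() - 1;
  const int INF = INT_MAX;
  int n_events = rec_gen.size();

  // bucket recombination events by generation
  std::vector<std::vector<int>> ev_at(G + 1);
  for (int e = 0; e < n_events; ++e) ev_at[rec_gen[e]].push_back(e);
  std::vector<std::vector<int>> bps_cache(n_events);
  for (int e = 0; e < n_events; ++e) {
    IntegerVector b = rec_bps[e];
    bps_cache[e].assign(b.begin(), b.end());
  }

  LogicalVector keep(n_events, false);
  IntegerVector donor(n_events, 0); // transparent events: 0 parent, 1 homolog
  List surv_idx(G + 1), surv_rs(G + 1), surv_re(G + 1);

  std::vector<int> rs(n_haps[G], INF), re(n_haps[G], 0);
  for (int t = 0; t < init_idx.size(); ++t) {
    rs[init_idx[t]] = 0;
    re[init_idx[t]] = L;
  }

  for (int g = G; g >= 1; --g) {
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
    IntegerVector pm = parent_map[g];
    int nprev = n_haps[g - 1];
    std::vector<int> prs(nprev, INF), pre(nprev, 0);

    // per-generation event lookup (few events per generation)
    std::unordered_map<int, int> ev_of;
    for (int e : ev_at[g]) ev_of[rec_hap[e]] = e;

    std::vector<int> si, srs, sre;
    for (int j = 0; j < n_haps[g]; ++j) {
      if (rs[j] > re[j]) continue;
      si.push_back(j); srs.push_back(rs[j]); sre.push_back(re[j]);
      int p = pm[j];
      auto f = ev_of.find(j);
      if (f == ev_of.end()) {
        if (rs[j] < prs[p]) prs[p] = rs[j];
        if (re[j] > pre[p]) pre[p] = re[j];
      } else {
        int e = f->second;
        int h = p ^ 1;
        int dp = 0;
        bool k = propagate_region_core(rs[j], re[j], bps_cache[e],
                                       prs[p], pre[p], prs[h], pre[h], dp);
        if (k) { keep[e] = true; donor[e] = -1; } else donor[e] = dp;
      }
    }
    surv_idx[g] = IntegerVector(si.begin(), si.end());
    surv_rs[g] = IntegerVector(srs.begin(), srs.end());
    surv_re[g] = IntegerVector(sre.begin(), sre.end());
    rs.swap(prs);
    re.swap(pre);
  }
  { // founder generation
    std::vector<int> si, srs, sre;
    for (int j = 0; j < n_haps[0]; ++j)
      if (rs[j] <= re[j]) { si.push_back(j); srs.push_back(rs[j]); sre.push_back(re[j]); }
    surv_idx[0] = IntegerVector(si.begin(), si.end());
    surv_rs[0] = IntegerVector(srs.begin(), srs.end());
    surv_re[0] = IntegerVector(sre.begin(), sre.end());
  }

  return List::create(_["survivors"] = surv_idx, _["rs"] = surv_rs,
                      _["re"] = surv_re, _["keep"] = keep,
                      _["donor"] = donor);
}

// ---------------------------------------------------------------------------
// A-posteriori neutral mutation placement on survivors
// ---------------------------------------------------------------------------

// rate: per-haplotype per-generation neutral mutation rate handled by the
// ancestry path (mu * L * neutral_fraction * (1 - forward share)).
// Positions are drawn uniformly on [0, L) and filtered against the
// survivor's super-region (draw-then-filter).
// [[Rcpp::export]]
List cpp_place_neutral(List surv_idx, List surv_rs, List surv_re,
                       int L, double rate) {
  const int G = surv_idx.size() - 1;
  std::vector<int> o_gen, o_hap, o_pos, o_base;
  long drawn = 0;
  for (int g = 1; g <= G; ++g) {
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
    IntegerVector idx = surv_idx[g], rs = surv_rs[g], re = surv_re[g];
    for (int t = 0; t < idx.size(); ++t) {
      int n = (int)R::rpois(rate);
      drawn += n;
      for (int q = 0; q < n; ++q) {
        int pos = ui_int(L);
        if (pos >= rs[t] && pos <= re[t]) {
          o_gen.push_back(g);
          o_hap.push_back(idx[t]);
          o_pos.push_back(pos);
          o_base.push_back(1 + ui_int(3));
        }
      }
    }
  }
  return List::create(
      _["generation"] = IntegerVector(o_gen.begin(), o_gen.end()),
      _["hap_index"] = IntegerVector(o_hap.begin(), o_hap.end()),
      _["position"] = IntegerVector(o_pos.begin(), o_pos.end()),
      _["base"] = IntegerVector(o_base.begin(), o_base.end()),
      _["n_drawn"] = (double)drawn);
}

// ---------------------------------------------------------------------------
// Backward Event Graph construction (forward pass over generations)
// ---------------------------------------------------------------------------

// Events must be sorted by generation (stable within generation). Node 0 is
// the founder sentinel. M-nodes have out-degree 1 (e1), R-nodes out-degree 2
// (e1 = donor of [0,b1), e2 = homolog donor). Payload indexes the caller's
// R-event / M-stub tables (0-based).
// [[Rcpp::export]]
List cpp_build_graph(List parent_map, IntegerVector n_haps,
                     IntegerVector r_gen, IntegerVector r_hap,
                     LogicalVector r_keep, IntegerVector r_donor,
                     IntegerVector m_gen, IntegerVector m_hap) {
  const int G = n_haps.size() - 1;
  std::vector<std::vector<int>> rev(G + 1), mev(G + 1);
  for (int e = 0; e < r_gen.size(); ++e) rev[r_gen[e]].push_back(e);
  for (int e = 0; e < m_gen.size(); ++e) mev[m_gen[e]].push_back(e);

  std::vector<int> kind(1, 0), gen(1, -1), hap(1, -1), payload(1, -1),
      e1(1, -1), e2(1, -1);

  std::vector<int> refs_prev(n_haps[0], 0), refs_cur;
  for (int g = 1; g <= G; ++g) {
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
    IntegerVector pm = parent_map[g];
    refs_cur.resize(n_haps[g]);
    for (int j = 0; j < n_haps[g]; ++j) refs_cur[j] = refs_prev[pm[j]];
    for (int e : rev[g]) {
      int j = r_hap[e];
      int p = pm[j];
      if (r_keep[e]) {
        int id = (int)kind.size();
        kind.push_back(2); gen.push_back(g); hap.push_back(j); payload.push_back(e);
        e1.push_back(refs_prev[p]);
        e2.push_back(refs_prev[p ^ 1]);
        refs_cur[j] = id;
      } else if (r_donor[e] == 1) {
        // transparent event whose surviving material comes from the homolog
        refs_cur[j] = refs_prev[p ^ 1];
      }
    }
    for (int e : mev[g]) {
      int j = m_hap[e];
      int id = (int)kind.size();
      kind.push_back(1); gen.push_back(g); hap.push_back(j); payload.push_back(e);
      e1.push_back(refs_cur[j]);
      e2.push_back(-1);
      refs_cur[j] = id;
    }
    refs_prev.swap(refs_cur);
  }

  return List::create(
      _["kind"] = IntegerVector(kind.begin(), kind.end()),
      _["generation"] = IntegerVector(gen.begin(), gen.end()),
      _["hap_index"] = IntegerVector(hap.begin(), hap.end()),
      _["payload"] = IntegerVector(payload.begin(), payload.end()),
      _["e1"] = IntegerVector(e1.begin(), e1.end()),
      _["e2"] = IntegerVector(e2.begin(), e2.end()),
      _["entries"] = IntegerVector(refs_prev.begin(), refs_prev.end()));
}

// ---------------------------------------------------------------------------
// Visit counting (pre-traversal for explicit-node selection)
// ---------------------------------------------------------------------------

// One traversal per entry; a traversal stops at nodes already visited
// (by any traversal, including itself) but still counts the reach.
// [[Rcpp::export]]
IntegerVector cpp_count_visits(IntegerVector kind, IntegerVector e1,
                               IntegerVector e2, IntegerVector entries) {
  int n = kind.size();
  IntegerVector v(n, 0);
  std::vector<char> visited(n, 0);
  std::vector<int> stack;
  for (int t = 0; t < entries.size(); ++t) {
    stack.clear();
    stack.push_back(entries[t]);
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      if (visited[x]) { ++v[x]; continue; }
      visited[x] = 1;
      ++v[x];
      if (e1[x] >= 0) stack.push_back(e1[x]);
      if (e2[x] >= 0) stack.push_back(e2[x]);
    }
  }
  return v;
}

// ---------------------------------------------------------------------------
// Sequence extraction with exact fragmented regions of interest
// ---------------------------------------------------------------------------

typedef std::vector<std::pair<int, int>> Regions; // disjoint closed intervals

static bool regions_contain(const Regions& rg, int pos) {
  for (auto& iv : rg)
    if (pos >= iv.first && pos <= iv.second) return true;
  return false;
}

// split closed regions by breakpoints into donor-A (even segments) and
// donor-B (odd segments) parts
static void split_regions(const Regions& rg, const std::vector<int>& bps,
                          Regions& ra, Regions& rb) {
  ra.clear();
  rb.clear();
  size_t nseg = bps.size() + 1;
  int start = 0;
  for (size_t seg = 0; seg < nseg; ++seg) {
    int end = (seg < bps.size()) ? bps[seg] : INT_MAX;
    for (auto& iv : rg) {
      int lo = std::max(iv.first, start);
      int hi = std::min(iv.second, end - 1);
      if (lo <= hi) ((seg % 2 == 0) ? ra : rb).push_back({lo, hi});
    }
    start = end;
  }
}

struct BitRow {
  std::vector<uint64_t> w;
  explicit BitRow(int ncol) : w((ncol + 63) / 64, 0) {}
  BitRow() {}
  void set(int i) { w[i >> 6] |= (uint64_t)1 << (i & 63); }
  bool get(int i) const { return (w[i >> 6] >> (i & 63)) & 1; }
};

// OR src into dst restricted to columns whose position lies in rg
static void or_masked(BitRow& dst, const BitRow& src, const Regions& rg,
                      const std::vector<int>& col_pos) {
  BitRow mask((int)col_pos.size());
  for (auto& iv : rg) {
    int lo = (int)(std::lower_bound(col_pos.begin(), col_pos.end(), iv.first) -
                   col_pos.begin());
    int hi = (int)(std::upper_bound(col_pos.begin(), col_pos.end(), iv.second) -
                   col_pos.begin());
    for (int c = lo; c < hi; ++c) mask.set(c);
  }
  for (size_t t = 0; t < dst.w.size(); ++t) dst.w[t] |= src.w[t] & mask.w[t];
}

struct Extractor {
  const int* kind;
  const int* e1;
  const int* e2;
  const int* payload;
  const std::vector<std::vector<int>>& r_bps;
  const std::vector<int>& m_col;
  const std::vector<int>& m_pos;
  const std::vector<int>& col_pos;
  const std::vector<char>& expl;
  std::unordered_map<int, BitRow> cache;
  int L;
  int ncol;

  Extractor(const int* kind_, const int* e1_, const int* e2_,
            const int* payload_, const std::vector<std::vector<int>>& rb,
            const std::vector<int>& mc, const std::vector<int>& mp,
            const std::vector<int>& cp, const std::vector<char>& ex, int L_)
      : kind(kind_), e1(e1_), e2(e2_), payload(payload_), r_bps(rb), m_col(mc),
        m_pos(mp), col_pos(cp), expl(ex), L(L_), ncol((int)cp.size()) {}

  // traverse from `start` with initial regions; OR results into `out`
  void traverse(int start, const Regions& init, BitRow& out) {
    std::vector<std::pair<int, Regions>> stack;
    stack.push_back({start, init});
    bool first = true;
    while (!stack.empty()) {
      int x = stack.back().first;
      Regions rg = std::move(stack.back().second);
      stack.pop_back();
      if (rg.empty()) { first = false; continue; }
      if (!first && expl[x]) {
        auto f = cache.find(x);
        if (f != cache.end()) {
          or_masked(out, f->second, rg, col_pos);
          continue;
        }
      }
      first = false;
      int k = kind[x];
      if (k == 0) continue; // founder sentinel
      if (k == 1) {         // M-node
        int p = payload[x];
        if (regions_contain(rg, m_pos[p])) out.set(m_col[p]);
        stack.push_back({e1[x], std::move(rg)});
      } else { // R-node
        Regions ra, rb;
        split_regions(rg, r_bps[payload[x]], ra, rb);
        stack.push_back({e1[x], std::move(ra)});
        stack.push_back({e2[x], std::move(rb)});
      }
    }
  }

  void build_cache(int x) {
    Regions full{{0, L}};
    BitRow b(ncol);
    traverse(x, full, b);
    cache.emplace(x, std::move(b));
  }
};

// m_col / m_pos are indexed by M-node payload (0-based); r_bps by R-node
// payload. col_pos: sorted unique positions defining matrix columns.
// [[Rcpp::export]]
LogicalMatrix cpp_extract(IntegerVector kind, IntegerVector e1,
                          IntegerVector e2, IntegerVector payload,
                          List r_bps, IntegerVector m_col, IntegerVector m_pos,
                          IntegerVector col_pos, IntegerVector entries,
                          LogicalVector explicit_flag, int L) {
  int n = kind.size();
  std::vector<std::vector<int>> rb(r_bps.size());
  for (int i = 0; i < r_bps.size(); ++i) {
    IntegerVector b = r_bps[i];
    rb[i].assign(b.begin(), b.end());
  }
  std::vector<int> mc(m_col.begin(), m_col.end());
  std::vector<int> mp(m_pos.begin(), m_pos.end());
  std::vector<int> cp(col_pos.begin(), col_pos.end());
  std::vector<char> ex(n, 0);
  for (int i = 0; i < n; ++i) ex[i] = explicit_flag[i] ? 1 : 0;

  Extractor E(INTEGER(kind), INTEGER(e1), INTEGER(e2), INTEGER(payload), rb,
              mc, mp, cp, ex, L);

  // explicit caches: edges point to lower node ids, so ascending order
  // guarantees a cache never depends on a not-yet-built cache
  for (int x = 0; x < n; ++x)
    if (ex[x]) E.build_cache(x);

  int ncol = cp.size();
  int nrow = entries.size();
  LogicalMatrix out(nrow, ncol);
  std::unordered_map<int, BitRow> memo; // full-region results per node

  for (int t = 0; t < nrow; ++t) {
    Rcpp::checkUserInterrupt();
    // copy-then-append shortcut: strip the leading M-chain, reuse shared tail
    std::vector<int> chain_cols;
    int x = entries[t];
    while (kind[x] == 1 && memo.find(x) == memo.end()) {
      chain_cols.push_back(mc[payload[x]]);
      x = e1[x];
    }
    BitRow row(ncol);
    auto f = memo.find(x);
    if (f != memo.end()) {
      row = f->second;
    } else {
      Regions full{{0, L}};
      E.traverse(x, full, row);
      memo.emplace(x, row);
    }
    for (int c : chain_cols) row.set(c);
    memo.emplace(entries[t], row);
    for (int c = 0; c < ncol; ++c) out(t, c) = row.get(c);
  }
  return out;
}
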