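#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Structured-coalescent ancestral recombination graph for a sample made of a
// non-recombining balanced class (S) and a recombining duplicated pseudogene
// class (P).  Time is measured in coalescent units where an S-class pair
// coalesces at rate 1 (i.e. units of 4*N_e*f generations); the P class, with
// effective size smaller by the factor f, coalesces at pairwise rate f.
//
// Epochs, looking backward from the present:
//   [0, t_d)          : S and P are separate loci; no cross-class coalescence.
//                       P lineages recombine at rate rho_site per link of
//                       their ancestral material (material measure, not the
//                       extent: breakpoints fall inside or between material
//                       segments, never in trapped gaps).
//   [t_d, t_d + t_b)  : bottleneck at the duplication; P pairs coalesce at
//                       rate theta_s / theta_b, recombination off.
//   [t_d + t_b, inf)  : single origin of the duplicate; surviving P lineages
//                       join the S class; plain coalescent to the grand MRCA.
//
// Ancestral material is a sorted list of half-open segments over [0, L).
// Each segment carries the node id of its current marginal subtree root and
// the number of sample tips below it; a segment reaching count == n has found
// its MRCA and is retired.
//
// Pruning: under the prescribed severe bottleneck every P lineage alive at
// t_d coalesces into one lineage during [t_d, t_d + t_b) with probability
// 1 - exp(-(theta_s/theta_b) * t_b) per pair (~ 1 - e^-10000 at the default
// theta_b).  Once no site has two or more surviving P copies, all remaining
// within-P events before the classes merge act on pairwise-disjoint material:
// coalescences concatenate segment lists without creating marginal nodes and
// recombinations repartition material that is guaranteed to be reunited, so
// neither can change any marginal tree.  The simulator therefore freezes the
// P class at that point and lets the bottleneck collapse it.  The freeze is
// applied only when the bottleneck is strong ((theta_s/theta_b)*t_b > 50);
// a run with a mild bottleneck gets the unpruned process.

namespace {

struct Seg {
  int start, end;   // half-open [start, end)
  int node;         // marginal subtree root for this stretch
  int count;        // tips below
};

typedef std::vector<Seg> Lineage;

inline int material(const Lineage& lin) {
  int m = 0;
  for (size_t i = 0; i < lin.size(); ++i) m += lin[i].end - lin[i].start;
  return m;
}

struct NodeTable {
  std::vector<double> time;
  std::vector<int> left, right;
  int add(double t, int l, int r) {
    time.push_back(t); left.push_back(l); right.push_back(r);
    return (int)time.size() - 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".arg_simulate_cpp")]]
List arg_simulate_cpp(int n, int n_p, double f, double theta_s,
                      double t_d, double t_b, double theta_b,
                      double rho_site, int L) {
  if (n < 1 || L < 1) stop("need n >= 1 and L >= 1");
  if (n_p < 0 || n_p > n) stop("pseudogene count outside sample");

  NodeTable nodes;
  nodes.time.reserve(8 * n); nodes.left.reserve(8 * n); nodes.right.reserve(8 * n);
  for (int i = 0; i < n; ++i) nodes.add(0.0, -1, -1);

  std::vector<Lineage> lin;
  std::vector<int> cls;   // 0 = S, 1 = P
  std::vector<int> mat;   // material size per lineage (cached)
  lin.reserve(4 * n); cls.reserve(4 * n); mat.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    Lineage l(1);
    l[0].start = 0; l[0].end = L; l[0].node = i; l[0].count = 1;
    lin.push_back(l);
    cls.push_back(i < n_p ? 1 : 0);
    mat.push_back(L);
  }

  std::vector<Seg> done;  // completed (MRCA-found) segments; node = root

  const bool strong_bneck = (theta_b > 0.0) && (t_b * theta_s / theta_b > 50.0);

  // per-site surviving P copy count, for the pruning rule
  std::vector<int> pcnt;
  long n_multi = 0;                  // sites with >= 2 P copies
  bool track = strong_bneck && n_p >= 2 && rho_site > 0.0;
  if (track) { pcnt.assign(L, n_p); n_multi = L; }
  bool frozen = track ? false : (strong_bneck && rho_site > 0.0);
  // frozen == true means within-P events are marginal no-ops

  int kS = n - n_p, kP = n_p;
  long totP_mat = (long)n_p * L;     // total P material (for link count)

  double t = 0.0;
  int n_rec = 0;
  long guard = 0;
  const long guard_max = 500000000L;
  Lineage merged; merged.reserve(64);

  while (!lin.empty()) {
    if (++guard > guard_max) stop("event budget exceeded");
    int phase = (t < t_d) ? 0 : (t < t_d + t_b ? 1 : 2);

    if (phase == 2 && kP > 0) {  // duplicate joins the S-allele genealogy
      for (size_t i = 0; i < cls.size(); ++i) cls[i] = 0;
      kS += kP; kP = 0;
    }

    double rateS = 0.5 * (double)kS * (kS - 1);
    double rateP = 0.0, rateR = 0.0;
    if (phase == 0) {
      if (!frozen) {
        rateP = f * 0.5 * (double)kP * (kP - 1);
        if (rho_site > 0.0 && kP > 0)
          rateR = rho_site * (double)(totP_mat - kP);
      }
    } else if (phase == 1) {
      rateP = (theta_s / theta_b) * 0.5 * (double)kP * (kP - 1);
    }

    double total = rateS + rateP + rateR;
    if (total <= 0.0) {
      if (phase == 0) { t = t_d; continue; }
      if (phase == 1) { t = t_d + t_b; continue; }
      stop("stalled coalescent: no possible event in final phase");
    }
    double dt = R::exp_rand() / total;
    if (phase == 0 && t + dt > t_d)       { t = t_d; continue; }
    if (phase == 1 && t + dt > t_d + t_b) { t = t_d + t_b; continue; }
    t += dt;

    double u = R::unif_rand() * total;
    if (u < rateR) {
      // ---- recombination on a P lineage ------------------------------
      // lineage chosen proportional to its link count (material - 1),
      // breakpoint uniform over links: interior material positions and
      // the junctions between segments
      double target = R::unif_rand() * (double)(totP_mat - kP);
      int idx = -1; double acc = 0.0;
      for (size_t i = 0; i < lin.size(); ++i) {
        if (cls[i] != 1) continue;
        acc += mat[i] - 1;
        if (target < acc) { idx = (int)i; break; }
      }
      if (idx < 0 || mat[idx] < 2) continue;
      // link index 1..mat-1: split after the link-th material site
      int link = 1 + (int)(R::unif_rand() * (mat[idx] - 1));
      if (link > mat[idx] - 1) link = mat[idx] - 1;
      const Lineage& src = lin[idx];
      Lineage left, right;
      left.reserve(src.size()); right.reserve(src.size());
      int seen = 0, left_mat = 0;
      for (size_t s = 0; s < src.size(); ++s) {
        const Seg& sg = src[s];
        int w = sg.end - sg.start;
        if (seen + w <= link) {
          left.push_back(sg); left_mat += w;
        } else if (seen >= link) {
          right.push_back(sg);
        } else {
          int b = sg.start + (link - seen);
          Seg a = sg, c = sg;
          a.end = b; c.start = b;
          left.push_back(a); right.push_back(c);
          left_mat += b - sg.start;
        }
        seen += w;
      }
      if (left.empty() || right.empty()) continue;
      int right_mat = mat[idx] - left_mat;
      lin[idx] = left; mat[idx] = left_mat;
      lin.push_back(right);
      cls.push_back(1);
      mat.push_back(right_mat);
      ++kP;
      ++n_rec;
    } else {
      // ---- coalescence within the chosen class -----------------------
      int want = (u < rateR + rateP) ? 1 : 0;
      int k = want ? kP : kS;
      if (k < 2) continue;
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t i = 0; i < lin.size(); ++i) {
        if (cls[i] != want) continue;
        if (seen == a) ia = (int)i;
        if (seen == b) ib = (int)i;
        ++seen;
        if (ia >= 0 && ib >= 0) break;
      }
      const Lineage &A = lin[ia], &B = lin[ib];
      const bool upd = track && want == 1 && !frozen;
      merged.clear();
      int new_mat = 0;
      size_t i = 0, j = 0;
      Seg x, y; bool hx = false, hy = false;
      while (true) {
        if (!hx && i < A.size()) { x = A[i++]; hx = true; }
        if (!hy && j < B.size()) { y = B[j++]; hy = true; }
        if (!hx && !hy) break;
        if (hx && (!hy || x.end <= y.start)) {
          merged.push_back(x); new_mat += x.end - x.start; hx = false; continue;
        }
        if (hy && (!hx || y.end <= x.start)) {
          merged.push_back(y); new_mat += y.end - y.start; hy = false; continue;
        }
        // overlap exists
        if (x.start < y.start) {
          Seg pre = x; pre.end = y.start;
          merged.push_back(pre); new_mat += pre.end - pre.start;
          x.start = y.start;
        } else if (y.start < x.start) {
          Seg pre = y; pre.end = x.start;
          merged.push_back(pre); new_mat += pre.end - pre.start;
          y.start = x.start;
        }
        int e = std::min(x.end, y.end);
        Seg ov;
        ov.start = x.start; ov.end = e;
        ov.count = x.count + y.count;
        ov.node = nodes.add(t, x.node, y.node);
        if (upd) {
          for (int s2 = ov.start; s2 < e; ++s2)
            if (--pcnt[s2] == 1) --n_multi;
        }
        if (ov.count == n) done.push_back(ov);
        else { merged.push_back(ov); new_mat += e - ov.start; }
        if (x.end == e) hx = false; else x.start = e;
        if (y.end == e) hy = false; else y.start = e;
      }
      if (want == 1) totP_mat += (long)new_mat - mat[ia] - mat[ib];
      int hi_idx = std::max(ia, ib), lo_idx = std::min(ia, ib);
      lin.erase(lin.begin() + hi_idx);
      cls.erase(cls.begin() + hi_idx);
      mat.erase(mat.begin() + hi_idx);
      if (want == 1) --kP; else --kS;
      if (merged.empty()) {
        lin.erase(lin.begin() + lo_idx);
        cls.erase(cls.begin() + lo_idx);
        mat.erase(mat.begin() + lo_idx);
        if (want == 1) --kP; else --kS;
      } else {
        lin[lo_idx] = merged;
        mat[lo_idx] = new_mat;
      }
      if (upd && n_multi == 0) frozen = true;
    }
  }

  std::sort(done.begin(), done.end(),
            [](const Seg& a, const Seg& b) { return a.start < b.start; });
  int m = (int)done.size();
  IntegerVector seg_start(m), seg_end(m), seg_root(m);
  for (int i = 0; i < m; ++i) {
    seg_start[i] = done[i].start;
    seg_end[i]   = done[i].end;
    seg_root[i]  = done[i].node;
  }
  return List::create(
    _["node_time"]  = wrap(nodes.time),
    _["node_left"]  = wrap(nodes.left),
    _["node_right"] = wrap(nodes.right),
    _["seg_start"]  = seg_start,
    _["seg_end"]    = seg_end,
    _["seg_root"]   = seg_root,
    _["n_recomb"]   = n_rec);
}

// Jukes-Cantor evolution along the marginal genealogies.  Branch lengths are
// (coalescent time difference) * theta_s / 2 expected substitutions per site;
// substitution events are realised as a Poisson jump process (each jump moves
// to one of the three other bases uniformly), so the returned event count can
// be compared with infinite-sites expectations.
// [[Rcpp::export(name = ".evolve_jc_cpp")]]
List evolve_jc_cpp(NumericVector node_time, IntegerVector node_left,
                   IntegerVector node_right, IntegerVector seg_start,
                   IntegerVector seg_end, IntegerVector seg_root,
                   double theta_s, int n, int L) {
  IntegerMatrix aln(n, L);
  long n_mut = 0;
  int nseg = seg_start.size();
  for (int s = 0; s < nseg; ++s) {
    int a = seg_start[s], b = seg_end[s], w = b - a;
    std::vector<std::pair<int, std::vector<unsigned char> > > stack;
    std::vector<unsigned char> rootstate(w);
    for (int i = 0; i < w; ++i) {
      int st = (int)(R::unif_rand() * 4.0); if (st > 3) st = 3;
      rootstate[i] = (unsigned char)st;
    }
    stack.push_back(std::make_pair(seg_root[s], rootstate));
    while (!stack.empty()) {
      int node = stack.back().first;
      std::vector<unsigned char> st = stack.back().second;
      stack.pop_back();
      if (node < n) {  // tip
        for (int i = 0; i < w; ++i) aln(node, a + i) = st[i];
        continue;
      }
      int ch[2] = { node_left[node], node_right[node] };
      for (int c = 0; c < 2; ++c) {
        double d = (node_time[node] - node_time[ch[c]]) * theta_s / 2.0;
        std::vector<unsigned char> cs = st;
        if (d > 0) {
          for (int i = 0; i < w; ++i) {
            int k = (int)R::rpois(d);
            for (int j = 0; j < k; ++j) {
              int step = 1 + (int)(R::unif_rand() * 3.0); if (step > 3) step = 3;
              cs[i] = (unsigned char)((cs[i] + step) & 3);
            }
            n_mut += k;
          }
        }
        stack.push_back(std::make_pair(ch[c], cs));
      }
    }
  }
  return List::create(_["alignment"] = aln, _["n_mut_events"] = (double)n_mut);
}

// Inner loop of the LD-distance permutation test.  The r-squared value of a
// column pair does not change when columns are reassigned to positions, and
// the multiset of pairwise distances is likewise permutation-invariant, so
// the Pearson correlation is monotone in S = sum_{i<j} r2_ij * d_ij and the
// tail count can be taken on S alone.  Permutations of <= 7 columns are
// enumerated exhaustively when the permutation budget allows.
// [[Rcpp::export(name = ".perm_count_cpp")]]
List perm_count_cpp(NumericMatrix r2, NumericVector pos, int n_perm) {
  int S = r2.nrow();
  if (r2.ncol() != S || pos.size() != S) stop("r2/pos size mismatch");
  double obs = 0.0;
  for (int i = 0; i < S; ++i)
    for (int j = i + 1; j < S; ++j)
      obs += r2(i, j) * std::fabs(pos[i] - pos[j]);
  double tol = 1e-9 * (std::fabs(obs) + 1.0);

  double fact = 1.0;
  for (int i = 2; i <= S; ++i) fact *= i;
  bool exhaustive = (S <= 7) && (fact <= (double)n_perm);

  long count = 0, total = 0;
  if (exhaustive) {
    std::vector<int> idx(S);
    for (int i = 0; i < S; ++i) idx[i] = i;
    do {
      double ssum = 0.0;
      for (int i = 0; i < S; ++i)
        for (int j = i + 1; j < S; ++j)
          ssum += r2(i, j) * std::fabs(pos[idx[i]] - pos[idx[j]]);
      if (ssum <= obs + tol) ++count;
      ++total;
    } while (std::next_permutation(idx.begin(), idx.end()));
  } else {
    std::vector<int> idx(S);
    for (int p = 0; p < n_perm; ++p) {
      for (int i = 0; i < S; ++i) idx[i] = i;
      for (int i = S - 1; i > 0; --i) {   // Fisher-Yates with R's RNG
        int j = (int)(R::unif_rand() * (i + 1)); if (j > i) j = i;
        std::swap(idx[i], idx[j]);
      }
      double ssum = 0.0;
      for (int i = 0; i < S; ++i) {
        double pi_ = pos[idx[i]];
        for (int j = i + 1; j < S; ++j)
          ssum += r2(i, j) * std::fabs(pi_ - pos[idx[j]]);
      }
      if (ssum <= obs + tol) ++count;
      ++total;
    }
  }
  return List::create(_["obs_sum"] = obs, _["count_le"] = (double)count,
                      _["total"] = (double)total, _["exhaustive"] = exhaustive);
}
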