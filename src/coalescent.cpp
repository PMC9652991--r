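// Structured-coalescent Monte-Carlo engine.
//
// Time is measured backwards from the present in units of 2*Nref generations,
// deme sizes (nu) relative to Nref, and backward migration rates M[a][b] give
// the rate at which a lineage currently in deme a traces its ancestry to deme
// b (equal to the population-scaled forward rate 2*Nref*m_ab of migration
// into a from b).  Demography is a list of epochs ordered from the present
// into the past; each epoch carries its end time, deme sizes, a migration
// matrix, and a "popmap" relabelling applied to all lineages on entry (used
// to merge daughter populations into the ancestral one at the split time).
// The last epoch must have infinite t_end and guarantee common ancestry.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {


// xoshiro256+ with splitmix64 seeding: fast uniform doubles for the hot
// event loop; deterministic given the seed
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]
  inline double unif() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
};

struct Epoch {
  double t_end;
  std::vector<int> popmap;   // 0-based, applied on entry
  std::vector<double> nu;
  std::vector<double> M;     // row-major d*d, diagonal zero
  std::vector<double> mout;  // row sums
  int d;
};

std::vector<Epoch> parse_epochs(List epochs) {
  int ne = epochs.size();
  if (ne < 1) stop("at least one epoch required");
  std::vector<Epoch> out(ne);
  int d0 = -1;
  for (int e = 0; e < ne; ++e) {
    List el = epochs[e];
    Epoch ep;
    ep.t_end = as<double>(el["t_end"]);
    IntegerVector pm = el["popmap"];
    NumericVector nu = el["nu"];
    NumericMatrix M = el["M"];
    ep.d = nu.size();
    if (d0 < 0) d0 = ep.d;
    if (ep.d != d0) stop("all epochs must use the same number of demes");
    if ((int)pm.size() != ep.d || M.nrow() != ep.d || M.ncol() != ep.d)
      stop("epoch popmap/M dimensions must match nu");
    ep.popmap.resize(ep.d);
    for (int i = 0; i < ep.d; ++i) {
      ep.popmap[i] = pm[i] - 1;
      if (ep.popmap[i] < 0 || ep.popmap[i] >= ep.d) stop("popmap out of range");
      if (!(nu[i] > 0)) stop("deme sizes nu must be positive");
    }
    ep.nu.assign(nu.begin(), nu.end());
    ep.M.assign(ep.d * ep.d, 0.0);
    ep.mout.assign(ep.d, 0.0);
    for (int a = 0; a < ep.d; ++a)
      for (int b = 0; b < ep.d; ++b) {
        if (a == b) continue;
        double v = M(a, b);
        if (v < 0) stop("migration rates must be non-negative");
        ep.M[a * ep.d + b] = v;
        ep.mout[a] += v;
      }
    if (e > 0 && !(ep.t_end > out[e - 1].t_end))
      stop("epoch end times must be strictly increasing");
    out[e] = ep;
  }
  if (!std::isinf(out[ne - 1].t_end))
    stop("last epoch must have infinite t_end");
  return out;
}

struct Tree {
  std::vector<double> tbirth, tend;  // tend of root left as birth marker
  std::vector<int> c1, c2;           // children, -1 for tips
  int n_tips, root;
};

// Simulate one genealogy; tip_deme is 0-based.
void sim_tree(const std::vector<Epoch>& eps, const std::vector<int>& tip_deme,
              FastRng& rng, Tree& tr) {
  const int n = tip_deme.size();
  const int d = eps[0].d;
  const int n_nodes = 2 * n - 1;
  tr.n_tips = n;
  tr.tbirth.assign(n_nodes, 0.0);
  tr.tend.assign(n_nodes, -1.0);
  tr.c1.assign(n_nodes, -1);
  tr.c2.assign(n_nodes, -1);

  std::vector<std::vector<int>> bydeme(d);
  for (int i = 0; i < n; ++i) {
    if (tip_deme[i] < 0 || tip_deme[i] >= d) stop("tip deme out of range");
    bydeme[tip_deme[i]].push_back(i);
  }
  std::vector<double> coal(d), mig(d);

  double t = 0.0;
  int ei = 0;
  int k = n;
  int next_node = n;

  // popmap of the first epoch (normally identity)
  {
    std::vector<std::vector<int>> nb(d);
    for (int a = 0; a < d; ++a)
      for (int id : bydeme[a]) nb[eps[0].popmap[a]].push_back(id);
    bydeme.swap(nb);
  }

  long guard = 0;
  while (k > 1) {
    if (++guard > 100000000L) stop("coalescent event horizon exceeded");
    const Epoch& ep = eps[ei];
    double R = 0.0;
    for (int a = 0; a < d; ++a) {
      double ka = bydeme[a].size();
      coal[a] = ka * (ka - 1.0) * 0.5 / ep.nu[a];
      mig[a] = ka * ep.mout[a];
      R += coal[a] + mig[a];
    }
    double tnext;
    if (R > 0) {
      double u = rng.unif();
      if (u <= 0) u = std::numeric_limits<double>::min();
      tnext = t - std::log(u) / R;
    } else {
      tnext = std::numeric_limits<double>::infinity();
    }
    if (tnext > ep.t_end) {
      if (ei + 1 >= (int)eps.size())
        stop("no coalescence possible in final epoch");
      t = ep.t_end;
      ++ei;
      const Epoch& np = eps[ei];
      std::vector<std::vector<int>> nb(d);
      for (int a = 0; a < d; ++a)
        for (int id : bydeme[a]) nb[np.popmap[a]].push_back(id);
      bydeme.swap(nb);
      continue;
    }
    t = tnext;
    double u = rng.unif() * R;
    bool done = false;
    for (int a = 0; a < d && !done; ++a) {
      if (u < coal[a]) {
        int ka = bydeme[a].size();
        int i1 = std::min((int)(rng.unif() * ka), ka - 1);
        int i2 = std::min((int)(rng.unif() * (ka - 1)), ka - 2);
        if (i2 >= i1) ++i2;
        int id1 = bydeme[a][i1], id2 = bydeme[a][i2];
        int par = next_node++;
        tr.tbirth[par] = t;
        tr.c1[par] = id1;
        tr.c2[par] = id2;
        tr.tend[id1] = t;
        tr.tend[id2] = t;
        // swap-remove the higher index first
        int hi = std::max(i1, i2), lo = std::min(i1, i2);
        bydeme[a][hi] = bydeme[a].back(); bydeme[a].pop_back();
        bydeme[a][lo] = bydeme[a].back(); bydeme[a].pop_back();
        bydeme[a].push_back(par);
        --k;
        done = true;
        break;
      }
      u -= coal[a];
      if (u < mig[a]) {
        int ka = bydeme[a].size();
        int i1 = std::min((int)(rng.unif() * ka), ka - 1);
        int id = bydeme[a][i1];
        double v = rng.unif() * ep.mout[a];
        int b = -1;
        for (int bb = 0; bb < d; ++bb) {
          if (bb == a) continue;
          if (v < ep.M[a * d + bb]) { b = bb; break; }
          v -= ep.M[a * d + bb];
        }
        if (b < 0) b = (a + 1) % d;  // numerical edge
        bydeme[a][i1] = bydeme[a].back(); bydeme[a].pop_back();
        bydeme[b].push_back(id);
        done = true;
        break;
      }
      u -= mig[a];
    }
    if (!done) stop("internal error: event selection failed");
  }
  tr.root = next_node - 1;
}

double tree_length(const Tree& tr) {
  const int n_nodes = 2 * tr.n_tips - 1;
  double total = 0.0;
  for (int i = 0; i < n_nodes; ++i)
    if (i != tr.root) total += tr.tend[i] - tr.tbirth[i];
  return total;
}

// Draw a genealogy with probability proportional to its total branch length
// (the correct conditioning for a locus known to carry one segregating
// mutation under the infinite-sites limit).  Rejection against a cap on the
// total length; trees beyond the cap (vanishingly rare when the cap is set
// from a warm-up sample) are always accepted.
void sim_tree_length_weighted(const std::vector<Epoch>& eps,
                              const std::vector<int>& tip_deme,
                              FastRng& rng, double l_cap, Tree& tr) {
  for (;;) {
    sim_tree(eps, tip_deme, rng, tr);
    double l = tree_length(tr);
    if (l >= l_cap || rng.unif() < l / l_cap) return;
  }
}

// warm-up estimate of the rejection cap
double length_cap(const std::vector<Epoch>& eps,
                  const std::vector<int>& tip_deme, FastRng& rng) {
  Tree tr;
  double mx = 0.0;
  for (int r = 0; r < 200; ++r) {
    sim_tree(eps, tip_deme, rng, tr);
    mx = std::max(mx, tree_length(tr));
  }
  return 3.0 * mx;
}

// Pick one branch proportional to length, return derived tip indicator.
void drop_mutation(const Tree& tr, FastRng& rng,
                   std::vector<int>& derived, std::vector<int>& stack) {
  const int n_nodes = 2 * tr.n_tips - 1;
  double total = 0.0;
  for (int i = 0; i < n_nodes; ++i)
    if (i != tr.root) total += tr.tend[i] - tr.tbirth[i];
  double x = rng.unif() * total;
  int chosen = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (i == tr.root) continue;
    double len = tr.tend[i] - tr.tbirth[i];
    if (x < len) { chosen = i; break; }
    x -= len;
  }
  if (chosen < 0) chosen = (tr.root == 0) ? 1 : 0;
  std::fill(derived.begin(), derived.end(), 0);
  stack.clear();
  stack.push_back(chosen);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < tr.n_tips) {
      derived[v] = 1;
    } else {
      stack.push_back(tr.c1[v]);
      stack.push_back(tr.c2[v]);
    }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".coal_expected_jafs_cpp")]]
List coal_expected_jafs_cpp(int n1, int n2, List epochs, int n_reps,
                            double seed) {
  std::vector<Epoch> eps = parse_epochs(epochs);
  if (n1 < 0 || n2 < 0 || n1 + n2 < 2) stop("need at least two sampled gene copies");
  if (n_reps < 1) stop("n_reps must be >= 1");
  std::vector<int> tip_deme(n1 + n2);
  for (int i = 0; i < n1; ++i) tip_deme[i] = 0;
  for (int i = 0; i < n2; ++i) tip_deme[n1 + i] = (eps[0].d > 1 ? 1 : 0);
  FastRng rng((uint64_t)seed);
  NumericMatrix out(n1 + 1, n2 + 1);
  NumericMatrix sumsq(n1 + 1, n2 + 1);
  const int ncell = (n1 + 1) * (n2 + 1);
  std::vector<double> cell(ncell, 0.0);
  Tree tr;
  const int n = n1 + n2, n_nodes = 2 * n - 1;
  std::vector<int> d1(n_nodes), d2(n_nodes);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
    sim_tree(eps, tip_deme, rng, tr);
    for (int i = 0; i < n; ++i) { d1[i] = (i < n1); d2[i] = (i >= n1); }
    for (int i = n; i < n_nodes; ++i) {
      d1[i] = d1[tr.c1[i]] + d1[tr.c2[i]];
      d2[i] = d2[tr.c1[i]] + d2[tr.c2[i]];
    }
    // per-genealogy cell totals, so the caller can estimate the
    // Monte-Carlo variance of every cell mean
    std::fill(cell.begin(), cell.end(), 0.0);
    for (int i = 0; i < n_nodes; ++i) {
      if (i == tr.root) continue;
      cell[d1[i] + d2[i] * (n1 + 1)] += tr.tend[i] - tr.tbirth[i];
    }
    for (int c = 0; c < ncell; ++c) {
      if (cell[c] > 0) {
        out[c] += cell[c];
        sumsq[c] += cell[c] * cell[c];
      }
    }
  }
  NumericMatrix varm(n1 + 1, n2 + 1);
  for (int c = 0; c < ncell; ++c) {
    out[c] /= n_reps;
    double v = sumsq[c] / n_reps - out[c] * out[c];
    varm[c] = (v > 0 ? v / n_reps : 0.0);
  }
  return List::create(Named("mean") = out, Named("var") = varm);
}

//' @noRd
// [[Rcpp::export(name = ".coal_sim_loci_cpp")]]
IntegerMatrix coal_sim_loci_cpp(IntegerVector tip_deme, List epochs,
                                int n_loci, double seed) {
  std::vector<Epoch> eps = parse_epochs(epochs);
  const int n = tip_deme.size();
  if (n < 2) stop("need at least two sampled gene copies");
  std::vector<int> td(n);
  for (int i = 0; i < n; ++i) td[i] = tip_deme[i] - 1;
  FastRng rng((uint64_t)seed);
  IntegerMatrix out(n, n_loci);
  Tree tr;
  std::vector<int> derived(n), stack;
  double l_cap = length_cap(eps, td, rng);
  for (int l = 0; l < n_loci; ++l) {
    if (l % 512 == 0) Rcpp::checkUserInterrupt();
    sim_tree_length_weighted(eps, td, rng, l_cap, tr);
    drop_mutation(tr, rng, derived, stack);
    for (int i = 0; i < n; ++i) out(i, l) = derived[i];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".coal_sim_genotype_counts_cpp")]]
IntegerMatrix coal_sim_genotype_counts_cpp(IntegerVector pop_sizes_diploid,
                                           IntegerVector pop_deme, List epochs,
                                           int n_loci, double seed) {
  std::vector<Epoch> eps = parse_epochs(epochs);
  const int npop = pop_sizes_diploid.size();
  if ((int)pop_deme.size() != npop) stop("pop_deme length mismatch");
  std::vector<int> td;
  std::vector<int> tip_pop;
  for (int p = 0; p < npop; ++p) {
    for (int i = 0; i < 2 * pop_sizes_diploid[p]; ++i) {
      td.push_back(pop_deme[p] - 1);
      tip_pop.push_back(p);
    }
  }
  const int n = td.size();
  if (n < 2) stop("need at least two sampled gene copies");
  FastRng rng((uint64_t)seed);
  IntegerMatrix out(n_loci, 3 * npop);
  Tree tr;
  std::vector<int> derived(n), stack;
  double l_cap = length_cap(eps, td, rng);
  for (int l = 0; l < n_loci; ++l) {
    if (l % 512 == 0) Rcpp::checkUserInterrupt();
    sim_tree_length_weighted(eps, td, rng, l_cap, tr);
    drop_mutation(tr, rng, derived, stack);
    for (int i = 0; i < n; i += 2) {
      int g = derived[i] + derived[i + 1];
      ++out(l, 3 * tip_pop[i] + g);
    }
  }
  return out;
}
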