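#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over the 7 loss states, vectorised across all 6^G joint
// orthology states, for a batch of distinct pillar presence patterns.
//
// masks:      nPat x G, per-genome presence bitmask (bit t set = track t+1
//             occupied), columns ordered as plan$leaf_seq.
// leafstate:  8 x 6 integer lookup, [mask, perm] -> loss-state index 0..6,
//             or -1 for the all-empty (missing data) mask.
// Pcube:      7*7*nEdge, column-major P(u) per edge in plan edge order.
// ops:        postorder program; row = (is_leaf, genome_col, edge_idx).
//             Internal nodes pop two stack entries; edge_idx = -1 at the root
//             (the root edge is folded into rvec by the caller).
// rvec:       root distribution propagated through the root edge.
//
// Returns an S x nPat matrix (one contiguous emission vector per pattern).
// Combo index convention: leaf digits in `ops` leaf order, first leaf
// fastest (mixed radix base 6), matching the forward kernel's axis order.
//
// Partial-likelihood arrays are memoized per node on the unique sub-patterns
// below that node, so shared subtrees (e.g. a cherry with only 64 possible
// mask pairs) are computed once rather than per pattern.
// [[Rcpp::export]]
NumericMatrix cpp_emissions(IntegerMatrix masks, IntegerMatrix leafstate,
                            NumericVector Pcube, IntegerMatrix ops,
                            NumericVector rvec, int S) {
  const int nPat = masks.nrow();
  const int nOps = ops.nrow();
  NumericMatrix out(S, nPat);
  double* const po = REAL(out);
  const double* const P = REAL(Pcube);
  const double* const rv = REAL(rvec);

  // per op: unique partial arrays (7 x m, column-major, concatenated),
  // combo size m, and each pattern's index into the unique arrays
  std::vector< std::vector<double> > arrays(nOps);
  std::vector< std::vector<int> > patidx(nOps);
  std::vector<int> comboSize(nOps), nUnique(nOps), stack;
  stack.reserve(nOps);
  int root_op = -1;

  for (int o = 0; o < nOps; ++o) {
    if (ops(o, 0) == 1) {                          // leaf
      const int g = ops(o, 1);
      const int e = ops(o, 2);
      int lut[8];
      for (int k = 0; k < 8; ++k) lut[k] = -1;
      std::vector<int>& idx = patidx[o];
      idx.resize(nPat);
      int nu = 0;
      for (int p = 0; p < nPat; ++p) {
        const int mask = masks(p, g);
        if (lut[mask] < 0) lut[mask] = nu++;
        idx[p] = lut[mask];
      }
      arrays[o].assign((size_t)42 * nu, 0.0);
      for (int mask = 0; mask < 8; ++mask) {
        if (lut[mask] < 0) continue;
        double* M = arrays[o].data() + (size_t)42 * lut[mask];
        for (int perm = 0; perm < 6; ++perm) {
          const int st = leafstate(mask, perm);
          if (st < 0) {
            for (int i = 0; i < 7; ++i) M[i + 7 * perm] = 1.0;
          } else {
            const double* col = P + 7 * st + 49 * e;
            for (int i = 0; i < 7; ++i) M[i + 7 * perm] = col[i];
          }
        }
      }
      comboSize[o] = 6;
      nUnique[o] = nu;
      stack.push_back(o);
    } else {                                       // merge two children
      const int e = ops(o, 2);
      const int o2 = stack.back(); stack.pop_back();
      const int o1 = stack.back(); stack.pop_back();
      const int n1 = nUnique[o1], n2 = nUnique[o2];
      const int m1 = comboSize[o1], m2 = comboSize[o2];
      const int m = m1 * m2;
      if (e < 0) {                                 // root: emissions directly
        root_op = o;
        // unique (i1, i2) pairs still matter only through the final matmul;
        // patterns are globally deduplicated so just compute per pattern:
        // out(:, p) = A^T * (diag(rvec) * B), written column-major
        std::vector<double> D((size_t)7 * m2 * n2);
        for (int k = 0; k < n2; ++k) {
          const double* B = arrays[o2].data() + (size_t)7 * m2 * k;
          double* Dk = D.data() + (size_t)7 * m2 * k;
          for (int c = 0; c < m2; ++c)
            for (int i = 0; i < 7; ++i)
              Dk[i + 7 * c] = rv[i] * B[i + 7 * c];
        }
        // cache per unique (i1,i2) pair
        std::vector<int> pairlut((size_t)n1 * n2, -1);
        std::vector<double> cache;
        cache.reserve((size_t)m * std::min(nPat, n1 * n2));
        int ncached = 0;
        for (int p = 0; p < nPat; ++p) {
          const int i1 = patidx[o1][p], i2 = patidx[o2][p];
          const size_t key = (size_t)i1 * n2 + i2;
          int slot = pairlut[key];
          if (slot < 0) {
            slot = ncached++;
            pairlut[key] = slot;
            cache.resize((size_t)m * ncached);
            const double* A = arrays[o1].data() + (size_t)7 * m1 * i1;
            const double* Dk = D.data() + (size_t)7 * m2 * i2;
            double* oc = cache.data() + (size_t)m * slot;
            for (int j2 = 0; j2 < m2; ++j2) {
              const double* d = Dk + 7 * j2;
              double* orow = oc + (size_t)m1 * j2;
              for (int j1 = 0; j1 < m1; ++j1) {
                const double* a = A + 7 * j1;
                double s = 0.0;
                for (int i = 0; i < 7; ++i) s += a[i] * d[i];
                orow[j1] = s;
              }
            }
          }
          std::copy(cache.data() + (size_t)m * slot,
                    cache.data() + (size_t)m * (slot + 1),
                    po + (size_t)p * S);
        }
        arrays[o1].clear(); arrays[o2].clear();
        break;
      }
      // interior merge: memoize on unique child-index pairs
      std::vector<int> pairlut((size_t)n1 * n2, -1);
      std::vector<int>& idx = patidx[o];
      idx.resize(nPat);
      int nu = 0;
      for (int p = 0; p < nPat; ++p) {
        const size_t key = (size_t)patidx[o1][p] * n2 + patidx[o2][p];
        if (pairlut[key] < 0) pairlut[key] = nu++;
        idx[p] = pairlut[key];
      }
      arrays[o].assign((size_t)7 * m * nu, 0.0);
      const double* Pe = P + 49 * e;
      for (size_t key = 0; key < (size_t)n1 * n2; ++key) {
        const int slot = pairlut[key];
        if (slot < 0) continue;
        const int i1 = (int)(key / n2), i2 = (int)(key % n2);
        const double* L = arrays[o1].data() + (size_t)7 * m1 * i1;
        const double* R = arrays[o2].data() + (size_t)7 * m2 * i2;
        double* C = arrays[o].data() + (size_t)7 * m * slot;
        for (int j2 = 0; j2 < m2; ++j2) {
          const double* r2 = R + 7 * j2;
          double* Cb = C + (size_t)7 * m1 * j2;
          for (int j1 = 0; j1 < m1; ++j1) {
            const double* l1 = L + 7 * j1;
            double* c = Cb + 7 * j1;
            double prod[7];
            for (int i = 0; i < 7; ++i) prod[i] = l1[i] * r2[i];
            for (int i = 0; i < 7; ++i) {
              double s = 0.0;
              for (int j = 0; j < 7; ++j) s += Pe[i + 7 * j] * prod[j];
              c[i] = s;
            }
          }
        }
      }
      comboSize[o] = m;
      nUnique[o] = nu;
      arrays[o1].clear(); arrays[o2].clear();
      stack.push_back(o);
    }
  }
  if (root_op < 0) {
    // degenerate single-leaf tree: the only op is a leaf; finish with rvec
    const int o = nOps - 1;
    for (int p = 0; p < nPat; ++p) {
      const double* M = arrays[o].data() + (size_t)42 * patidx[o][p];
      double* ocol = po + (size_t)p * S;
      for (int c = 0; c < 6; ++c) {
        const double* col = M + 7 * c;
        double s = 0.0;
        for (int i = 0; i < 7; ++i) s += rv[i] * col[i];
        ocol[c] = s;
      }
    }
  }
  return out;
}

// Per-genome HMM transition kernel A = (1-theta) I + (theta/5)(J - I) applied
// along every genome axis of the 6^G state vector, in place.
static void apply_kernel(double* f, int S, int G, double theta) {
  const double c1 = 1.0 - theta - theta / 5.0;
  const double c2 = theta / 5.0;
  int stride = 1;
  for (int g = 0; g < G; ++g) {
    const int bigstride = stride * 6;
    for (int h = 0; h < S; h += bigstride) {
      for (int l = 0; l < stride; ++l) {
        double* base = f + h + l;
        double s = base[0];
        for (int j = 1; j < 6; ++j) s += base[j * stride];
        const double add = c2 * s;
        for (int j = 0; j < 6; ++j) {
          double* x = base + j * stride;
          *x = c1 * *x + add;
        }
      }
    }
    stride = bigstride;
  }
}

// Scaled forward recursion; uniform initial distribution, re-initialised at
// contiguity breaks (new_block). emis is S x nPat. Returns the ln-likelihood.
// [[Rcpp::export]]
double cpp_forward_loglik(NumericMatrix emis, IntegerVector pat,
                          LogicalVector new_block, double theta, int G) {
  const int S = emis.nrow();
  const int n = pat.size();
  const double* const E = REAL(emis);
  std::vector<double> fv((size_t)S);
  double* f = fv.data();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (new_block[t]) {
      const double u0 = 1.0 / S;
      for (int s = 0; s < S; ++s) f[s] = u0;
    } else {
      apply_kernel(f, S, G, theta);
    }
    const double* e = E + (size_t)pat[t] * S;
    double sc = 0.0;
    for (int s = 0; s < S; ++s) { f[s] *= e[s]; sc += f[s]; }
    if (!(sc > 0.0)) return R_NegInf;
    ll += std::log(sc);
    const double inv = 1.0 / sc;
    for (int s = 0; s < S; ++s) f[s] *= inv;
  }
  return ll;
}

// Forward-backward posterior decoding. Returns the forward ln-likelihood,
// per-genome marginal posteriors over the 6 permutations (n x 6G), the MAP
// joint state (0-based) with its posterior, and optionally the full joint
// posterior (n x S).
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix emis, IntegerVector pat,
                          LogicalVector new_block, double theta, int G,
                          bool return_joint) {
  const int S = emis.nrow();
  const int n = pat.size();
  const double* const E = REAL(emis);
  std::vector<double> alpha((size_t)S * n), scales(n);
  double ll = 0.0;
  {
    std::vector<double> fv((size_t)S);
    double* f = fv.data();
    for (int t = 0; t < n; ++t) {
      if (new_block[t]) {
        const double u0 = 1.0 / S;
        for (int s = 0; s < S; ++s) f[s] = u0;
      } else {
        apply_kernel(f, S, G, theta);
      }
      const double* e = E + (size_t)pat[t] * S;
      double sc = 0.0;
      for (int s = 0; s < S; ++s) { f[s] *= e[s]; sc += f[s]; }
      if (!(sc > 0.0)) stop("zero forward mass at pillar %d", t + 1);
      ll += std::log(sc);
      const double inv = 1.0 / sc;
      double* a = alpha.data() + (size_t)S * t;
      for (int s = 0; s < S; ++s) { f[s] *= inv; a[s] = f[s]; }
      scales[t] = sc;
    }
  }
  NumericMatrix joint = return_joint ? NumericMatrix(n, S) : NumericMatrix(0, 0);
  NumericMatrix marg(n, G * 6);
  IntegerVector map_idx(n);
  NumericVector map_prob(n);
  std::vector<double> b((size_t)S, 1.0), tmp((size_t)S);
  for (int t = n - 1; t >= 0; --t) {
    const bool block_end = (t == n - 1) || new_block[t + 1];
    if (block_end) {
      std::fill(b.begin(), b.end(), 1.0);
    } else {
      const double* e1 = E + (size_t)pat[t + 1] * S;
      for (int s = 0; s < S; ++s) tmp[s] = b[s] * e1[s];
      apply_kernel(tmp.data(), S, G, theta);
      const double inv = 1.0 / scales[t + 1];
      for (int s = 0; s < S; ++s) b[s] = tmp[s] * inv;
    }
    const double* a = alpha.data() + (size_t)S * t;
    double tot = 0.0;
    int best = 0; double bestv = -1.0;
    for (int s = 0; s < S; ++s) {
      const double v = a[s] * b[s];
      tot += v;
      if (v > bestv) { bestv = v; best = s; }
    }
    const double inv = 1.0 / tot;
    for (int s = 0; s < S; ++s) {
      const double v = a[s] * b[s] * inv;
      if (return_joint) joint(t, s) = v;
      int code = s;
      for (int g = 0; g < G; ++g) {
        marg(t, g * 6 + (code % 6)) += v;
        code /= 6;
      }
    }
    map_idx[t] = best;
    map_prob[t] = bestv * inv;
  }
  return List::create(_["loglik"] = ll, _["marg"] = marg,
                      _["map_idx"] = map_idx, _["map_prob"] = map_prob,
                      _["joint"] = joint);
}

// Backward-only ln-likelihood (independent recursion direction, used to check
// the forward/backward identity).
// [[Rcpp::export]]
double cpp_backward_loglik(NumericMatrix emis, IntegerVector pat,
                           LogicalVector new_block, double theta, int G) {
  const int S = emis.nrow();
  const int n = pat.size();
  const double* const E = REAL(emis);
  std::vector<double> b((size_t)S, 1.0), tmp((size_t)S);
  double ll = 0.0;
  for (int t = n - 1; t >= 0; --t) {
    const double* e = E + (size_t)pat[t] * S;
    for (int s = 0; s < S; ++s) tmp[s] = b[s] * e[s];
    if (new_block[t]) {
      double m = 0.0;
      for (int s = 0; s < S; ++s) m += tmp[s];
      m /= (double)S;
      if (!(m > 0.0)) return R_NegInf;
      ll += std::log(m);
      std::fill(b.begin(), b.end(), 1.0);
    } else {
      apply_kernel(tmp.data(), S, G, theta);
      double mx = 0.0;
      for (int s = 0; s < S; ++s) if (tmp[s] > mx) mx = tmp[s];
      if (!(mx > 0.0)) return R_NegInf;
      ll += std::log(mx);
      const double inv = 1.0 / mx;
      for (int s = 0; s < S; ++s) b[s] = tmp[s] * inv;
    }
  }
  return ll;
}
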