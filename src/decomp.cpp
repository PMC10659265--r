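#include <RcppArmadillo.h>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Proximal operator of step * (lambda * sum_g ||a_g||_2 + indicator(a >= 0)):
// Euclidean projection onto the nonnegative orthant followed by groupwise
// soft-thresholding of the norm. Correctness is established against
// independent oracles in the test suite rather than assumed.
static vec prox_nngl(const vec& v, double thr, const std::vector<uvec>& gidx) {
  vec a = v;
  a.transform([](double x) { return x > 0.0 ? x : 0.0; });
  for (size_t g = 0; g < gidx.size(); ++g) {
    double nrm = norm(a(gidx[g]), 2);
    if (nrm <= thr) {
      a(gidx[g]).zeros();
    } else {
      a(gidx[g]) *= (1.0 - thr / nrm);
    }
  }
  return a;
}

static std::vector<uvec> group_index(const ivec& groups) {
  int ng = groups.max() + 1;
  std::vector<uvec> gidx(ng);
  for (int g = 0; g < ng; ++g) gidx[g] = find(groups == g);
  return gidx;
}

// General FISTA on 0.5*||D a - y||^2 + lambda * sum_g ||a_g||, a >= 0.
// [[Rcpp::export]]
arma::vec cpp_fista_group_lasso(const arma::mat& D, const arma::vec& y,
                                double lambda, const arma::ivec& groups,
                                double tol, int maxit) {
  mat G = D.t() * D;
  vec b = D.t() * y;
  vec ev = eig_sym(G);
  double L = ev.max();
  if (L <= 0.0) L = 1.0;
  double step = 1.0 / L;
  std::vector<uvec> gidx = group_index(groups);
  int C = G.n_rows;
  vec a(C, fill::zeros), z(C, fill::zeros), a_old;
  double tk = 1.0;
  for (int it = 0; it < maxit; ++it) {
    a_old = a;
    vec grad = G * z - b;
    a = prox_nngl(z - step * grad, step * lambda, gidx);
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    z = a + ((tk - 1.0) / tk1) * (a - a_old);
    tk = tk1;
    double sc = std::max(1.0, norm(a, "inf"));
    if (norm(a - a_old, "inf") < tol * sc) break;
  }
  return a;
}

// ---- allocation-free small-problem machinery for the shift search ------

#define MAXC 4

struct SmallProb {
  int C;
  int ng;                 // number of groups
  int gid[MAXC];          // group id per coordinate
  double G[MAXC][MAXC];
  double b[MAXC];
  double lambda;
  double step;
};

// FISTA specialized for C <= MAXC coordinates; returns the attained value
// of 0.5 a'Ga - b'a + lambda * sum_g ||a_g||; amplitudes written to a_out.
static double fista_small(const SmallProb& P, double tol, int maxit,
                          double* a_out) {
  const int C = P.C;
  double a[MAXC] = {0}, z[MAXC] = {0}, a_old[MAXC], grad[MAXC], gn[MAXC];
  double tk = 1.0;
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < C; ++i) a_old[i] = a[i];
    for (int i = 0; i < C; ++i) {
      double s = -P.b[i];
      for (int j = 0; j < C; ++j) s += P.G[i][j] * z[j];
      grad[i] = s;
    }
    double thr = P.step * P.lambda;
    for (int i = 0; i < C; ++i) {
      double v = z[i] - P.step * grad[i];
      a[i] = v > 0.0 ? v : 0.0;
    }
    for (int g = 0; g < P.ng; ++g) gn[g] = 0.0;
    for (int i = 0; i < C; ++i) gn[P.gid[i]] += a[i] * a[i];
    for (int g = 0; g < P.ng; ++g) gn[g] = std::sqrt(gn[g]);
    for (int i = 0; i < C; ++i) {
      double n = gn[P.gid[i]];
      a[i] = (n <= thr) ? 0.0 : a[i] * (1.0 - thr / n);
    }
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double mom = (tk - 1.0) / tk1;
    double diff = 0.0, amax = 1.0;
    for (int i = 0; i < C; ++i) {
      z[i] = a[i] + mom * (a[i] - a_old[i]);
      diff = std::max(diff, std::fabs(a[i] - a_old[i]));
      amax = std::max(amax, std::fabs(a[i]));
    }
    tk = tk1;
    if (diff < tol * amax) break;
  }
  double quad = 0.0, lin = 0.0;
  for (int i = 0; i < C; ++i) {
    lin += P.b[i] * a[i];
    for (int j = 0; j < C; ++j) quad += a[i] * P.G[i][j] * a[j];
  }
  for (int g = 0; g < P.ng; ++g) gn[g] = 0.0;
  for (int i = 0; i < C; ++i) gn[P.gid[i]] += a[i] * a[i];
  double pen = 0.0;
  for (int g = 0; g < P.ng; ++g) pen += std::sqrt(gn[g]);
  if (a_out) for (int i = 0; i < C; ++i) a_out[i] = a[i];
  return 0.5 * quad - lin + P.lambda * pen;
}

struct Combo {
  double obj;
  int tau[MAXC];
};

struct SearchCtx {
  int C, T;
  const cube* Rcc;  // C x C x T basis cross-correlations
  const mat* xc;    // C x T trace correlations
  double lambda, step;
  int ng;
  int gid[MAXC];
};

static double eval_tau(const SearchCtx& S, const int* tau, double tol,
                       int maxit, double* a_out) {
  SmallProb P;
  P.C = S.C; P.ng = S.ng; P.lambda = S.lambda; P.step = S.step;
  for (int i = 0; i < S.C; ++i) P.gid[i] = S.gid[i];
  const int T = S.T;
  for (int c = 0; c < S.C; ++c) {
    int tc = ((tau[c] % T) + T) % T;
    P.b[c] = (*S.xc)(c, tc);
    for (int d = 0; d < S.C; ++d) {
      int delta = (((tau[d] - tau[c]) % T) + T) % T;
      P.G[c][d] = (*S.Rcc)(c, d, delta);
    }
  }
  return fista_small(P, tol, maxit, a_out);
}

static void keep_top(std::vector<Combo>& pool, size_t n_keep) {
  std::stable_sort(pool.begin(), pool.end(),
                   [](const Combo& a, const Combo& b) { return a.obj < b.obj; });
  if (pool.size() > n_keep) pool.resize(n_keep);
}

static long long combo_key(const int* tau, int C, int T) {
  long long k = 0;
  for (int c = 0; c < C; ++c) k = k * (2 * T + 1) + (tau[c] + T);
  return k;
}

static Combo search_electrode(const SearchCtx& S, const ivec& lo,
                              const ivec& hi, bool exhaustive, int stride,
                              int n_keep, int marg_m, long long auto_cap,
                              const int* prev_tau, bool has_prev,
                              double tol_search, int maxit_search,
                              const std::vector<bool>& active) {
  const int C = S.C, T = S.T;
  if (!exhaustive && auto_cap > 0) {
    // exact enumeration whenever the combination count is affordable;
    // the heuristic schedule exists for the large search spaces
    long long total = 1;
    for (int c = 0; c < C; ++c) {
      if (active[c]) total *= (long long)(hi(c) - lo(c) + 1);
      if (total > auto_cap) break;
    }
    if (total <= auto_cap) exhaustive = true;
  }
  std::vector<std::vector<int>> cand(C);
  for (int c = 0; c < C; ++c) {
    if (!active[c]) {
      cand[c].push_back(lo(c));
    } else if (exhaustive) {
      for (int t = lo(c); t <= hi(c); ++t) cand[c].push_back(t);
    } else {
      std::set<int> s;
      // safety grid (adaptive step so wide ranges stay tractable); dense
      // coverage is delegated to the correlation-guided candidates and to
      // the coordinate / pairwise polish
      int gstep = std::max(stride, (hi(c) - lo(c) + 1) / 8);
      for (int t = lo(c); t <= hi(c); t += gstep) s.insert(t);
      s.insert(hi(c));
      // correlation-guided candidates: matched-filter responses locate the
      // shift basins that a blind coarse grid misses for brief waveforms
      std::vector<std::pair<double, int>> sc;
      for (int t = lo(c); t <= hi(c); ++t) {
        int tm = ((t % T) + T) % T;
        sc.push_back(std::make_pair(-(*S.xc)(c, tm), t));
      }
      std::stable_sort(sc.begin(), sc.end());
      int m = std::min((size_t)marg_m, sc.size());
      for (int i = 0; i < m; ++i) s.insert(sc[i].second);
      cand[c].assign(s.begin(), s.end());
    }
  }

  std::vector<Combo> pool;
  size_t total = 1;
  for (int c = 0; c < C; ++c) total *= cand[c].size();
  pool.reserve(exhaustive ? std::min(total, (size_t)4096) : total);

  std::vector<Combo> mp_starts;
  if (!exhaustive) {
    // matching-pursuit multi-starts: add compartments one at a time (all
    // orders), each at the shift maximizing its correlation with the
    // residual of the already-selected compartments; handles weak
    // compartments masked by strong superimposed ones
    std::vector<int> order(C);
    for (int c = 0; c < C; ++c) order[c] = c;
    std::sort(order.begin(), order.end());
    do {
      SmallProb P;
      P.C = C; P.ng = S.ng; P.lambda = S.lambda; P.step = S.step;
      for (int i = 0; i < C; ++i) P.gid[i] = S.gid[i];
      // start with every coordinate pinned (b = 0, unit diagonal)
      for (int i = 0; i < C; ++i) {
        P.b[i] = 0.0;
        for (int j = 0; j < C; ++j) P.G[i][j] = (i == j) ? 1.0 : 0.0;
      }
      Combo st;
      for (int c = 0; c < C; ++c) st.tau[c] = lo(c);
      double a_cur[MAXC] = {0};
      std::vector<int> sel;
      for (int oi = 0; oi < C; ++oi) {
        int c = order[oi];
        if (!active[c]) continue;
        // residual correlation: xc_c(tau) - sum_j a_j R_{j,c}(tau - tau_j)
        double best_v = -datum::inf;
        int best_t = lo(c);
        for (int t = lo(c); t <= hi(c); ++t) {
          int tm = ((t % T) + T) % T;
          double v = (*S.xc)(c, tm);
          for (int j : sel) {
            if (a_cur[j] == 0.0) continue;
            int delta = (((t - st.tau[j]) % T) + T) % T;
            v -= a_cur[j] * (*S.Rcc)(j, c, delta);
          }
          if (v > best_v) { best_v = v; best_t = t; }
        }
        st.tau[c] = best_t;
        sel.push_back(c);
        // refit amplitudes over the selected compartments
        for (int i : sel) {
          int ti = ((st.tau[i] % T) + T) % T;
          P.b[i] = (*S.xc)(i, ti);
          for (int j : sel) {
            int delta = (((st.tau[j] - st.tau[i]) % T) + T) % T;
            P.G[i][j] = (*S.Rcc)(i, j, delta);
          }
        }
        fista_small(P, tol_search, maxit_search, a_cur);
      }
      st.obj = eval_tau(S, st.tau, tol_search, maxit_search, nullptr);
      mp_starts.push_back(st);
    } while (std::next_permutation(order.begin(), order.end()));
  }

  Combo cur;
  std::vector<size_t> idx(C, 0);
  Combo best_ex;
  best_ex.obj = datum::inf;
  bool done = false;
  while (!done) {
    for (int c = 0; c < C; ++c) cur.tau[c] = cand[c][idx[c]];
    cur.obj = eval_tau(S, cur.tau, tol_search, maxit_search, nullptr);
    if (exhaustive) {
      if (cur.obj < best_ex.obj) best_ex = cur;
    } else {
      pool.push_back(cur);
    }
    int c = C - 1;
    while (c >= 0) {
      if (++idx[c] < cand[c].size()) break;
      idx[c] = 0;
      --c;
    }
    if (c < 0) done = true;
  }
  if (exhaustive) {
    pool.push_back(best_ex);
  }
  keep_top(pool, exhaustive ? 1 : (size_t)std::max(n_keep, 1));
  // the matching-pursuit starts always survive into refinement and polish
  for (auto& st : mp_starts) pool.push_back(st);
  std::stable_sort(pool.begin(), pool.end(),
                   [](const Combo& a, const Combo& b) { return a.obj < b.obj; });

  if (!exhaustive) {
    // stride-halving refinement around survivors
    for (int s = stride / 2; s >= 1; s /= 2) {
      std::set<long long> seen;
      for (auto& cd : pool) seen.insert(combo_key(cd.tau, C, T));
      size_t n0 = pool.size();
      int offs[3] = {-s, 0, s};
      for (size_t q = 0; q < n0; ++q) {
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            for (int k = 0; k < 3; ++k) {
              Combo c2 = pool[q];
              int oo[3] = {offs[i], offs[j], offs[k]};
              for (int c = 0; c < C && c < 3; ++c) {
                if (!active[c]) continue;
                c2.tau[c] = std::min(std::max(pool[q].tau[c] + oo[c],
                                              (int)lo(c)), (int)hi(c));
              }
              long long key = combo_key(c2.tau, C, T);
              if (seen.count(key)) continue;
              seen.insert(key);
              c2.obj = eval_tau(S, c2.tau, tol_search, maxit_search, nullptr);
              pool.push_back(c2);
            }
      }
      keep_top(pool, (size_t)std::max(n_keep, 1));
    }
    // coordinate-wise exhaustive polish: sweep each compartment's shift
    // over its full range holding the others fixed; rescues weak
    // compartments whose marginal correlation is masked by a stronger
    // superimposed one
    for (size_t q = 0; q < pool.size(); ++q) {
      Combo& cd = pool[q];
      bool improved = true;
      int sweeps = 0;
      while (improved && sweeps < 4) {
        improved = false;
        ++sweeps;
        for (int c = 0; c < C; ++c) {
          if (!active[c]) continue;
          Combo c2 = cd;
          for (int t = lo(c); t <= hi(c); ++t) {
            if (t == cd.tau[c]) continue;
            c2.tau[c] = t;
            c2.obj = eval_tau(S, c2.tau, tol_search, maxit_search, nullptr);
            if (c2.obj < cd.obj - 1e-14) {
              cd = c2;
              improved = true;
            }
          }
        }
        // pairwise sweeps over candidate lists (top survivors only):
        // escapes jointly-displaced pairs of compartments
        if (q < 3) {
          for (int c = 0; c < C; ++c) {
            if (!active[c]) continue;
            for (int d = c + 1; d < C; ++d) {
              if (!active[d]) continue;
              Combo c2 = cd;
              for (int tc : cand[c]) {
                for (int td : cand[d]) {
                  if (tc == cd.tau[c] && td == cd.tau[d]) continue;
                  c2.tau[c] = tc;
                  c2.tau[d] = td;
                  c2.obj = eval_tau(S, c2.tau, tol_search, maxit_search,
                                    nullptr);
                  if (c2.obj < cd.obj - 1e-14) {
                    cd = c2;
                    improved = true;
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  if (has_prev) {
    Combo pc;
    for (int c = 0; c < C; ++c) pc.tau[c] = prev_tau[c];
    pc.obj = eval_tau(S, pc.tau, tol_search, maxit_search, nullptr);
    pool.push_back(pc);
  }
  keep_top(pool, 3);
  if (!exhaustive) {
    // full-range pairwise sweep on the top candidates: escapes "label
    // swap" optima (compartments impersonating each other's peaks) that
    // no sequence of single-compartment moves can cross
    for (size_t q = 0; q < pool.size(); ++q) {
    Combo& cd = pool[q];
    for (int round = 0; round < 2; ++round) {
      bool improved = false;
      for (int c = 0; c < C; ++c) {
        if (!active[c]) continue;
        for (int d = c + 1; d < C; ++d) {
          if (!active[d]) continue;
          // bounded-budget lattice: swap basins are several samples wide
          // (the template main-lobe width), so a stride-sp lattice finds
          // them and the coordinate settle recovers the exact offsets
          double npair = (double)(hi(c) - lo(c) + 1) * (hi(d) - lo(d) + 1);
          int sp = (int)std::ceil(std::sqrt(npair / 8192.0));
          if (sp < 1) sp = 1;
          Combo c2 = cd;
          for (int tc = lo(c); tc <= hi(c); tc += sp) {
            c2.tau[c] = tc;
            for (int td = lo(d); td <= hi(d); td += sp) {
              if (tc == cd.tau[c] && td == cd.tau[d]) continue;
              c2.tau[d] = td;
              c2.obj = eval_tau(S, c2.tau, tol_search, maxit_search, nullptr);
              if (c2.obj < cd.obj - 1e-14) {
                cd = c2;
                improved = true;
              }
            }
            c2.tau[d] = cd.tau[d];
          }
        }
      }
      if (!improved) break;
      // settle with another round of single-coordinate sweeps
      for (int c = 0; c < C; ++c) {
        if (!active[c]) continue;
        Combo c2 = cd;
        for (int t = lo(c); t <= hi(c); ++t) {
          if (t == cd.tau[c]) continue;
          c2.tau[c] = t;
          c2.obj = eval_tau(S, c2.tau, tol_search, maxit_search, nullptr);
          if (c2.obj < cd.obj - 1e-14) cd = c2;
        }
      }
    }
    }
    keep_top(pool, 1);
  }
  return pool[0];
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_electrodes(const arma::mat& X, const arma::mat& Bw,
                              double lambda, const arma::ivec& groups,
                              const arma::ivec& lo, const arma::ivec& hi,
                              bool exhaustive, int stride, int n_keep,
                              int marg_m, double auto_cap,
                              const arma::imat& prev_tau,
                              double tol_search, int maxit_search,
                              double tol_final, int maxit_final) {
  int C = Bw.n_rows, T = Bw.n_cols, N = X.n_cols;
  if (C > MAXC) Rcpp::stop("at most %d compartments are supported", MAXC);

  // circular cross-correlations between basis rows:
  // Rcc(c,d,delta) = sum_t B_c[t] * B_d[(t - delta) mod T]
  cube Rcc(C, C, T);
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < C; ++d)
      for (int delta = 0; delta < T; ++delta) {
        double s = 0.0;
        for (int t = 0; t < T; ++t) s += Bw(c, t) * Bw(d, (t - delta + T) % T);
        Rcc(c, d, delta) = s;
      }

  std::vector<bool> active(C);
  double tr = 0.0;
  for (int c = 0; c < C; ++c) {
    active[c] = norm(Bw.row(c), 2) > 0.0;
    tr += Rcc(c, c, 0);
  }

  bool has_prev = prev_tau.n_cols == (uword)N && prev_tau.n_rows == (uword)C;

  mat A(C, N, fill::zeros);
  imat tau_out(C, N, fill::zeros);
  vec obj(N);
  SearchCtx S;
  S.C = C; S.T = T; S.Rcc = &Rcc; S.lambda = lambda;
  // PSD Gram: lambda_max <= trace, shared across all shift combinations
  S.step = tr > 0.0 ? 1.0 / tr : 1.0;
  S.ng = groups.max() + 1;
  for (int c = 0; c < C; ++c) S.gid[c] = groups(c);

  for (int n = 0; n < N; ++n) {
    vec x = X.col(n);
    mat xc(C, T);
    for (int c = 0; c < C; ++c)
      for (int tshift = 0; tshift < T; ++tshift) {
        double s = 0.0;
        for (int t = 0; t < T; ++t) s += Bw(c, (t - tshift + T) % T) * x(t);
        xc(c, tshift) = s;
      }
    S.xc = &xc;
    int pv[MAXC] = {0};
    if (has_prev) for (int c = 0; c < C; ++c) pv[c] = prev_tau(c, n);
    Combo best = search_electrode(S, lo, hi, exhaustive, stride, n_keep,
                                  marg_m, (long long)auto_cap, pv, has_prev,
                                  tol_search, maxit_search, active);
    double a_fin[MAXC];
    double obj_fin = eval_tau(S, best.tau, tol_final, maxit_final, a_fin);
    if (obj_fin > best.obj) {
      obj_fin = eval_tau(S, best.tau, tol_search, maxit_search, a_fin);
    }
    for (int c = 0; c < C; ++c) {
      A(c, n) = a_fin[c];
      tau_out(c, n) = ((best.tau[c] % T) + T) % T;
    }
    obj(n) = obj_fin + 0.5 * dot(x, x);
  }
  return Rcpp::List::create(Rcpp::Named("amplitudes") = A,
                            Rcpp::Named("shifts") = tau_out,
                            Rcpp::Named("objective") = obj);
}
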