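#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <string>
#include <vector>
#include "sketch_common.h"
using namespace Rcpp;

double dist_regmatch_cpp(NumericVector a, NumericVector b);
double setsketch_lsh_cpp(NumericVector a, NumericVector b, double base);
double setsketch_jmle_cpp(NumericVector Ka, NumericVector Kb, double base, double a);

// Distance over register vectors (columns of the sketch matrix), with an
// evaluation counter so query cost can be audited.
struct DistCtx {
  int type;  // 0 register_match, 1 setsketch_lsh, 2 setsketch_jmle
  double base, a;
  const double* S;
  int m;
  long long count;

  double raw(const double* x, const double* y) {
    ++count;
    if (type == 0) {
      int eq = 0;
      for (int t = 0; t < m; ++t) eq += (x[t] == y[t]);
      return 1.0 - (double)eq / (double)m;
    }
    NumericVector xv(x, x + m), yv(y, y + m);
    if (type == 1) return setsketch_lsh_cpp(xv, yv, base);
    return setsketch_jmle_cpp(xv, yv, base, a);
  }
  double node(int i, int j) { return raw(S + (size_t)i * m, S + (size_t)j * m); }
  double toq(const double* q, int j) { return raw(q, S + (size_t)j * m); }
};

static int dist_type_from_tag(const std::string& tag) {
  if (tag == "register_match") return 0;
  if (tag == "setsketch_lsh") return 1;
  if (tag == "setsketch_jmle") return 2;
  stop("unknown distance tag: %s", tag.c_str());
}

typedef std::pair<double, int> DI;  // (distance, ordinal); ties broken on ordinal

struct Hnsw {
  int N, M, efc;
  double mL;
  uint64_t seed;
  int entry, maxlevel;
  std::vector<int> level;
  std::vector<std::vector<std::vector<int> > > adj;  // [layer][node] -> neighbours
  DistCtx* D;
  std::vector<uint32_t> visited;
  uint32_t vepoch;

  int cap(int l) const { return l == 0 ? 2 * M : M; }

  int draw_level(int ordinal) const {
    SxRng rng(sx_hash64((uint64_t)ordinal + 1ULL, seed ^ 0xC2B2AE3D27D4EB4FULL));
    double u = rng.unif();
    int lev = (int)std::floor(-std::log(u) * mL);
    return lev < 0 ? 0 : lev;
  }

  void ensure_layers(int l) {
    while ((int)adj.size() <= l) adj.push_back(std::vector<std::vector<int> >(N));
  }

  // beam search at one layer; returns candidates sorted ascending (dist, ord)
  std::vector<DI> search_layer(const double* q, const std::vector<DI>& eps,
                               int ef, int l) {
    ++vepoch;
    std::priority_queue<DI, std::vector<DI>, std::greater<DI> > cand;
    std::priority_queue<DI> res;  // max-heap: worst of the ef best on top
    for (size_t i = 0; i < eps.size(); ++i) {
      if (visited[eps[i].second] == vepoch) continue;
      visited[eps[i].second] = vepoch;
      cand.push(eps[i]);
      res.push(eps[i]);
      if ((int)res.size() > ef) res.pop();
    }
    while (!cand.empty()) {
      DI c = cand.top();
      cand.pop();
      if ((int)res.size() >= ef && c.first > res.top().first) break;
      const std::vector<int>& nb = adj[l][c.second];
      for (size_t t = 0; t < nb.size(); ++t) {
        int e = nb[t];
        if (visited[e] == vepoch) continue;
        visited[e] = vepoch;
        double d = D->toq(q, e);
        if ((int)res.size() < ef || d < res.top().first ||
            (d == res.top().first && e < res.top().second)) {
          cand.push(DI(d, e));
          res.push(DI(d, e));
          if ((int)res.size() > ef) res.pop();
        }
      }
    }
    std::vector<DI> out;
    out.reserve(res.size());
    while (!res.empty()) {
      out.push_back(res.top());
      res.pop();
    }
    std::sort(out.begin(), out.end());
    return out;
  }

  // Malkov-style selection: keep a candidate only if it is closer to the
  // target than to every already kept neighbour; fall back to nearest-first
  // fill if fewer than mx survive.
  std::vector<DI> select_neighbors(const std::vector<DI>& cands, int mx) {
    std::vector<DI> kept;
    std::vector<DI> dropped;
    for (size_t i = 0; i < cands.size() && (int)kept.size() < mx; ++i) {
      bool good = true;
      for (size_t s = 0; s < kept.size(); ++s) {
        if (D->node(cands[i].second, kept[s].second) < cands[i].first) {
          good = false;
          break;
        }
      }
      if (good) kept.push_back(cands[i]);
      else dropped.push_back(cands[i]);
    }
    for (size_t i = 0; i < dropped.size() && (int)kept.size() < mx; ++i)
      kept.push_back(dropped[i]);
    return kept;
  }

  void prune(int e, int l, const double* Se) {
    std::vector<DI> cands;
    const std::vector<int>& nb = adj[l][e];
    cands.reserve(nb.size());
    for (size_t t = 0; t < nb.size(); ++t)
      cands.push_back(DI(D->node(e, nb[t]), nb[t]));
    std::sort(cands.begin(), cands.end());
    std::vector<DI> kept = select_neighbors(cands, cap(l));
    std::vector<int> newnb;
    newnb.reserve(kept.size());
    for (size_t t = 0; t < kept.size(); ++t) newnb.push_back(kept[t].second);
    adj[l][e] = newnb;
    (void)Se;
  }

  void insert(int i, bool first) {
    int lev = level[i];
    ensure_layers(lev);
    if (first) {
      entry = i;
      maxlevel = lev;
      return;
    }
    const double* q = D->S + (size_t)i * D->m;
    int ep = entry;
    double epd = D->toq(q, ep);
    for (int l = maxlevel; l > lev; --l) {  // greedy descent above own level
      bool moved = true;
      while (moved) {
        moved = false;
        const std::vector<int>& nb = adj[l][ep];
        for (size_t t = 0; t < nb.size(); ++t) {
          double d = D->toq(q, nb[t]);
          if (d < epd || (d == epd && nb[t] < ep)) {
            epd = d;
            ep = nb[t];
            moved = true;
          }
        }
      }
    }
    std::vector<DI> eps(1, DI(epd, ep));
    for (int l = std::min(lev, maxlevel); l >= 0; --l) {
      std::vector<DI> W = search_layer(q, eps, efc, l);
      std::vector<DI> nbrs = select_neighbors(W, cap(l));
      for (size_t t = 0; t < nbrs.size(); ++t) {
        int e = nbrs[t].second;
        adj[l][i].push_back(e);
        adj[l][e].push_back(i);  // reverse update
        if ((int)adj[l][e].size() > cap(l)) prune(e, l, NULL);
      }
      eps = W;
    }
    if (lev > maxlevel) {
      maxlevel = lev;
      entry = i;
    }
  }
};

static Hnsw make_hnsw(const NumericMatrix& S, int M, int efc, double mL,
                      double seed, DistCtx* D) {
  Hnsw g;
  g.N = S.ncol();
  g.M = M;
  g.efc = efc;
  g.mL = mL;
  g.seed = (uint64_t)(int64_t)seed;
  g.entry = -1;
  g.maxlevel = -1;
  g.D = D;
  g.level.resize(g.N);
  g.visited.assign(g.N, 0);
  g.vepoch = 0;
  return g;
}

static List hnsw_to_list(const Hnsw& g, long long ndist) {
  IntegerVector lev(g.N);
  for (int i = 0; i < g.N; ++i) lev[i] = g.level[i];
  List layers(g.adj.size());
  for (size_t l = 0; l < g.adj.size(); ++l) {
    List nodes(g.N);
    for (int i = 0; i < g.N; ++i) {
      const std::vector<int>& nb = g.adj[l][i];
      IntegerVector v(nb.size());
      for (size_t t = 0; t < nb.size(); ++t) v[t] = nb[t] + 1;  // 1-based
      nodes[i] = v;
    }
    layers[l] = nodes;
  }
  return List::create(_["levels"] = lev, _["entry"] = g.entry + 1,
                      _["max_level"] = g.maxlevel, _["adjacency"] = layers,
                      _["n_dist_evals"] = (double)ndist);
}

static void hnsw_from_list(Hnsw& g, const List& gl, int n_keep) {
  IntegerVector lev = gl["levels"];
  for (int i = 0; i < n_keep; ++i) g.level[i] = lev[i];
  g.entry = as<int>(gl["entry"]) - 1;
  g.maxlevel = as<int>(gl["max_level"]);
  List layers = gl["adjacency"];
  g.ensure_layers((int)layers.size() - 1);
  for (int l = 0; l < (int)layers.size(); ++l) {
    List nodes = layers[l];
    for (int i = 0; i < n_keep; ++i) {
      IntegerVector v = nodes[i];
      std::vector<int>& nb = g.adj[l][i];
      nb.resize(v.size());
      for (int t = 0; t < v.size(); ++t) nb[t] = v[t] - 1;
    }
  }
}

static DistCtx make_dist(const NumericMatrix& S, List distspec) {
  DistCtx D;
  D.type = dist_type_from_tag(as<std::string>(distspec["tag"]));
  D.base = distspec.containsElementNamed("b") ? as<double>(distspec["b"]) : 2.0;
  D.a = distspec.containsElementNamed("a") ? as<double>(distspec["a"]) : 1.0;
  D.S = S.begin();
  D.m = S.nrow();
  D.count = 0;
  return D;
}

// [[Rcpp::export]]
List hnsw_build_cpp(NumericMatrix S, int M, int efc, double mL, double seed,
                    List distspec) {
  DistCtx D = make_dist(S, distspec);
  Hnsw g = make_hnsw(S, M, efc, mL, seed, &D);
  for (int i = 0; i < g.N; ++i) g.level[i] = g.draw_level(i);
  for (int i = 0; i < g.N; ++i) g.insert(i, i == 0);
  return hnsw_to_list(g, D.count);
}

// continue inserting into an existing graph: ordinals n_old..N-1 are new
// [[Rcpp::export]]
List hnsw_add_cpp(List graph, NumericMatrix S, int n_old, int M, int efc,
                  double mL, double seed, List distspec) {
  DistCtx D = make_dist(S, distspec);
  Hnsw g = make_hnsw(S, M, efc, mL, seed, &D);
  hnsw_from_list(g, graph, n_old);
  for (int i = n_old; i < g.N; ++i) g.level[i] = g.draw_level(i);
  for (int i = n_old; i < g.N; ++i) g.insert(i, n_old == 0 && i == 0);
  return hnsw_to_list(g, D.count);
}

// [[Rcpp::export]]
List hnsw_query_cpp(List graph, NumericMatrix S, NumericMatrix Q,
                    CharacterVector ids, int K, int ef, List distspec) {
  DistCtx D = make_dist(S, distspec);
  Hnsw g = make_hnsw(S, 2, 2, 0.5, 0.0, &D);
  hnsw_from_list(g, graph, g.N);

  const int nq = Q.ncol();
  const int kk = std::min(K, g.N);
  IntegerMatrix oidx(kk, nq);
  NumericMatrix odist(kk, nq);
  NumericVector ondist(nq);

  std::vector<std::string> sid(g.N);
  for (int i = 0; i < g.N; ++i) sid[i] = as<std::string>(ids[i]);

  for (int qi = 0; qi < nq; ++qi) {
    D.count = 0;
    const double* q = Q.begin() + (size_t)qi * D.m;
    std::vector<DI> W;
    if (ef >= g.N) {
      // an exhaustive beam visits every node; evaluate all of them directly
      W.reserve(g.N);
      for (int i = 0; i < g.N; ++i) W.push_back(DI(D.toq(q, i), i));
      std::sort(W.begin(), W.end());
    } else {
      int ep = g.entry;
      double epd = D.toq(q, ep);
      for (int l = g.maxlevel; l >= 1; --l) {  // greedy upper-layer descent
        bool moved = true;
        while (moved) {
          moved = false;
          const std::vector<int>& nb = g.adj[l][ep];
          for (size_t t = 0; t < nb.size(); ++t) {
            double d = D.toq(q, nb[t]);
            if (d < epd || (d == epd && nb[t] < ep)) {
              epd = d;
              ep = nb[t];
              moved = true;
            }
          }
        }
      }
      std::vector<DI> eps(1, DI(epd, ep));
      W = g.search_layer(q, eps, ef, 0);
    }
    // final ranking ties broken by genome id for deterministic reporting
    std::stable_sort(W.begin(), W.end(), [&](const DI& x, const DI& y) {
      if (x.first != y.first) return x.first < y.first;
      return sid[x.second] < sid[y.second];
    });
    for (int t = 0; t < kk; ++t) {
      if (t < (int)W.size()) {
        oidx(t, qi) = W[t].second + 1;
        odist(t, qi) = W[t].first;
      } else {
        oidx(t, qi) = NA_INTEGER;
        odist(t, qi) = NA_REAL;
      }
    }
    ondist[qi] = (double)D.count;
  }
  return List::create(_["idx"] = oidx, _["dist"] = odist,
                      _["n_dist_evals"] = ondist);
}
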