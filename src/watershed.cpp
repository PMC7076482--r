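#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Watershed of the fluid-phase distance transform with h-maxima merging:
// fluid voxels are processed in order of decreasing distance value; basins
// whose peak exceeds the meeting saddle by less than hmerge are merged.
// Saddles between surviving basins become constrictions.

struct UF {
  std::vector<int> parent;
  std::vector<double> peak;
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  int unite(int a, int b) {  // returns surviving root
    a = find(a); b = find(b);
    if (a == b) return a;
    if (peak[a] < peak[b]) std::swap(a, b);
    parent[b] = a;
    return a;
  }
};

// [[Rcpp::export(name = ".watershed_cpp")]]
List watershed_cpp(NumericVector edt, LogicalVector solid,
                   int nx, int ny, int nz, double hmerge) {
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> order;
  order.reserve(N);
  for (R_xlen_t t = 0; t < N; ++t) if (!solid[t]) order.push_back(t);
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) { return edt[a] > edt[b]; });

  std::vector<int> lab(N, -1);         // region id per voxel (pre-union)
  UF uf;
  struct Saddle { double val; R_xlen_t vox; };
  std::map<std::pair<int, int>, Saddle> saddles;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  int nreg = 0;
  std::vector<int> nb; nb.reserve(6);
  for (R_xlen_t idx = 0; idx < (R_xlen_t)order.size(); ++idx) {
    const R_xlen_t t = order[idx];
    const int i = (int)(t % nx);
    const int j = (int)((t / nx) % ny);
    const int k = (int)(t / sz);
    nb.clear();
    // 6-neighbours inside the box (lateral faces are walls)
    if (i > 0 && lab[t - sx] >= 0) nb.push_back(uf.find(lab[t - sx]));
    if (i < nx - 1 && lab[t + sx] >= 0) nb.push_back(uf.find(lab[t + sx]));
    if (j > 0 && lab[t - sy] >= 0) nb.push_back(uf.find(lab[t - sy]));
    if (j < ny - 1 && lab[t + sy] >= 0) nb.push_back(uf.find(lab[t + sy]));
    if (k > 0 && lab[t - sz] >= 0) nb.push_back(uf.find(lab[t - sz]));
    if (k < nz - 1 && lab[t + sz] >= 0) nb.push_back(uf.find(lab[t + sz]));
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    if (nb.empty()) {
      lab[t] = nreg;
      uf.parent.push_back(nreg);
      uf.peak.push_back(edt[t]);
      ++nreg;
      continue;
    }
    // assign to the basin with the highest peak
    int best = nb[0];
    for (int r : nb) if (uf.peak[r] > uf.peak[best]) best = r;
    lab[t] = best;
    for (int r : nb) {
      if (r == best) continue;
      const double lowpeak = std::min(uf.peak[r], uf.peak[best]);
      if (lowpeak - edt[t] < hmerge) {
        best = uf.unite(r, best);
      } else {
        std::pair<int, int> key(std::min(r, best), std::max(r, best));
        auto it = saddles.find(key);
        if (it == saddles.end() || edt[t] > it->second.val)
          saddles[key] = {edt[t], t};
      }
    }
    lab[t] = uf.find(best);
  }

  // compact surviving roots to 1..K
  std::map<int, int> root2id;
  for (int r = 0; r < nreg; ++r)
    if (uf.find(r) == r) root2id[r] = (int)root2id.size() + 1;
  const int K = (int)root2id.size();

  IntegerVector labels(N, 0);
  std::vector<double> vol(K, 0.0), peak(K, 0.0);
  std::vector<double> cx(K, 0.0), cy(K, 0.0), cz(K, 0.0);
  std::vector<double> px(K, 0.0), py(K, 0.0), pz(K, 0.0);
  std::vector<int> inlet(K, 0), outlet(K, 0);
  std::vector<double> inw(K, 0.0), outw(K, 0.0);  // widest face opening
  for (R_xlen_t t = 0; t < N; ++t) {
    if (solid[t]) continue;
    const int id = root2id[uf.find(lab[t])];
    labels[t] = id;
    const int i = (int)(t % nx);
    const int j = (int)((t / nx) % ny);
    const int k = (int)(t / sz);
    vol[id - 1] += 1.0;
    cx[id - 1] += i + 0.5; cy[id - 1] += j + 0.5; cz[id - 1] += k + 0.5;
    if (edt[t] > peak[id - 1]) {
      peak[id - 1] = edt[t];
      px[id - 1] = i + 0.5; py[id - 1] = j + 0.5; pz[id - 1] = k + 0.5;
    }
    if (k == 0) {
      inlet[id - 1] = 1;
      inw[id - 1] = std::max(inw[id - 1], edt[t]);
    }
    if (k == nz - 1) {
      outlet[id - 1] = 1;
      outw[id - 1] = std::max(outw[id - 1], edt[t]);
    }
  }
  for (int q = 0; q < K; ++q) {
    cx[q] /= vol[q]; cy[q] /= vol[q]; cz[q] /= vol[q];
  }

  // resolve saddles to final basins; keep the widest per surviving pair
  std::map<std::pair<int, int>, Saddle> final_saddles;
  for (auto &kv : saddles) {
    int a = root2id[uf.find(kv.first.first)];
    int b = root2id[uf.find(kv.first.second)];
    if (a == b) continue;
    std::pair<int, int> key(std::min(a, b), std::max(a, b));
    auto it = final_saddles.find(key);
    if (it == final_saddles.end() || kv.second.val > it->second.val)
      final_saddles[key] = kv.second;
  }
  const int M = (int)final_saddles.size();
  IntegerVector ea(M), eb(M);
  NumericVector esad(M), ei(M), ej(M), ek(M);
  int m = 0;
  for (auto &kv : final_saddles) {
    ea[m] = kv.first.first; eb[m] = kv.first.second;
    esad[m] = kv.second.val;
    const R_xlen_t t = kv.second.vox;
    ei[m] = (double)(t % nx) + 0.5;
    ej[m] = (double)((t / nx) % ny) + 0.5;
    ek[m] = (double)(t / sz) + 0.5;
    ++m;
  }
  labels.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(
      _["labels"] = labels,
      _["n_pores"] = K,
      _["voxels"] = NumericVector(vol.begin(), vol.end()),
      _["peak"] = NumericVector(peak.begin(), peak.end()),
      _["centroid_i"] = NumericVector(cx.begin(), cx.end()),
      _["centroid_j"] = NumericVector(cy.begin(), cy.end()),
      _["centroid_k"] = NumericVector(cz.begin(), cz.end()),
      _["peak_i"] = NumericVector(px.begin(), px.end()),
      _["peak_j"] = NumericVector(py.begin(), py.end()),
      _["peak_k"] = NumericVector(pz.begin(), pz.end()),
      _["inlet"] = IntegerVector(inlet.begin(), inlet.end()),
      _["outlet"] = IntegerVector(outlet.begin(), outlet.end()),
      _["inlet_w"] = NumericVector(inw.begin(), inw.end()),
      _["outlet_w"] = NumericVector(outw.begin(), outw.end()),
      _["edge_a"] = ea, _["edge_b"] = eb, _["edge_saddle"] = esad,
      _["edge_i"] = ei, _["edge_j"] = ej, _["edge_k"] = ek);
}

// 6-connected components of the fluid phase (0 = solid), labels 1..K.
// [[Rcpp::export(name = ".flood_components_cpp")]]
IntegerVector flood_components_cpp(LogicalVector solid, int nx, int ny, int nz) {
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(N, 0);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  std::vector<R_xlen_t> stack;
  int K = 0;
  for (R_xlen_t t0 = 0; t0 < N; ++t0) {
    if (solid[t0] || labels[t0] != 0) continue;
    ++K;
    stack.push_back(t0);
    labels[t0] = K;
    while (!stack.empty()) {
      const R_xlen_t t = stack.back();
      stack.pop_back();
      const int i = (int)(t % nx);
      const int j = (int)((t / nx) % ny);
      const int k = (int)(t / sz);
      const R_xlen_t nbs[6] = {t - 1, t + 1, t - nx, t + nx, t - sz, t + sz};
      const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1};
      for (int q = 0; q < 6; ++q) {
        if (ok[q] && !solid[nbs[q]] && labels[nbs[q]] == 0) {
          labels[nbs[q]] = K;
          stack.push_back(nbs[q]);
        }
      }
    }
  }
  labels.attr("dim") = IntegerVector::create(nx, ny, nz);
  return labels;
}
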