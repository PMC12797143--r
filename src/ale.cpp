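#include <Rcpp.h>
using namespace Rcpp;

// Modelled-activation map under the non-additive (max) rule: place a
// probability-mass kernel at every focus, keeping the voxelwise maximum.
// centers are 1-based voxel indices (rows: i, j, k); out-of-grid kernel
// mass is clipped.
// [[Rcpp::export(name = ".ma_max_map_cpp")]]
NumericVector ma_max_map_cpp(IntegerVector shape, NumericVector kern,
                             IntegerVector kshape, IntegerMatrix centers) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int kx = kshape[0], ky = kshape[1], kz = kshape[2];
  const int rx = (kx - 1) / 2, ry = (ky - 1) / 2, rz = (kz - 1) / 2;
  NumericVector vol(nx * ny * nz);
  for (int f = 0; f < centers.nrow(); ++f) {
    const int ci = centers(f, 0) - 1, cj = centers(f, 1) - 1,
              ck = centers(f, 2) - 1;
    const int i0 = std::max(0, ci - rx), i1 = std::min(nx - 1, ci + rx);
    const int j0 = std::max(0, cj - ry), j1 = std::min(ny - 1, cj + ry);
    const int k0 = std::max(0, ck - rz), k1 = std::min(nz - 1, ck + rz);
    for (int k = k0; k <= k1; ++k) {
      const int kk = k - (ck - rz);
      for (int j = j0; j <= j1; ++j) {
        const int kj = j - (cj - ry);
        const double *ksl = &kern[(size_t)kk * kx * ky + (size_t)kj * kx];
        double *vsl = &vol[(size_t)k * nx * ny + (size_t)j * nx];
        for (int i = i0; i <= i1; ++i) {
          const double v = ksl[i - (ci - rx)];
          if (v > vsl[i]) vsl[i] = v;
        }
      }
    }
  }
  return vol;
}

// One step of the sequential binned histogram integration: combine the
// current null histogram (dense, bin value = lower edge) with one
// experiment's binned MA distribution through the union formula,
// flooring combined scores into bins (conservative tails).
// [[Rcpp::export(name = ".null_combine_cpp")]]
NumericVector null_combine_cpp(NumericVector dense, IntegerVector qbins,
                               NumericVector qprobs, double binw) {
  const int nb = dense.size();
  NumericVector out(nb);
  std::vector<int> occ;
  occ.reserve(nb);
  for (int b = 0; b < nb; ++b)
    if (dense[b] > 0) occ.push_back(b);
  for (int j = 0; j < qbins.size(); ++j) {
    const double m = qbins[j] * binw, qp = qprobs[j];
    for (size_t t = 0; t < occ.size(); ++t) {
      const int b = occ[t];
      const double score = 1.0 - (1.0 - b * binw) * (1.0 - m);
      int idx = (int)std::floor(score / binw + 1e-12);
      if (idx > nb - 1) idx = nb - 1;
      out[idx] += dense[b] * qp;
    }
  }
  return out;
}

// Connected-component labelling of a logical 3-D array under 6/18/26
// connectivity (breadth-first flood fill).  Returns integer labels,
// 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector supra, IntegerVector shape,
                                   int connectivity) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n);
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int nzc = std::abs(a) + std::abs(b) + std::abs(c);
        if (nzc == 0) continue;
        if (connectivity == 6 && nzc > 1) continue;
        if (connectivity == 18 && nzc > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  std::vector<size_t> stack;
  int lab = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!supra[s] || labels[s] != 0) continue;
    labels[s] = ++lab;
    stack.assign(1, s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int k = cur / (nx * ny), rem = cur % (nx * ny);
      const int j = rem / nx, i = rem % nx;
      for (size_t o = 0; o < di.size(); ++o) {
        const int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t lin = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
        if (supra[lin] && labels[lin] == 0) {
          labels[lin] = lab;
          stack.push_back(lin);
        }
      }
    }
  }
  return labels;
}
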