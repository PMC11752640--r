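#include <Rcpp.h>
#include <vector>

// Threshold-free cluster enhancement of a non-negative 3D statistic map:
//   TFCE(p) = sum over thresholds h = dh, 2dh, ... of
//             extent(p, h)^E * h^H * dh,
// where extent(p, h) is the size of the connected component containing p
// among voxels with map >= h. Connectivity: 6 (faces), 18 (faces+edges)
// or 26 (faces+edges+corners).

static void neighbour_offsets(int connectivity, std::vector<int>& dx,
                              std::vector<int>& dy, std::vector<int>& dz) {
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                int s = std::abs(a) + std::abs(b) + std::abs(c);
                if (s == 0) continue;
                if (connectivity == 6 && s > 1) continue;
                if (connectivity == 18 && s > 2) continue;
                dx.push_back(a); dy.push_back(b); dz.push_back(c);
            }
}

// [[Rcpp::export]]
Rcpp::NumericVector tfce_pos(Rcpp::NumericVector map, Rcpp::IntegerVector dims,
                             int connectivity, double H, double E, double dh) {
    if (dims.size() != 3) Rcpp::stop("tfce: dims must have length 3");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int nv = nx * ny * nz;
    if ((int)map.size() != nv) Rcpp::stop("tfce: map size does not match dims");
    if (dh <= 0) Rcpp::stop("tfce: dh must be positive");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        Rcpp::stop("tfce: connectivity must be 6, 18 or 26");

    std::vector<int> dx, dy, dz;
    neighbour_offsets(connectivity, dx, dy, dz);
    const int nn = (int)dx.size();

    Rcpp::NumericVector out(nv, 0.0);
    double hmax = 0.0;
    for (int i = 0; i < nv; ++i) {
        if (!R_finite(map[i])) Rcpp::stop("tfce: map must be finite");
        if (map[i] > hmax) hmax = map[i];
    }
    if (hmax <= 0) return out;

    std::vector<int> label(nv), stack, members;
    const int nstep = (int)std::floor(hmax / dh + 1e-12);
    // ties between voxel values and threshold levels are resolved towards
    // inclusion, so results are stable under last-ulp threshold rounding
    const double heps = 1e-9 * dh;
    for (int step = 1; step <= nstep; ++step) {
        const double h = step * dh;
        const double hcut = h - heps;
        std::fill(label.begin(), label.end(), 0);
        int cur = 0;
        for (int seed = 0; seed < nv; ++seed) {
            if (map[seed] < hcut || label[seed]) continue;
            ++cur;
            stack.clear(); members.clear();
            stack.push_back(seed);
            label[seed] = cur;
            while (!stack.empty()) {
                int v = stack.back();
                stack.pop_back();
                members.push_back(v);
                int z = v / (nx * ny), rem = v % (nx * ny);
                int y = rem / nx, x = rem % nx;
                for (int k = 0; k < nn; ++k) {
                    int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                        zz < 0 || zz >= nz) continue;
                    int u = xx + nx * (yy + ny * zz);
                    if (map[u] >= hcut && !label[u]) {
                        label[u] = cur;
                        stack.push_back(u);
                    }
                }
            }
            const double add =
                std::pow((double)members.size(), E) * std::pow(h, H) * dh;
            for (size_t k = 0; k < members.size(); ++k) out[members[k]] += add;
        }
    }
    return out;
}
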