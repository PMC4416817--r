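#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Large-but-finite stand-in for infinity: keeps the parabola intersection
// arithmetic in the distance transform free of Inf - Inf.
static const double BIG = 1e30;

// 1-D squared distance transform along a sampled grid with spacing w
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas algorithm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double xq = q * w;
        double s;
        while (true) {
            double xv = v[k] * w;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * w;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * w;
        d[q] = dx * dx + f[v[k]];
    }
}

//' Anisotropic Euclidean distance transform of a 3-D mask
//'
//' For every voxel, the physical distance to the nearest \code{TRUE}
//' (source) voxel centre. Exact (not chamfer), separable per axis.
//'
//' @param src logical vector of a 3-D array in R's column-major order.
//' @param dims integer vector (nx, ny, nz).
//' @param spacing numeric vector of voxel edge lengths (dx, dy, dz), any
//'   consistent physical unit.
//' @return numeric vector of distances in the unit of \code{spacing};
//'   voxels with no source anywhere get a very large finite value.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector src, IntegerVector dims,
                        NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (src.size() != n) stop("mask length does not match dims");
    NumericVector out(n);
    // squared distances, seeded at 0 on sources
    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = src[i] ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest index)
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f, d, nx, spacing[0], v, z);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    }
    // pass along y
    for (int k = 0; k < nz; ++k) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
            dt1d(f, d, ny, spacing[1], v, z);
            for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
        }
    }
    // pass along z
    const R_xlen_t stride_z = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * stride_z];
            dt1d(f, d, nz, spacing[2], v, z);
            for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * stride_z] = d[k];
        }
    }
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = g[i] >= BIG ? std::sqrt(BIG) : std::sqrt(g[i]);
    return out;
}

//' Connected-component labelling of a 3-D mask
//'
//' @param mask logical vector in column-major order.
//' @param dims integer vector (nx, ny, nz).
//' @param connectivity 6 (face) or 26 (face+edge+vertex).
//' @return integer vector of labels, 0 for background, components
//'   numbered 1..n in first-encounter (column-major scan) order.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    if (connectivity != 6 && connectivity != 26)
        stop("connectivity must be 6 or 26");

    // neighbour offsets as (di, dj, dk) triples
    std::vector<int> di, dj, dk;
    for (int c = -1; c <= 1; ++c)
        for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
                if (a == 0 && b == 0 && c == 0) continue;
                int manh = std::abs(a) + std::abs(b) + std::abs(c);
                if (connectivity == 6 && manh != 1) continue;
                di.push_back(a);
                dj.push_back(b);
                dk.push_back(c);
            }
    const int nn = (int)di.size();

    IntegerVector lab(n);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int i = (int)(cur % nx);
            int j = (int)((cur / nx) % ny);
            int k = (int)(cur / ((R_xlen_t)nx * ny));
            for (int m = 0; m < nn; ++m) {
                int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                    kk >= nz)
                    continue;
                R_xlen_t q =
                    (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
                if (mask[q] && lab[q] == 0) {
                    lab[q] = next;
                    stack.push_back(q);
                }
            }
        }
    }
    return lab;
}
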