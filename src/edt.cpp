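#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// separable lower-envelope-of-parabolas algorithm, generalised to a
// per-axis grid spacing so distances come out in world millimetres on
// anisotropic grids. Distances are measured between voxel centres.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform with sample spacing h:
//   d[p] = min_q ( (p-q)^2 h^2 + f[q] )
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
    const double h2 = h * h;
    int k = -1; // index of the last parabola on the lower envelope
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue; // infinite parabolas never contribute
        double s = 0.0;
        while (k >= 0) {
            int p = v[k];
            s = ((f[q] + (double)q * q * h2) - (f[p] + (double)p * p * h2)) /
                (2.0 * h2 * (q - p));
            if (s <= z[k]) --k; else break;
        }
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
        } else {
            ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
        }
    }
    if (k < 0) { // no finite source anywhere on this line
        for (int p = 0; p < n; ++p) d[p] = INF;
        return;
    }
    k = 0;
    for (int p = 0; p < n; ++p) {
        while (z[k + 1] < (double)p) ++k;
        double dq = ((double)p - v[k]) * h;
        d[p] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d")]]
Rcpp::NumericVector edt3d(Rcpp::LogicalVector mask, Rcpp::IntegerVector dim,
                          Rcpp::NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    Rcpp::NumericVector out(n);
    // squared distance accumulator; 0 on mask voxels, INF elsewhere
    std::vector<double> g((size_t)n);
    for (R_xlen_t i = 0; i < n; ++i) g[(size_t)i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            size_t base = (size_t)k * nx * ny + (size_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            size_t base = (size_t)k * nx * ny + (size_t)i;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
        }
    // pass along z
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            size_t base = (size_t)j * nx + (size_t)i;
            for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
        }

    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (g[(size_t)i] == INF) ? R_PosInf : std::sqrt(g[(size_t)i]);
    out.attr("dim") = dim;
    return out;
}
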