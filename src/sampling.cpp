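#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Deterministic barycentric grid sampling of a triangle soup. Each triangle
// with longest edge e is subdivided into k = ceil(e / spacing) segments per
// edge; the (k+1)(k+2)/2 lattice points A + (i/k)(B-A) + (j/k)(C-A), i+j <= k,
// are emitted. All sub-edges then have length <= spacing, so every surface
// point lies within spacing of a sample (worst case spacing/sqrt(3) for an
// equilateral micro-triangle). No randomness: bitwise repeatable.
// [[Rcpp::export(name = ".cpp_sample_triangles")]]
List cpp_sample_triangles(NumericMatrix vertices, IntegerMatrix faces,
                          double spacing) {
    if (spacing <= 0) stop("spacing must be > 0");
    int nf = faces.nrow();
    int nv = vertices.nrow();

    std::vector<int> k_of(nf, 0);
    long long total = 0;
    int n_degenerate = 0;
    double max_step = 0.0;

    for (int f = 0; f < nf; ++f) {
        int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
        if (ia < 0 || ib < 0 || ic < 0 || ia >= nv || ib >= nv || ic >= nv)
            stop("face %d references a vertex outside the mesh", f + 1);
        double ax = vertices(ia, 0), ay = vertices(ia, 1), az = vertices(ia, 2);
        double bx = vertices(ib, 0), by = vertices(ib, 1), bz = vertices(ib, 2);
        double cx = vertices(ic, 0), cy = vertices(ic, 1), cz = vertices(ic, 2);
        double e1x = bx - ax, e1y = by - ay, e1z = bz - az;
        double e2x = cx - ax, e2y = cy - ay, e2z = cz - az;
        // twice the triangle area via cross product
        double nx = e1y * e2z - e1z * e2y;
        double ny = e1z * e2x - e1x * e2z;
        double nz = e1x * e2y - e1y * e2x;
        double area2 = std::sqrt(nx * nx + ny * ny + nz * nz);
        if (area2 <= 0.0 || !std::isfinite(area2)) {
            n_degenerate++;
            continue;
        }
        double l1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
        double l2 = std::sqrt(e2x * e2x + e2y * e2y + e2z * e2z);
        double dx = cx - bx, dy = cy - by, dz = cz - bz;
        double l3 = std::sqrt(dx * dx + dy * dy + dz * dz);
        double emax = std::max(l1, std::max(l2, l3));
        int k = (int)std::ceil(emax / spacing);
        if (k < 1) k = 1;
        k_of[f] = k;
        total += (long long)(k + 1) * (k + 2) / 2;
        double step = emax / k;
        if (step > max_step) max_step = step;
    }

    if (total == 0) stop("all triangles are degenerate (zero area)");
    if (total > 60000000LL)
        stop("sampling would produce %.0f points; increase max_spacing_mm",
             (double)total);

    NumericMatrix out((int)total, 3);
    long long row = 0;
    for (int f = 0; f < nf; ++f) {
        int k = k_of[f];
        if (k == 0) continue;
        int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
        double ax = vertices(ia, 0), ay = vertices(ia, 1), az = vertices(ia, 2);
        double e1x = vertices(ib, 0) - ax, e1y = vertices(ib, 1) - ay,
               e1z = vertices(ib, 2) - az;
        double e2x = vertices(ic, 0) - ax, e2y = vertices(ic, 1) - ay,
               e2z = vertices(ic, 2) - az;
        for (int i = 0; i <= k; ++i) {
            double u = (double)i / k;
            for (int j = 0; j <= k - i; ++j) {
                double v = (double)j / k;
                out(row, 0) = ax + u * e1x + v * e2x;
                out(row, 1) = ay + u * e1y + v * e2y;
                out(row, 2) = az + u * e1z + v * e2z;
                ++row;
            }
        }
    }

    return List::create(_["points"] = out,
                        _["max_step"] = max_step,
                        _["n_degenerate"] = n_degenerate);
}

// Minimum distance from each query point to a polyline (point-to-segment,
// exact). Used for centerline ground-truth oracles.
// [[Rcpp::export(name = ".cpp_dist_to_polyline")]]
NumericVector cpp_dist_to_polyline(NumericMatrix query, NumericMatrix line) {
    int m = query.nrow(), n = line.nrow();
    if (n < 1) stop("polyline must contain at least one point");
    NumericVector out(m);
    for (int i = 0; i < m; ++i) {
        double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
        double best = R_PosInf;
        for (int j = 0; j + 1 < n; ++j) {
            double ax = line(j, 0), ay = line(j, 1), az = line(j, 2);
            double dx = line(j + 1, 0) - ax, dy = line(j + 1, 1) - ay,
                   dz = line(j + 1, 2) - az;
            double len2 = dx * dx + dy * dy + dz * dz;
            double t = 0.0;
            if (len2 > 0) {
                t = ((qx - ax) * dx + (qy - ay) * dy + (qz - az) * dz) / len2;
                if (t < 0) t = 0; else if (t > 1) t = 1;
            }
            double px = ax + t * dx - qx, py = ay + t * dy - qy,
                   pz = az + t * dz - qz;
            double d2 = px * px + py * py + pz * pz;
            if (d2 < best) best = d2;
        }
        if (n == 1) {
            double px = line(0, 0) - qx, py = line(0, 1) - qy,
                   pz = line(0, 2) - qz;
            best = px * px + py * py + pz * pz;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}
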