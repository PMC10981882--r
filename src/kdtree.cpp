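#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Median-split kd-tree over 3-D points. Implicit balanced layout: the node
// for index range [lo, hi) stores its point at position mid = (lo+hi)/2 of
// the permutation vector, children in [lo, mid) and (mid, hi).
struct KDTree {
    std::vector<double> pts; // xyz interleaved, 3*n
    std::vector<int> perm;
    int n;

    void build(const NumericMatrix& m) {
        n = m.nrow();
        pts.resize(3 * (size_t)n);
        for (int i = 0; i < n; ++i) {
            pts[3 * (size_t)i]     = m(i, 0);
            pts[3 * (size_t)i + 1] = m(i, 1);
            pts[3 * (size_t)i + 2] = m(i, 2);
        }
        perm.resize(n);
        for (int i = 0; i < n; ++i) perm[i] = i;
        build_range(0, n, 0);
    }

    void build_range(int lo, int hi, int dim) {
        if (hi - lo <= 1) return;
        int mid = (lo + hi) / 2;
        const double* p = pts.data();
        std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                         [p, dim](int a, int b) {
                             return p[3 * (size_t)a + dim] < p[3 * (size_t)b + dim];
                         });
        build_range(lo, mid, (dim + 1) % 3);
        build_range(mid + 1, hi, (dim + 1) % 3);
    }

    void query(const double* q, int lo, int hi, int dim,
               int& best, double& best_d2) const {
        if (hi <= lo) return;
        int mid = (lo + hi) / 2;
        int i = perm[mid];
        double dx = q[0] - pts[3 * (size_t)i];
        double dy = q[1] - pts[3 * (size_t)i + 1];
        double dz = q[2] - pts[3 * (size_t)i + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best_d2) { best_d2 = d2; best = i; }
        double diff = q[dim] - pts[3 * (size_t)i + dim];
        int nd = (dim + 1) % 3;
        if (diff < 0) {
            query(q, lo, mid, nd, best, best_d2);
            if (diff * diff < best_d2) query(q, mid + 1, hi, nd, best, best_d2);
        } else {
            query(q, mid + 1, hi, nd, best, best_d2);
            if (diff * diff < best_d2) query(q, lo, mid, nd, best, best_d2);
        }
    }
};

// [[Rcpp::export(name = ".cpp_nn_build")]]
SEXP cpp_nn_build(NumericMatrix pts) {
    if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
    if (pts.nrow() < 1) stop("points must contain at least one row");
    XPtr<KDTree> tree(new KDTree(), true);
    tree->build(pts);
    return tree;
}

// [[Rcpp::export(name = ".cpp_nn_query")]]
List cpp_nn_query(SEXP tree_ptr, NumericMatrix query) {
    XPtr<KDTree> tree(tree_ptr);
    int m = query.nrow();
    IntegerVector idx(m);
    NumericVector dist(m);
    double q[3];
    for (int i = 0; i < m; ++i) {
        q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
        int best = -1;
        double best_d2 = R_PosInf;
        tree->query(q, 0, tree->n, 0, best, best_d2);
        idx[i] = best + 1; // 1-based for R
        dist[i] = std::sqrt(best_d2);
    }
    return List::create(_["index"] = idx, _["dist"] = dist);
}

// Global minimum distance between two clouds: tree on `target`, scan `query`.
// [[Rcpp::export(name = ".cpp_min_dist")]]
double cpp_min_dist(SEXP tree_ptr, NumericMatrix query) {
    XPtr<KDTree> tree(tree_ptr);
    int m = query.nrow();
    double best_d2 = R_PosInf;
    double q[3];
    for (int i = 0; i < m; ++i) {
        q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
        int best = -1;
        tree->query(q, 0, tree->n, 0, best, best_d2);
    }
    return std::sqrt(best_d2);
}
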