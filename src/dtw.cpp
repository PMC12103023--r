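#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>
using namespace Rcpp;

// log-ratio Euclidean distance between signed degrees, exponentiated.
// minusOne switches to the variant where identical degrees score 0.
static inline double ebedVal(int ap, int an, int bp, int bn, bool minusOne) {
    const double x = std::log((double)(ap + 1) / (bp + 1));
    const double y = std::log((double)(an + 1) / (bn + 1));
    const double d = std::exp(std::sqrt(x * x + y * y));
    return minusOne ? d - 1.0 : d;
}

// Distinct signed-degree classes and the exact pairwise EBED table between
// them; the DTW inner loop then only does table lookups. This is plain
// memoisation of the local cost, not a sequence compression.
struct CostTable {
    std::vector<int> cls;              // per input row, its class id
    std::vector<double> C;             // nCls x nCls cost table
    int nCls;
    double at(int a, int b) const { return C[(size_t)a * nCls + b]; }
};

static CostTable makeCostTable(const IntegerMatrix& deg, bool minusOne) {
    CostTable t;
    std::map<std::pair<int, int>, int> seen;
    std::vector<std::pair<int, int> > classes;
    const int n = deg.nrow();
    t.cls.resize(n);
    for (int i = 0; i < n; ++i) {
        std::pair<int, int> key(deg(i, 0), deg(i, 1));
        std::map<std::pair<int, int>, int>::iterator it = seen.find(key);
        if (it == seen.end()) {
            it = seen.insert(std::make_pair(key, (int)classes.size())).first;
            classes.push_back(key);
        }
        t.cls[i] = it->second;
    }
    t.nCls = (int)classes.size();
    t.C.resize((size_t)t.nCls * t.nCls);
    for (int a = 0; a < t.nCls; ++a)
        for (int b = 0; b < t.nCls; ++b)
            t.C[(size_t)a * t.nCls + b] =
                ebedVal(classes[a].first, classes[a].second,
                        classes[b].first, classes[b].second, minusOne);
    return t;
}

// DTW with sum aggregation and steps {(1,0),(0,1),(1,1)} over two
// class-index sequences.
static double dtwSeq(const std::vector<int>& su, const std::vector<int>& sv,
                     const CostTable& ct, std::vector<double>& prev,
                     std::vector<double>& cur) {
    const size_t m = su.size(), n = sv.size();
    if (prev.size() < n) { prev.resize(n); cur.resize(n); }
    const int c0 = su[0];
    for (size_t j = 0; j < n; ++j) {
        const double c = ct.at(c0, sv[j]);
        prev[j] = (j == 0) ? c : prev[j - 1] + c;
    }
    for (size_t i = 1; i < m; ++i) {
        const int ci = su[i];
        const double* row = &ct.C[(size_t)ci * ct.nCls];
        cur[0] = prev[0] + row[sv[0]];
        for (size_t j = 1; j < n; ++j) {
            double best = prev[j];
            if (prev[j - 1] < best) best = prev[j - 1];
            if (cur[j - 1] < best) best = cur[j - 1];
            cur[j] = best + row[sv[j]];
        }
        std::swap(prev, cur);
    }
    return prev[n - 1];
}

// Cumulative structural dissimilarity f_k for all unordered node pairs
// (diagonal included). deg: n x 2 signed degrees; dist: n x n shortest-path
// hop counts on the unsigned union graph (< 0 for unreachable); ord: 1-based
// canonical node order (ascending total degree, then d+, then d-).
// Returns a list of kMax + 1 symmetric matrices; NA marks pairs truncated
// because one ring ran empty at or below that layer.
// [[Rcpp::export(name = ".cppDissimilarity")]]
List cppDissimilarity(IntegerMatrix deg, IntegerMatrix dist, IntegerVector ord,
                      int kMax, bool minusOne) {
    const int n = deg.nrow();
    const CostTable ct = makeCostTable(deg, minusOne);

    // rings[u][k]: degree classes of nodes at exactly k hops from u,
    // canonical order
    std::vector<std::vector<std::vector<int> > > rings(
        n, std::vector<std::vector<int> >(kMax + 1));
    for (int u = 0; u < n; ++u) {
        rings[u][0].push_back(ct.cls[u]);
        for (int oi = 0; oi < n; ++oi) {
            const int v = ord[oi] - 1;
            const int d = dist(u, v);
            if (d >= 1 && d <= kMax) rings[u][d].push_back(ct.cls[v]);
        }
    }

    List out(kMax + 1);
    std::vector<NumericMatrix> fm;
    for (int k = 0; k <= kMax; ++k) {
        NumericMatrix m(n, n);
        std::fill(m.begin(), m.end(), NA_REAL);
        fm.push_back(m);
        out[k] = m;
    }

    std::vector<double> prev, cur;
    for (int u = 0; u < n; ++u) {
        for (int v = u; v < n; ++v) {
            double cum = ct.at(ct.cls[u], ct.cls[v]);
            fm[0](u, v) = cum; fm[0](v, u) = cum;
            for (int k = 1; k <= kMax; ++k) {
                if (rings[u][k].empty() || rings[v][k].empty()) break;
                cum += dtwSeq(rings[u][k], rings[v][k], ct, prev, cur);
                fm[k](u, v) = cum; fm[k](v, u) = cum;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}

// DTW between two explicit signed-degree sequences (m x 2 integer matrices).
// [[Rcpp::export(name = ".cppDTW")]]
double cppDTW(IntegerMatrix s, IntegerMatrix t, bool minusOne) {
    const int m = s.nrow(), n = t.nrow();
    IntegerMatrix deg(m + n, 2);
    for (int i = 0; i < m; ++i) { deg(i, 0) = s(i, 0); deg(i, 1) = s(i, 1); }
    for (int j = 0; j < n; ++j) { deg(m + j, 0) = t(j, 0); deg(m + j, 1) = t(j, 1); }
    const CostTable ct = makeCostTable(deg, minusOne);
    std::vector<int> su(m), sv(n);
    for (int i = 0; i < m; ++i) su[i] = ct.cls[i];
    for (int j = 0; j < n; ++j) sv[j] = ct.cls[m + j];
    std::vector<double> prev, cur;
    return dtwSeq(su, sv, ct, prev, cur);
}

// DTW for many pairs drawn from a shared pool of sequences; pairs is a
// two-column 1-based index matrix into seqs.
// [[Rcpp::export(name = ".cppDTWCross")]]
NumericVector cppDTWCross(List seqs, IntegerMatrix pairs, bool minusOne) {
    const int nSeq = seqs.size();
    std::vector<IntegerMatrix> mats;
    int total = 0;
    for (int i = 0; i < nSeq; ++i) {
        IntegerMatrix m = seqs[i];
        mats.push_back(m);
        total += m.nrow();
    }
    IntegerMatrix deg(total, 2);
    int at = 0;
    std::vector<std::vector<int> > rowOf(nSeq);
    for (int i = 0; i < nSeq; ++i) {
        for (int r = 0; r < mats[i].nrow(); ++r) {
            deg(at, 0) = mats[i](r, 0);
            deg(at, 1) = mats[i](r, 1);
            rowOf[i].push_back(at++);
        }
    }
    const CostTable ct = makeCostTable(deg, minusOne);
    std::vector<std::vector<int> > seqCls(nSeq);
    for (int i = 0; i < nSeq; ++i)
        for (size_t r = 0; r < rowOf[i].size(); ++r)
            seqCls[i].push_back(ct.cls[rowOf[i][r]]);
    NumericVector out(pairs.nrow());
    std::vector<double> prev, cur;
    for (int p = 0; p < pairs.nrow(); ++p) {
        out[p] = dtwSeq(seqCls[pairs(p, 0) - 1], seqCls[pairs(p, 1) - 1], ct,
                        prev, cur);
        if (p % 100000 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
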