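#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Biased random walks on the multilayer similarity graph.
//
// nbr / cum: per layer (length kMax + 1), a list of per-node integer
// neighbour vectors (1-based) and matching cumulative intra-move
// probabilities normalised to 1. pIntra / pUp: n x (kMax + 1) absolute move
// probabilities at each (node, layer); the downward probability is the
// remainder. Walks start at layer 0; only intra-layer steps append a token.
// Uses R's RNG, so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".cppWalks")]]
List cppWalks(List nbr, List cum, NumericMatrix pIntra, NumericMatrix pUp,
              int walksPerNode, int walkLength) {
    const int n = pIntra.nrow();
    const int nLayers = pIntra.ncol();
    // unpack to plain C++ structures once
    std::vector<std::vector<std::vector<int> > > NB(nLayers);
    std::vector<std::vector<std::vector<double> > > CM(nLayers);
    for (int k = 0; k < nLayers; ++k) {
        List lk = nbr[k], ck = cum[k];
        NB[k].resize(n); CM[k].resize(n);
        for (int u = 0; u < n; ++u) {
            IntegerVector nv = lk[u];
            NumericVector cv = ck[u];
            NB[k][u].assign(nv.begin(), nv.end());
            CM[k][u].assign(cv.begin(), cv.end());
        }
    }

    List out(n * walksPerNode);
    std::vector<int> walk;
    const long maxSteps = 100L * walkLength;
    int w = 0;
    for (int start = 0; start < n; ++start) {
        for (int r = 0; r < walksPerNode; ++r) {
            walk.clear();
            int u = start, k = 0;
            walk.push_back(u + 1);
            long steps = 0;
            while ((int)walk.size() < walkLength && steps++ < maxSteps) {
                const double move = unif_rand();
                const double pi = pIntra(u, k);
                if (move < pi && !NB[k][u].empty()) {
                    const double r2 = unif_rand();
                    const std::vector<double>& cm = CM[k][u];
                    const size_t j = std::lower_bound(cm.begin(), cm.end(), r2)
                                     - cm.begin();
                    u = NB[k][u][j < cm.size() ? j : cm.size() - 1] - 1;
                    walk.push_back(u + 1);
                } else if (move < pi + pUp(u, k)) {
                    if (k < nLayers - 1) ++k;
                } else {
                    if (k > 0) --k;
                }
            }
            out[w++] = IntegerVector(walk.begin(), walk.end());
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}
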