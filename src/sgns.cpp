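#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Skip-Gram with negative sampling over a walk corpus.
//
// walks: list of 1-based token vectors; counts: per-token corpus frequency
// (vocabulary = every token, min count 1). Training is single-threaded and
// consumes R's RNG only, so results are reproducible under set.seed().
// Learning rate decays linearly from alpha to minAlpha over
// epochs * corpus tokens; negative samples drawn from the unigram^(3/4)
// table as in word2vec. Returns the input (syn0) vectors.
// [[Rcpp::export(name = ".cppSGNS")]]
NumericMatrix cppSGNS(List walks, int vocab, IntegerVector counts, int dim,
                      int window, int epochs, int negative, double alpha,
                      double minAlpha) {
    const int EXP_TABLE_SIZE = 1000, MAX_EXP = 6;
    std::vector<double> expTable(EXP_TABLE_SIZE);
    for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
        double x = std::exp(((double)i / EXP_TABLE_SIZE * 2 - 1) * MAX_EXP);
        expTable[i] = x / (x + 1);
    }

    // unigram^0.75 negative-sampling table
    const int TABLE_SIZE = 1000000;
    std::vector<int> table(TABLE_SIZE);
    double trainPow = 0.0;
    const double power = 0.75;
    for (int i = 0; i < vocab; ++i) trainPow += std::pow((double)counts[i], power);
    int i = 0;
    double d1 = std::pow((double)counts[0], power) / trainPow;
    for (int a = 0; a < TABLE_SIZE; ++a) {
        table[a] = i;
        if ((double)a / TABLE_SIZE > d1 && i < vocab - 1) {
            ++i;
            d1 += std::pow((double)counts[i], power) / trainPow;
        }
    }

    std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
    for (size_t a = 0; a < syn0.size(); ++a)
        syn0[a] = (unif_rand() - 0.5) / dim;

    long long totalTokens = 0;
    const int nWalks = walks.size();
    std::vector<std::vector<int> > corpus(nWalks);
    for (int wI = 0; wI < nWalks; ++wI) {
        IntegerVector wv = walks[wI];
        corpus[wI].assign(wv.begin(), wv.end());
        totalTokens += wv.size();
    }
    const long long totalWords = totalTokens * epochs;

    std::vector<double> neu1e(dim);
    long long processed = 0;
    double lr = alpha;
    for (int ep = 0; ep < epochs; ++ep) {
        for (int wI = 0; wI < nWalks; ++wI) {
            const std::vector<int>& sen = corpus[wI];
            const int len = (int)sen.size();
            for (int pos = 0; pos < len; ++pos) {
                ++processed;
                if (processed % 10000 == 0) {
                    lr = alpha * (1.0 - (double)processed / (totalWords + 1));
                    if (lr < minAlpha) lr = minAlpha;
                    Rcpp::checkUserInterrupt();
                }
                const int center = sen[pos] - 1;
                const int b = (int)(unif_rand() * window); // shrunk window
                for (int off = b - window; off <= window - b; ++off) {
                    if (off == 0) continue;
                    const int cpos = pos + off;
                    if (cpos < 0 || cpos >= len) continue;
                    const int context = sen[cpos] - 1;
                    double* l1 = &syn0[(size_t)context * dim];
                    std::fill(neu1e.begin(), neu1e.end(), 0.0);
                    for (int d = 0; d <= negative; ++d) {
                        int target; double label;
                        if (d == 0) { target = center; label = 1.0; }
                        else {
                            target = table[(int)(unif_rand() * TABLE_SIZE)];
                            if (target == center) continue;
                            label = 0.0;
                        }
                        double* l2 = &syn1[(size_t)target * dim];
                        double f = 0.0;
                        for (int c = 0; c < dim; ++c) f += l1[c] * l2[c];
                        double g;
                        if (f > MAX_EXP) g = (label - 1.0) * lr;
                        else if (f < -MAX_EXP) g = label * lr;
                        else g = (label - expTable[(int)((f + MAX_EXP) *
                                 (EXP_TABLE_SIZE / MAX_EXP / 2))]) * lr;
                        for (int c = 0; c < dim; ++c) neu1e[c] += g * l2[c];
                        for (int c = 0; c < dim; ++c) l2[c] += g * l1[c];
                    }
                    for (int c = 0; c < dim; ++c) l1[c] += neu1e[c];
                }
            }
        }
    }

    NumericMatrix out(vocab, dim);
    for (int v = 0; v < vocab; ++v)
        for (int c = 0; c < dim; ++c) out(v, c) = syn0[(size_t)v * dim + c];
    return out;
}
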