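// Word-embedding trainers: CBOW / subword-CBOW (full softmax or negative
// sampling) and GloVe (AdaGrad SGD or full-batch gradient descent).
// Single-threaded; all randomness comes from R's RNG so set.seed() in the
// calling R code makes training bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Binary search a cumulative probability table; u in [0,1).
static inline int sampleCum(const std::vector<double>& cum, double u) {
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (u <= cum[mid]) hi = mid; else lo = mid + 1;
    }
    return lo;
}

// CBOW training over integer sentences. Vector matrices are stored
// transposed (dim x entity) so each entity's vector is a contiguous
// column. Input vectors live in the columns of `win`, indexed through
// `wordRows`: word w is the SUM of columns wordRows[w] (a single column
// for plain CBOW; its character-n-gram columns for the subword encoder).
// Output vectors `wout` are per word (one column each). Returns the
// per-epoch mean loss (negative log-likelihood, or the negative-sampling
// objective when negative > 0 and |V| exceeds the softmax cap upstream).
// [[Rcpp::export]]
NumericVector cpp_cbow_train(List sentences, NumericMatrix win,
                             NumericMatrix wout, List wordRows,
                             int window, int epochs, double lr,
                             int negative, NumericVector unigramCum,
                             bool fullSoftmax) {
    const int V = wout.ncol(), dim = wout.nrow();
    const int nSent = sentences.size();
    NumericVector lossTrace(epochs);

    // Pre-extract sentence and subword indexing to plain C++ vectors.
    std::vector<std::vector<int>> sent(nSent);
    for (int s = 0; s < nSent; ++s) {
        IntegerVector iv = sentences[s];
        sent[s].assign(iv.begin(), iv.end());
    }
    std::vector<std::vector<int>> rowsOf(V);
    for (int w = 0; w < V; ++w) {
        IntegerVector iv = wordRows[w];
        rowsOf[w].assign(iv.begin(), iv.end());
    }
    std::vector<double> cum(unigramCum.begin(), unigramCum.end());

    std::vector<double> h(dim), gh(dim), scores(fullSoftmax ? V : 0);

    for (int ep = 0; ep < epochs; ++ep) {
        double lossSum = 0.0; long nTargets = 0;
        for (int s = 0; s < nSent; ++s) {
            const std::vector<int>& sn = sent[s];
            const int n = (int)sn.size();
            for (int t = 0; t < n; ++t) {
                int lo = std::max(0, t - window);
                int hi = std::min(n - 1, t + window);
                int nCtx = hi - lo - (t >= lo && t <= hi ? 1 : 0) + 1;
                if (nCtx <= 0) continue;
                // h = mean over context words of their (composed) vectors
                std::fill(h.begin(), h.end(), 0.0);
                for (int c = lo; c <= hi; ++c) {
                    if (c == t) continue;
                    for (int r : rowsOf[sn[c]])
                        for (int d = 0; d < dim; ++d) h[d] += win(d, r);
                }
                for (int d = 0; d < dim; ++d) h[d] /= nCtx;
                std::fill(gh.begin(), gh.end(), 0.0);
                const int target = sn[t];

                if (fullSoftmax) {
                    double mx = -1e300;
                    for (int k = 0; k < V; ++k) {
                        double sc = 0.0;
                        for (int d = 0; d < dim; ++d) sc += wout(d, k) * h[d];
                        scores[k] = sc;
                        if (sc > mx) mx = sc;
                    }
                    double Z = 0.0;
                    for (int k = 0; k < V; ++k) {
                        scores[k] = std::exp(scores[k] - mx);
                        Z += scores[k];
                    }
                    lossSum += -std::log(scores[target] / Z);
                    for (int k = 0; k < V; ++k) {
                        double g = scores[k] / Z - (k == target ? 1.0 : 0.0);
                        for (int d = 0; d < dim; ++d) {
                            gh[d] += g * wout(d, k);
                            wout(d, k) -= lr * g * h[d];
                        }
                    }
                } else {
                    for (int m = 0; m <= negative; ++m) {
                        int wj; double label;
                        if (m == 0) { wj = target; label = 1.0; }
                        else {
                            wj = sampleCum(cum, unif_rand());
                            if (wj == target) continue;
                            label = 0.0;
                        }
                        double sc = 0.0;
                        for (int d = 0; d < dim; ++d) sc += wout(d, wj) * h[d];
                        double p = sigmoid(sc);
                        lossSum += label > 0.5 ? -std::log(std::max(p, 1e-12))
                                               : -std::log(std::max(1.0 - p, 1e-12));
                        double g = p - label;
                        for (int d = 0; d < dim; ++d) {
                            gh[d] += g * wout(d, wj);
                            wout(d, wj) -= lr * g * h[d];
                        }
                    }
                }
                // distribute dL/dh to the input rows of each context word
                for (int c = lo; c <= hi; ++c) {
                    if (c == t) continue;
                    for (int r : rowsOf[sn[c]])
                        for (int d = 0; d < dim; ++d)
                            win(d, r) -= lr * gh[d] / nCtx;
                }
                ++nTargets;
            }
        }
        lossTrace[ep] = nTargets > 0 ? lossSum / nTargets : 0.0;
    }
    return lossTrace;
}

static double gloveLoss(const std::vector<int>& ti, const std::vector<int>& tj,
                        const std::vector<double>& fx,
                        const std::vector<double>& lx,
                        NumericMatrix w, NumericMatrix wc,
                        NumericVector b, NumericVector bc) {
    const int dim = w.nrow();
    double loss = 0.0;
    for (size_t e = 0; e < ti.size(); ++e) {
        double dot = 0.0;
        for (int d = 0; d < dim; ++d) dot += w(d, ti[e]) * wc(d, tj[e]);
        double diff = dot + b[ti[e]] + bc[tj[e]] - lx[e];
        loss += fx[e] * diff * diff;
    }
    return loss;
}

// GloVe: minimise sum f(X_ij) (v_i'v~_j + b_i + b~_j - log X_ij)^2 over the
// nonzero co-occurrence entries. `w`/`wc` are stored transposed (dim x V). adagrad=true gives the usual per-entry
// AdaGrad SGD with seeded shuffling; adagrad=false does deterministic
// full-batch gradient descent with a fixed step (monotone for small steps).
// Returns loss evaluated after each epoch's updates.
// [[Rcpp::export]]
NumericVector cpp_glove_train(IntegerVector ivec, IntegerVector jvec,
                              NumericVector xvec, NumericMatrix w,
                              NumericMatrix wc, NumericVector b,
                              NumericVector bc, int epochs, double lr,
                              double xmax, double alpha, bool adagrad) {
    const int dim = w.nrow(), V = w.ncol();
    const size_t nnz = ivec.size();
    std::vector<int> ti(ivec.begin(), ivec.end()), tj(jvec.begin(), jvec.end());
    std::vector<double> fx(nnz), lx(nnz);
    for (size_t e = 0; e < nnz; ++e) {
        double r = xvec[e] / xmax;
        fx[e] = r < 1.0 ? std::pow(r, alpha) : 1.0;
        lx[e] = std::log(xvec[e]);
    }
    NumericVector lossTrace(epochs);

    if (adagrad) {
        NumericMatrix gw(dim, V), gwc(dim, V);
        std::fill(gw.begin(), gw.end(), 1.0);
        std::fill(gwc.begin(), gwc.end(), 1.0);
        std::vector<double> gb(V, 1.0), gbc(V, 1.0);
        std::vector<size_t> ord(nnz);
        for (size_t e = 0; e < nnz; ++e) ord[e] = e;
        for (int ep = 0; ep < epochs; ++ep) {
            for (size_t e = nnz; e > 1; --e) {           // Fisher-Yates
                size_t k = (size_t)(unif_rand() * e);
                if (k >= e) k = e - 1;
                std::swap(ord[e - 1], ord[k]);
            }
            for (size_t q = 0; q < nnz; ++q) {
                size_t e = ord[q];
                int i = ti[e], j = tj[e];
                double dot = 0.0;
                for (int d = 0; d < dim; ++d) dot += w(d, i) * wc(d, j);
                double diff = dot + b[i] + bc[j] - lx[e];
                double g = 2.0 * fx[e] * diff;
                for (int d = 0; d < dim; ++d) {
                    double gi = g * wc(d, j), gj = g * w(d, i);
                    w(d, i)  -= lr * gi / std::sqrt(gw(d, i));
                    wc(d, j) -= lr * gj / std::sqrt(gwc(d, j));
                    gw(d, i)  += gi * gi;
                    gwc(d, j) += gj * gj;
                }
                b[i]  -= lr * g / std::sqrt(gb[i]);  gb[i]  += g * g;
                bc[j] -= lr * g / std::sqrt(gbc[j]); gbc[j] += g * g;
            }
            lossTrace[ep] = gloveLoss(ti, tj, fx, lx, w, wc, b, bc);
        }
    } else {
        NumericMatrix dw(dim, V), dwc(dim, V);
        std::vector<double> db(V), dbc(V);
        for (int ep = 0; ep < epochs; ++ep) {
            std::fill(dw.begin(), dw.end(), 0.0);
            std::fill(dwc.begin(), dwc.end(), 0.0);
            std::fill(db.begin(), db.end(), 0.0);
            std::fill(dbc.begin(), dbc.end(), 0.0);
            for (size_t e = 0; e < nnz; ++e) {
                int i = ti[e], j = tj[e];
                double dot = 0.0;
                for (int d = 0; d < dim; ++d) dot += w(d, i) * wc(d, j);
                double diff = dot + b[i] + bc[j] - lx[e];
                double g = 2.0 * fx[e] * diff;
                for (int d = 0; d < dim; ++d) {
                    dw(d, i)  += g * wc(d, j);
                    dwc(d, j) += g * w(d, i);
                }
                db[i] += g; dbc[j] += g;
            }
            for (int i = 0; i < V; ++i) {
                for (int d = 0; d < dim; ++d) {
                    w(d, i)  -= lr * dw(d, i);
                    wc(d, i) -= lr * dwc(d, i);
                }
                b[i]  -= lr * db[i];
                bc[i] -= lr * dbc[i];
            }
            lossTrace[ep] = gloveLoss(ti, tj, fx, lx, w, wc, b, bc);
        }
    }
    return lossTrace;
}
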