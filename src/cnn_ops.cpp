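// Fast path for CNN training and inference. One call runs the full
// forward + backward pass for a mini-batch (cpp_cnn_batch) or the
// inference forward pass (cpp_cnn_forward). Semantics mirror the base-R
// reference implementation in R/cnn.R (im2col/col2im, channel batch-norm,
// width-2 pooling); dropout randomness comes from R's RNG so set.seed()
// in the calling R code is honoured.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Patch matrix for valid 1-D convolution. A is a cube (B, L, C) whose
// memory layout matches an R array with dim c(B, L, C). Output is
// (B*Lout) x (k*C), column (j*C + c) holding positions j..j+Lout-1 of
// channel c — the same layout as the R im2col().
static arma::mat im2col_c(const arma::cube& A, int k) {
    const int B = A.n_rows, L = A.n_cols, C = A.n_slices;
    const int Lout = L - k + 1;
    arma::mat Xc(B * Lout, k * C);
    for (int j = 0; j < k; ++j)
        for (int c = 0; c < C; ++c) {
            const arma::mat sl = A.slice(c).cols(j, j + Lout - 1);
            Xc.col(j * C + c) = arma::vectorise(sl);
        }
    return Xc;
}

static arma::cube col2im_c(const arma::mat& dXc, int B, int L, int C, int k) {
    const int Lout = L - k + 1;
    arma::cube dA(B, L, C, arma::fill::zeros);
    for (int j = 0; j < k; ++j)
        for (int c = 0; c < C; ++c) {
            arma::mat part(dXc.colptr(j * C + c), B, Lout);
            dA.slice(c).cols(j, j + Lout - 1) += part;
        }
    return dA;
}

// Reinterpret a (B*L) x C matrix as a cube (B, L, C); both share the
// column-major layout of the R array so this is a straight copy.
static arma::cube matToCube(const arma::mat& M, int B, int L, int C) {
    return arma::cube(M.memptr(), B, L, C);
}

static arma::mat cubeToMat(const arma::cube& A) {
    return arma::mat(A.memptr(), A.n_rows * A.n_cols, A.n_slices);
}

struct LayerCache {
    arma::mat Xc;          // im2col patches
    arma::cube preRelu;    // pre-activation after BN
    arma::ucube poolMask;  // 1 where the first of each pair won (max pool)
    arma::cube dropMask;
    arma::mat xhat;        // BN normalised input, (B*Lout) x C
    arma::vec invsd;
    int inL, inC, Lout;
};

// [[Rcpp::export]]
List cpp_cnn_batch(List params, List running, const arma::mat& Xb,
                   const arma::vec& y, IntegerVector kernels,
                   IntegerVector filters, bool batchNorm, int poolType,
                   double dropout, int hiddenUnits, bool training,
                   double momentum, double eps) {
    const int B = Xb.n_rows;
    const int nConv = kernels.size();
    arma::cube A(Xb.memptr(), B, Xb.n_cols, 1);
    std::vector<LayerCache> caches(nConv);
    List runningOut = clone(running);

    // ---- forward ----
    for (int l = 0; l < nConv; ++l) {
        const int k = kernels[l];
        LayerCache& cc = caches[l];
        cc.inL = A.n_cols; cc.inC = A.n_slices;
        cc.Lout = cc.inL - k + 1;
        cc.Xc = im2col_c(A, k);
        const arma::mat W = as<arma::mat>(params[std::string("conv") +
                                                 std::to_string(l + 1) + ".W"]);
        const arma::vec b = as<arma::vec>(params[std::string("conv") +
                                                 std::to_string(l + 1) + ".b"]);
        arma::mat Z = cc.Xc * W;
        Z.each_row() += b.t();
        const int F = Z.n_cols;
        if (batchNorm) {
            const arma::vec gamma = as<arma::vec>(
                params[std::string("conv") + std::to_string(l + 1) + ".gamma"]);
            const arma::vec beta = as<arma::vec>(
                params[std::string("conv") + std::to_string(l + 1) + ".beta"]);
            arma::vec mu(F), v(F);
            List rl = runningOut[l];
            arma::vec rmean = as<arma::vec>(rl["mean"]);
            arma::vec rvar = as<arma::vec>(rl["var"]);
            if (training) {
                mu = arma::mean(Z, 0).t();
                v = arma::mean(arma::square(Z), 0).t() - arma::square(mu);
                v.clamp(0.0, arma::datum::inf);
                rmean = momentum * rmean + (1 - momentum) * mu;
                rvar = momentum * rvar + (1 - momentum) * v;
                runningOut[l] = List::create(_["mean"] = rmean,
                                             _["var"] = rvar);
            } else {
                mu = rmean; v = rvar;
            }
            cc.invsd = 1.0 / arma::sqrt(v + eps);
            Z.each_row() -= mu.t();
            Z.each_row() %= cc.invsd.t();
            cc.xhat = Z;
            Z.each_row() %= gamma.t();
            Z.each_row() += beta.t();
        }
        arma::cube Zarr = matToCube(Z, B, cc.Lout, F);
        cc.preRelu = Zarr;
        Zarr.transform([](double x) { return x > 0 ? x : 0.0; });
        // width-2 pooling, odd tail dropped; ties route to the first element
        const int Lp = cc.Lout / 2;
        arma::cube P(B, Lp, F);
        if (poolType == 0) cc.poolMask.set_size(B, Lp, F);
        for (int c = 0; c < F; ++c)
            for (int p = 0; p < Lp; ++p) {
                const arma::vec a1 = Zarr.slice(c).col(2 * p);
                const arma::vec a2 = Zarr.slice(c).col(2 * p + 1);
                if (poolType == 0) {
                    cc.poolMask.slice(c).col(p) = (a1 >= a2);
                    P.slice(c).col(p) = arma::max(a1, a2);
                } else {
                    P.slice(c).col(p) = (a1 + a2) / 2.0;
                }
            }
        if (training && dropout > 0) {
            cc.dropMask.set_size(B, Lp, F);
            for (arma::uword i = 0; i < cc.dropMask.n_elem; ++i)
                cc.dropMask(i) = unif_rand() >= dropout ? 1.0 : 0.0;
            P %= cc.dropMask;
            P /= (1.0 - dropout);
        }
        A = P;
    }

    const int flat = A.n_cols * A.n_slices;
    arma::mat Aflat(A.memptr(), B, flat);
    arma::mat H, Zh, maskH;
    arma::mat outIn;
    if (hiddenUnits > 0) {
        const arma::mat dW = as<arma::mat>(params["dense.W"]);
        const arma::vec db = as<arma::vec>(params["dense.b"]);
        Zh = Aflat * dW;
        Zh.each_row() += db.t();
        H = arma::clamp(Zh, 0.0, arma::datum::inf);
        if (training && dropout > 0) {
            maskH.set_size(H.n_rows, H.n_cols);
            for (arma::uword i = 0; i < maskH.n_elem; ++i)
                maskH(i) = unif_rand() >= dropout ? 1.0 : 0.0;
            H %= maskH;
            H /= (1.0 - dropout);
        }
        outIn = H;
    } else outIn = Aflat;
    const arma::mat oW = as<arma::mat>(params["out.W"]);
    const double ob = as<double>(params["out.b"]);
    arma::vec z = outIn * oW.col(0) + ob;
    arma::vec prob = 1.0 / (1.0 + arma::exp(-z));

    if (!training)
        return List::create(_["prob"] = prob);

    // ---- backward (BCE + sigmoid) ----
    List grads;
    arma::vec dz = (prob - y) / B;
    grads["out.W"] = arma::mat(outIn.t() * dz);
    grads["out.b"] = arma::accu(dz);
    arma::mat dOutIn = dz * oW.col(0).t();
    arma::mat dAflat;
    if (hiddenUnits > 0) {
        arma::mat dH = dOutIn;
        if (maskH.n_elem > 0) dH %= maskH / (1.0 - dropout);
        arma::mat dZh = dH % arma::conv_to<arma::mat>::from(Zh > 0);
        grads["dense.W"] = arma::mat(Aflat.t() * dZh);
        grads["dense.b"] = arma::vec(arma::sum(dZh, 0).t());
        const arma::mat dW = as<arma::mat>(params["dense.W"]);
        dAflat = dZh * dW.t();
    } else dAflat = dOutIn;

    arma::cube dA(dAflat.memptr(), B, A.n_cols, A.n_slices);
    for (int l = nConv - 1; l >= 0; --l) {
        LayerCache& cc = caches[l];
        const int F = cc.preRelu.n_slices;
        const int Lp = dA.n_cols;
        if (cc.dropMask.n_elem > 0)
            dA %= cc.dropMask / (1.0 - dropout);
        // un-pool to the pre-pool width
        arma::cube dZ(B, cc.Lout, F, arma::fill::zeros);
        for (int c = 0; c < F; ++c)
            for (int p = 0; p < Lp; ++p) {
                if (poolType == 0) {
                    const arma::vec m = arma::conv_to<arma::vec>::from(
                        cc.poolMask.slice(c).col(p));
                    dZ.slice(c).col(2 * p) = dA.slice(c).col(p) % m;
                    dZ.slice(c).col(2 * p + 1) = dA.slice(c).col(p) % (1.0 - m);
                } else {
                    dZ.slice(c).col(2 * p) = dA.slice(c).col(p) / 2.0;
                    dZ.slice(c).col(2 * p + 1) = dA.slice(c).col(p) / 2.0;
                }
            }
        for (arma::uword i = 0; i < dZ.n_elem; ++i)
            if (cc.preRelu(i) <= 0) dZ(i) = 0.0;
        arma::mat dZmat = cubeToMat(dZ);
        if (batchNorm) {
            const arma::vec gamma = as<arma::vec>(
                params[std::string("conv") + std::to_string(l + 1) + ".gamma"]);
            grads[std::string("conv") + std::to_string(l + 1) + ".gamma"] =
                arma::vec(arma::sum(dZmat % cc.xhat, 0).t());
            grads[std::string("conv") + std::to_string(l + 1) + ".beta"] =
                arma::vec(arma::sum(dZmat, 0).t());
            arma::mat dxhat = dZmat;
            dxhat.each_row() %= gamma.t();
            const arma::rowvec mean_dxhat = arma::mean(dxhat, 0);
            const arma::rowvec mean_dxx = arma::mean(dxhat % cc.xhat, 0);
            dxhat.each_row() -= mean_dxhat;
            dxhat -= cc.xhat.each_row() % mean_dxx;
            dxhat.each_row() %= cc.invsd.t();
            dZmat = dxhat;
        }
        const arma::mat W = as<arma::mat>(params[std::string("conv") +
                                                 std::to_string(l + 1) + ".W"]);
        grads[std::string("conv") + std::to_string(l + 1) + ".W"] =
            arma::mat(cc.Xc.t() * dZmat);
        grads[std::string("conv") + std::to_string(l + 1) + ".b"] =
            arma::vec(arma::sum(dZmat, 0).t());
        arma::mat dXc = dZmat * W.t();
        dA = col2im_c(dXc, B, cc.inL, cc.inC, kernels[l]);
    }

    return List::create(_["prob"] = prob, _["grads"] = grads,
                        _["running"] = runningOut);
}

// [[Rcpp::export]]
List cpp_cnn_forward(List params, List running, const arma::mat& Xb,
                     IntegerVector kernels, IntegerVector filters,
                     bool batchNorm, int poolType, int hiddenUnits,
                     double eps) {
    arma::vec dummy(Xb.n_rows, arma::fill::zeros);
    return cpp_cnn_batch(params, running, Xb, dummy, kernels, filters,
                         batchNorm, poolType, 0.0, hiddenUnits, false,
                         0.9, eps);
}
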