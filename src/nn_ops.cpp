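// Hot paths for the 1D CNN and attribution backgrounds.
// Layout convention: an input batch is a cube with dimensions (L, C, B):
// position fastest, then channel, then sample. Conv weights are a cube
// (k, C, F). All loops are single-threaded; BLAS does the heavy lifting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for one sample: M(P, k*C), column c*k + o = X(o : o+P-1, c)
static void im2col(const mat &Xs, int k, int P, mat &M) {
    const int C = Xs.n_cols;
    for (int c = 0; c < C; ++c)
        for (int o = 0; o < k; ++o)
            M.col((uword)c * k + o) = Xs(span(o, o + P - 1), c);
}

// [[Rcpp::export(rng = false)]]
arma::cube conv1d_fwd(const arma::cube &X, const arma::cube &W,
                      const arma::vec &b) {
    const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
    const int k = W.n_rows, F = W.n_slices;
    if ((int)W.n_cols != C) Rcpp::stop("conv1d_fwd: channel mismatch");
    const int P = L - k + 1;
    if (P < 1) Rcpp::stop("conv1d_fwd: kernel wider than input");
    mat Wm((double *)W.memptr(), k * C, F);  // (o + c*k, f), no copy
    cube Y(P, F, B);
    mat M(P, k * C);
    for (int s = 0; s < B; ++s) {
        im2col(X.slice(s), k, P, M);
        Y.slice(s) = M * Wm;
        Y.slice(s).each_row() += b.t();
    }
    return Y;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List conv1d_bwd(const arma::cube &X, const arma::cube &W,
                      const arma::cube &dY, const bool need_dx) {
    const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
    const int k = W.n_rows, F = W.n_slices;
    const int P = L - k + 1;
    mat Wm((double *)W.memptr(), k * C, F);
    mat dWm(k * C, F, fill::zeros);
    vec db(F, fill::zeros);
    cube dX;
    if (need_dx) dX.zeros(L, C, B);
    mat M(P, k * C);
    for (int s = 0; s < B; ++s) {
        im2col(X.slice(s), k, P, M);
        dWm += M.t() * dY.slice(s);
        db += sum(dY.slice(s), 0).t();
        if (need_dx) {
            mat dM = dY.slice(s) * Wm.t();  // P x kC
            for (int c = 0; c < C; ++c)
                for (int o = 0; o < k; ++o)
                    dX.slice(s)(span(o, o + P - 1), c) +=
                        dM.col((uword)c * k + o);
        }
    }
    cube dW(dWm.memptr(), k, C, F);
    return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                              Rcpp::Named("dX") = dX);
}

// Max pooling over non-overlapping windows of width w along the first
// dimension; trailing remainder positions are dropped. Returns the pooled
// cube and 1-based argmax positions for the backward pass.
// [[Rcpp::export(rng = false)]]
Rcpp::List maxpool_fwd(const arma::cube &Y, const int w) {
    const int P = Y.n_rows, F = Y.n_cols, B = Y.n_slices;
    const int Q = P / w;
    if (Q < 1) Rcpp::stop("maxpool_fwd: pool width exceeds input length");
    cube out(Q, F, B);
    icube idx(Q, F, B);
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f)
            for (int q = 0; q < Q; ++q) {
                int base = q * w, best = base;
                double m = Y(base, f, s);
                for (int i = 1; i < w; ++i)
                    if (Y(base + i, f, s) > m) { m = Y(base + i, f, s); best = base + i; }
                out(q, f, s) = m;
                idx(q, f, s) = best + 1;
            }
    return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(rng = false)]]
arma::cube maxpool_bwd(const arma::icube &idx, const arma::cube &dOut,
                       const int P) {
    const int Q = dOut.n_rows, F = dOut.n_cols, B = dOut.n_slices;
    cube dY(P, F, B, fill::zeros);
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f)
            for (int q = 0; q < Q; ++q)
                dY(idx(q, f, s) - 1, f, s) += dOut(q, f, s);
    return dY;
}

// Altschul-Erickson dinucleotide-preserving shuffle of an integer-coded
// sequence (values 0..3). Preserves the exact dinucleotide count vector and
// the first and last characters. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
Rcpp::IntegerVector dinuc_shuffle_one(const Rcpp::IntegerVector &seq) {
    const int L = seq.size();
    if (L < 2) Rcpp::stop("dinuc_shuffle_one: sequence shorter than 2");
    const int A = 4;
    std::vector<std::vector<int>> out(A);
    for (int i = 0; i + 1 < L; ++i) out[seq[i]].push_back(seq[i + 1]);
    const int s0 = seq[0], sEnd = seq[L - 1];

    // pick a random last-exit edge per vertex (except the end vertex) until
    // the chosen edges form paths that all reach the end vertex
    std::vector<int> last(A, -1);
    bool ok = false;
    while (!ok) {
        for (int v = 0; v < A; ++v) {
            last[v] = -1;
            if (v != sEnd && !out[v].empty())
                last[v] = out[v][(int)(R::unif_rand() * out[v].size())];
        }
        ok = true;
        for (int v = 0; v < A && ok; ++v) {
            if (out[v].empty() || v == sEnd) continue;
            int u = v, steps = 0;
            while (u != sEnd && steps <= A) {
                if (last[u] < 0) break;
                u = last[u];
                ++steps;
            }
            if (u != sEnd) ok = false;
        }
    }

    // shuffle remaining out-edges, appending the reserved last-exit edge
    std::vector<std::vector<int>> lists(A);
    for (int v = 0; v < A; ++v) {
        std::vector<int> pool = out[v];
        if (last[v] >= 0) {
            // remove one instance of the reserved edge
            for (size_t i = 0; i < pool.size(); ++i)
                if (pool[i] == last[v]) { pool.erase(pool.begin() + i); break; }
        }
        for (int i = (int)pool.size() - 1; i > 0; --i) {
            int j = (int)(R::unif_rand() * (i + 1));
            std::swap(pool[i], pool[j]);
        }
        if (last[v] >= 0) pool.push_back(last[v]);
        lists[v] = pool;
    }

    // walk the Eulerian path
    Rcpp::IntegerVector res(L);
    std::vector<size_t> ptr(A, 0);
    int v = s0;
    res[0] = v;
    for (int i = 1; i < L; ++i) {
        int u = lists[v][ptr[v]++];
        res[i] = u;
        v = u;
    }
    return res;
}

// Batch-norm helpers on (P, F, B) cubes: per-filter statistics over the
// position and sample dimensions.
// [[Rcpp::export(rng = false)]]
Rcpp::List bn_stats(const arma::cube &Z) {
    const int P = Z.n_rows, F = Z.n_cols, B = Z.n_slices;
    vec mu(F, fill::zeros), m2(F, fill::zeros);
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f) {
            const double *col = Z.slice(s).colptr(f);
            for (int p = 0; p < P; ++p) {
                mu[f] += col[p];
                m2[f] += col[p] * col[p];
            }
        }
    const double N = (double)P * B;
    mu /= N;
    vec v = m2 / N - mu % mu;
    return Rcpp::List::create(Rcpp::Named("mean") = mu, Rcpp::Named("var") = v);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List bn_apply(const arma::cube &Z, const arma::vec &mu,
                    const arma::vec &scale, const arma::vec &gamma,
                    const arma::vec &beta) {
    const int P = Z.n_rows, F = Z.n_cols, B = Z.n_slices;
    cube zhat(P, F, B), out(P, F, B);
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f) {
            const double *col = Z.slice(s).colptr(f);
            double *zh = zhat.slice(s).colptr(f);
            double *o = out.slice(s).colptr(f);
            for (int p = 0; p < P; ++p) {
                zh[p] = (col[p] - mu[f]) * scale[f];
                o[p] = zh[p] * gamma[f] + beta[f];
            }
        }
    return Rcpp::List::create(Rcpp::Named("out") = out,
                              Rcpp::Named("zhat") = zhat);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List bn_bwd(const arma::cube &dOut, const arma::cube &Zhat,
                  const arma::vec &gamma, const arma::vec &scale,
                  const bool training) {
    const int P = dOut.n_rows, F = dOut.n_cols, B = dOut.n_slices;
    vec dgamma(F, fill::zeros), dbeta(F, fill::zeros);
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f) {
            const double *dcol = dOut.slice(s).colptr(f);
            const double *zh = Zhat.slice(s).colptr(f);
            for (int p = 0; p < P; ++p) {
                dgamma[f] += dcol[p] * zh[p];
                dbeta[f] += dcol[p];
            }
        }
    cube dZ(P, F, B);
    const double N = (double)P * B;
    for (int s = 0; s < B; ++s)
        for (int f = 0; f < F; ++f) {
            const double *dcol = dOut.slice(s).colptr(f);
            const double *zh = Zhat.slice(s).colptr(f);
            double *o = dZ.slice(s).colptr(f);
            if (training) {
                for (int p = 0; p < P; ++p)
                    o[p] = scale[f] * (gamma[f] * dcol[p] -
                                       gamma[f] * dbeta[f] / N -
                                       zh[p] * gamma[f] * dgamma[f] / N);
            } else {
                for (int p = 0; p < P; ++p)
                    o[p] = scale[f] * gamma[f] * dcol[p];
            }
        }
    return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                              Rcpp::Named("dgamma") = dgamma,
                              Rcpp::Named("dbeta") = dbeta);
}
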