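// SPD-matrix primitives shared by the Riemannian decoders. All matrix
// functions go through a symmetric eigendecomposition with an eigenvalue
// floor so that numerically semi-definite inputs stay on the manifold.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EIG_FLOOR = 1e-12;

static mat sym(const mat& M) { return 0.5 * (M + M.t()); }

static mat eig_fun(const mat& M, double (*f)(double)) {
    vec d; mat V;
    if (!eig_sym(d, V, sym(M)))
        Rcpp::stop("eigendecomposition failed");
    d = clamp(d, EIG_FLOOR, datum::inf);
    d.transform([f](double v) { return f(v); });
    return V * diagmat(d) * V.t();
}

static double id_fun(double v)      { return v; }
static double log_fun(double v)     { return std::log(v); }
static double sqrt_fun(double v)    { return std::sqrt(v); }
static double invsqrt_fun(double v) { return 1.0 / std::sqrt(v); }

// [[Rcpp::export(name = ".spd_fun_cpp")]]
arma::mat spd_fun_cpp(const arma::mat& M, const std::string& what) {
    if (what == "log")     return eig_fun(M, log_fun);
    if (what == "exp")     return expmat_sym(sym(M));
    if (what == "sqrt")    return eig_fun(M, sqrt_fun);
    if (what == "invsqrt") return eig_fun(M, invsqrt_fun);
    if (what == "floor")   return eig_fun(M, id_fun);
    Rcpp::stop("unknown matrix function");
}

// Affine-invariant Riemannian distance: ||log(A^-1/2 B A^-1/2)||_F.
// [[Rcpp::export(name = ".airm_dist_cpp")]]
double airm_dist_cpp(const arma::mat& A, const arma::mat& B) {
    mat W = eig_fun(A, invsqrt_fun);
    vec d; mat V;
    if (!eig_sym(d, V, sym(W * B * W)))
        Rcpp::stop("eigendecomposition failed");
    d = clamp(d, EIG_FLOOR, datum::inf);
    return std::sqrt(accu(square(log(d))));
}

// Fixed-point (gradient descent) iteration for the Frechet mean under the
// affine-invariant metric, initialised at the arithmetic mean.
// [[Rcpp::export(name = ".riemannian_mean_cpp")]]
Rcpp::List riemannian_mean_cpp(const Rcpp::List& mats, double tol, int max_iter) {
    const int m = mats.size();
    std::vector<mat> C(m);
    for (int i = 0; i < m; ++i) C[i] = Rcpp::as<mat>(mats[i]);
    mat G = C[0];
    for (int i = 1; i < m; ++i) G += C[i];
    G = sym(G / m);
    double crit = datum::inf;
    int it = 0;
    for (; it < max_iter; ++it) {
        mat Gs = eig_fun(G, sqrt_fun);
        mat Gis = eig_fun(G, invsqrt_fun);
        mat S(G.n_rows, G.n_cols, fill::zeros);
        for (int i = 0; i < m; ++i) {
            S += eig_fun(Gis * C[i] * Gis, log_fun);
        }
        S /= m;
        crit = norm(S, "fro");
        if (crit < tol) break;
        G = sym(Gs * expmat_sym(sym(S)) * Gs);
    }
    return Rcpp::List::create(Rcpp::Named("mean") = G,
                              Rcpp::Named("crit") = crit,
                              Rcpp::Named("iterations") = it,
                              Rcpp::Named("converged") = crit < tol);
}

// Tangent-space coordinates at `ref` for a list of SPD matrices: rows are
// half-vectorizations (column-major upper triangle, off-diagonals * sqrt(2))
// of log(ref^-1/2 C ref^-1/2), so Euclidean norms equal AIRM distances.
// [[Rcpp::export(name = ".tangent_vecs_cpp")]]
arma::mat tangent_vecs_cpp(const Rcpp::List& mats, const arma::mat& ref) {
    const int m = mats.size();
    const unsigned int n = ref.n_rows;
    const double s2 = std::sqrt(2.0);
    mat W = eig_fun(ref, invsqrt_fun);
    mat out(m, n * (n + 1) / 2);
    for (int i = 0; i < m; ++i) {
        mat C = Rcpp::as<mat>(mats[i]);
        mat S = eig_fun(W * C * W, log_fun);
        unsigned int k = 0;
        for (unsigned int j = 0; j < n; ++j)
            for (unsigned int r = 0; r <= j; ++r)
                out(i, k++) = (r == j) ? S(r, j) : s2 * S(r, j);
    }
    return out;
}

// Per-trial covariances of a time window across trials stored side by side:
// X is samples x (n_ch * n_trials) with trial-major column blocks; rows
// i0..i1 (0-based, inclusive) are used.
// [[Rcpp::export(name = ".window_covs_cpp")]]
Rcpp::List window_covs_cpp(const arma::mat& X, int n_ch, int i0, int i1,
                           double lambda) {
    const int n_tr = X.n_cols / n_ch;
    const int T = i1 - i0 + 1;
    Rcpp::List out(n_tr);
    for (int tr = 0; tr < n_tr; ++tr) {
        mat sub = X.submat(i0, tr * n_ch, i1, tr * n_ch + n_ch - 1);
        sub.each_row() -= mean(sub, 0);
        mat C = (sub.t() * sub) / double(T - 1);
        if (lambda > 0.0) {
            double mu = trace(C) / n_ch;
            C = (1.0 - lambda) * C + lambda * mu * eye(n_ch, n_ch);
        }
        out[tr] = sym(C);
    }
    return out;
}

// Per-trial spatial covariance with shrinkage toward (trace/n) * I, computed
// on mean-removed rows. X is channels x samples.
// [[Rcpp::export(name = ".cov_shrink_cpp")]]
arma::mat cov_shrink_cpp(const arma::mat& X, double lambda) {
    const unsigned int T = X.n_cols;
    mat Xc = X.each_col() - mean(X, 1);
    mat C = (Xc * Xc.t()) / double(T - 1);
    if (lambda > 0.0) {
        double mu = trace(C) / C.n_rows;
        C = (1.0 - lambda) * C + lambda * mu * eye(C.n_rows, C.n_rows);
    }
    return sym(C);
}
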