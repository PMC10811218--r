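// Cross-validated surrogate classifier used as the window/band selection
// fitness: per-fold Gram-matrix PCA (cap pmax), regularized Fisher
// discriminant, nearest-centroid decision. Returns accuracy pooled over
// the folds, averaged across the supplied fold assignments.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".surrogate_cv_cpp")]]
double surrogate_cv_cpp(const arma::mat& scores, const arma::ivec& labels,
                        const arma::imat& folds, int pmax, double reg) {
    const int n = scores.n_rows;
    double acc_sum = 0.0;
    for (unsigned int r = 0; r < folds.n_cols; ++r) {
        int correct = 0;
        const ivec fold = folds.col(r);
        const int n_folds = fold.max();
        for (int f = 1; f <= n_folds; ++f) {
            uvec tr = find(fold != f), te = find(fold == f);
            mat Xtr = scores.rows(tr);
            rowvec ctr = mean(Xtr, 0);
            Xtr.each_row() -= ctr;
            mat K = Xtr * Xtr.t();
            vec ev; mat U;
            if (!eig_sym(ev, U, symmatu(K))) continue;
            // eigenvalues ascending -> take the top ones
            int avail = 0;
            double emax = ev.max();
            for (unsigned int i = 0; i < ev.n_elem; ++i)
                if (ev(i) > emax * 1e-10) ++avail;
            int p = std::min(std::min((int)tr.n_elem - 2, pmax), avail);
            if (p < 1) continue;
            mat Up = U.cols(U.n_cols - p, U.n_cols - 1);
            vec lam = ev.subvec(ev.n_elem - p, ev.n_elem - 1);
            mat Ztr = Up * diagmat(sqrt(lam));
            mat V = Xtr.t() * Up * diagmat(1.0 / sqrt(lam));
            // Fisher direction with ridge
            ivec ytr = labels(tr);
            uvec i1 = find(ytr == 1), i2 = find(ytr == 2);
            rowvec m1 = mean(Ztr.rows(i1), 0), m2 = mean(Ztr.rows(i2), 0);
            mat Z1 = Ztr.rows(i1); Z1.each_row() -= m1;
            mat Z2 = Ztr.rows(i2); Z2.each_row() -= m2;
            mat Sw = (Z1.t() * Z1 + Z2.t() * Z2) / double(tr.n_elem - 2);
            double gamma = reg * trace(Sw) / p + 1e-12;
            vec w = solve(Sw + gamma * eye(p, p), (m2 - m1).t(),
                          solve_opts::fast);
            double thr = dot(w, 0.5 * (m1 + m2));
            mat Xte = scores.rows(te);
            Xte.each_row() -= ctr;
            vec z = Xte * V * w;
            for (unsigned int i = 0; i < te.n_elem; ++i) {
                int pred = z(i) > thr ? 2 : 1;
                if (pred == labels(te(i))) ++correct;
            }
        }
        acc_sum += double(correct) / n;
    }
    return acc_sum / folds.n_cols;
}
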