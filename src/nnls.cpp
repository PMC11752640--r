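#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - b||^2 subject to x >= 0.
// Small dense systems (tens of columns), called once per voxel and
// regularization candidate, hence compiled.
// [[Rcpp::export]]
arma::vec nnls_lh(const arma::mat& A, const arma::vec& b, double tol = -1.0,
                  int max_iter = -1) {
    const uword m = A.n_rows, n = A.n_cols;
    if (m != b.n_elem)
        Rcpp::stop("nnls: A has %d rows but b has %d elements", (int)m,
                   (int)b.n_elem);
    if (max_iter < 0) max_iter = 5 * (int)n + 50;
    if (tol < 0) tol = 10.0 * datum::eps * norm(A, "fro") * (double)std::max(m, n);

    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = A.t() * b;  // gradient of -0.5 * RSS at x = 0

    int outer = 0;
    while (outer++ < max_iter) {
        // pick the most promising zero variable
        int jmax = -1;
        double wmax = tol;
        for (uword j = 0; j < n; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = (int)j; }
        }
        if (jmax < 0) break;  // KKT satisfied
        passive[jmax] = true;

        int inner = 0;
        while (inner++ < max_iter) {
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j)
                if (passive[j]) P(np++) = j;
            P.resize(np);

            vec z;
            bool ok = solve(z, A.cols(P), b);  // least-squares via QR
            if (!ok) Rcpp::stop("nnls: least-squares subproblem failed");

            if (z.min() > 0) {
                x.zeros();
                x(P) = z;
                break;
            }
            // step back to the feasibility boundary, drop blocked variables
            double alpha = datum::inf;
            for (uword k = 0; k < np; ++k) {
                if (z(k) <= 0) {
                    double a = x(P(k)) / (x(P(k)) - z(k));
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < np; ++k)
                x(P(k)) += alpha * (z(k) - x(P(k)));
            for (uword k = 0; k < np; ++k) {
                if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
            }
        }
        w = A.t() * (b - A * x);
    }
    return x;
}
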