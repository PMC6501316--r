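#include <Rcpp.h>
using namespace Rcpp;

// Projected Gauss-Seidel sweeps for the ADMM X-subproblem
//   P_Omega(X) + W X = rhs,  X >= 0,
// with W = gamma * I + c * ones(n, n), c = beta / n^2. Column j (one
// gene) decouples from the others; within a column the coupling through
// W is a constant times the column sum, tracked incrementally so a full
// sweep is O(n * m). Each coordinate update is the exact minimiser of
// the one-dimensional restriction of the strictly convex quadratic, so
// the iteration converges to the unique non-negative solution.
// [[Rcpp::export]]
NumericMatrix x_update_sweeps(NumericMatrix rhs, IntegerMatrix omega,
                              double gamma, double c, NumericMatrix Xinit,
                              int maxSweeps, double tol) {
    int n = rhs.nrow(), m = rhs.ncol();
    NumericMatrix X(clone(Xinit));
    std::vector<double> colsum(m);
    for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += X(i, j);
        colsum[j] = s;
    }
    for (int sweep = 0; sweep < maxSweeps; ++sweep) {
        double maxChange = 0.0, maxAbs = 0.0;
        for (int j = 0; j < m; ++j) {
            double s = colsum[j];
            for (int i = 0; i < n; ++i) {
                double old = X(i, j);
                double diagw = gamma + c + (omega(i, j) ? 1.0 : 0.0);
                double v = (rhs(i, j) - c * (s - old)) / diagw;
                if (v < 0.0) v = 0.0;
                X(i, j) = v;
                s += v - old;
                double ch = std::fabs(v - old);
                if (ch > maxChange) maxChange = ch;
                double av = std::fabs(v);
                if (av > maxAbs) maxAbs = av;
            }
            colsum[j] = s;
        }
        if (maxChange <= tol * (1.0 + maxAbs)) break;
    }
    return X;
}
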