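#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for the L1-hinge linear SVM without intercept,
// applied to ranking-constraint difference vectors (all targets +1):
//
//   min_w  0.5*||w||^2 + C * sum_p max(0, 1 - w.x_p)
//
// Dual: max_a sum(a) - 0.5*||X'a||^2, 0 <= a_p <= C.  Each coordinate update
// is exact; sweeps use a shuffled order and stop when the largest projected
// gradient violation over a sweep falls below eps (liblinear-style).
//
// [[Rcpp::export(name = ".dcd_solve")]]
List dcd_solve(NumericMatrix X, double C, double eps = 1e-10,
               int max_epochs = 5000, int seed = 1) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
        qii[i] = s;
    }
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::mt19937 rng(seed);
    int epoch = 0;
    for (epoch = 0; epoch < max_epochs; ++epoch) {
        std::shuffle(order.begin(), order.end(), rng);
        double maxviol = 0.0;
        for (int k = 0; k < n; ++k) {
            const int i = order[k];
            if (qii[i] <= 0.0) continue;  // zero difference vector
            double wx = 0.0;
            for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
            const double G = wx - 1.0;           // dual gradient
            double PG = G;                       // projected gradient
            if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
            if (alpha[i] >= C && G < 0.0) PG = 0.0;
            if (std::fabs(PG) > maxviol) maxviol = std::fabs(PG);
            if (PG != 0.0) {
                const double old = alpha[i];
                double a = old - G / qii[i];
                if (a < 0.0) a = 0.0; else if (a > C) a = C;
                const double delta = a - old;
                if (delta != 0.0) {
                    alpha[i] = a;
                    for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
                }
            }
        }
        if (maxviol < eps) break;
    }
    double wnorm2 = 0.0;
    for (int j = 0; j < d; ++j) wnorm2 += w[j] * w[j];
    double hinge = 0.0;
    for (int i = 0; i < n; ++i) {
        double wx = 0.0;
        for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
        const double xi = 1.0 - wx;
        if (xi > 0.0) hinge += xi;
    }
    return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                        _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                        _["objective"] = 0.5 * wnorm2 + C * hinge,
                        _["epochs"] = epoch + 1,
                        _["converged"] = epoch < max_epochs);
}
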