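#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Three-state global alignment DP with log-affine gap costs
//   C_k = a + b*k + c*log(k)  for a maximal gap of length k.
// States: M (last column is a substitution), X (last column gapped in b,
// i.e. consumes residues of a), Y (gapped in a, consumes b).  A gap run
// is charged as one event of its full length, so X may not follow X nor
// Y follow Y; gap events therefore jump k residues at once and the DP is
// O(n*m*(n+m)).  With free_end, leading and trailing gap runs cost 0.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=T, 4=N (wildcard: scores match).

static inline double sub_cost(int x, int y, double mc, double ts, double tv) {
    if (x == 4 || y == 4 || x == y) return mc;
    // with A=0,C=1,G=2,T=3 the transitions A<->G and C<->T are XOR 2
    return ((x ^ y) == 2) ? ts : tv;
}

// [[Rcpp::export]]
List logaffine_align_cpp(IntegerVector ai, IntegerVector bi,
                         double mc, double ts, double tv,
                         double ga, double gb, double gc,
                         bool free_end, bool traceback) {
    const int n = ai.size(), m = bi.size();
    const double INF = std::numeric_limits<double>::infinity();
    const int nr = n + 1;

    std::vector<double> Ck(std::max(n, m) + 1, 0.0);
    for (int k = 1; k <= std::max(n, m); ++k)
        Ck[k] = ga + gb * k + gc * std::log((double) k);

    std::vector<double> M((size_t) nr * (m + 1), INF);
    std::vector<double> X((size_t) nr * (m + 1), INF);
    std::vector<double> Y((size_t) nr * (m + 1), INF);
    // traceback stores: for M, the previous state; for X/Y the gap length
    // and the state the gap event started from (0 = M, 1 = X, 2 = Y)
    std::vector<signed char> Mfrom, Xfrom, Yfrom;
    std::vector<int> Xk, Yk;
    if (traceback) {
        Mfrom.assign((size_t) nr * (m + 1), -1);
        Xfrom.assign((size_t) nr * (m + 1), -1);
        Yfrom.assign((size_t) nr * (m + 1), -1);
        Xk.assign((size_t) nr * (m + 1), 0);
        Yk.assign((size_t) nr * (m + 1), 0);
    }
#define ID(i, j) ((size_t)(i) + (size_t)(j) * nr)

    M[ID(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[ID(i, 0)] = free_end ? 0.0 : Ck[i];
        if (traceback) { Xk[ID(i, 0)] = i; Xfrom[ID(i, 0)] = 0; }
    }
    for (int j = 1; j <= m; ++j) {
        Y[ID(0, j)] = free_end ? 0.0 : Ck[j];
        if (traceback) { Yk[ID(0, j)] = j; Yfrom[ID(0, j)] = 0; }
    }

    for (int j = 1; j <= m; ++j) {
        for (int i = 1; i <= n; ++i) {
            // substitution
            double dM = M[ID(i - 1, j - 1)], dX = X[ID(i - 1, j - 1)],
                   dY = Y[ID(i - 1, j - 1)];
            double best = dM; signed char from = 0;
            if (dX < best) { best = dX; from = 1; }
            if (dY < best) { best = dY; from = 2; }
            M[ID(i, j)] = best + sub_cost(ai[i - 1], bi[j - 1], mc, ts, tv);
            if (traceback) Mfrom[ID(i, j)] = from;

            // gap run in b of length k, consuming a[i-k .. i-1];
            // may start from M or Y (merging two X runs is one event)
            double bx = INF; int bxk = 0; signed char bxf = 0;
            for (int k = 1; k <= i; ++k) {
                double pm = M[ID(i - k, j)], py = Y[ID(i - k, j)];
                double p = pm <= py ? pm : py;
                if (p + Ck[k] < bx) {
                    bx = p + Ck[k]; bxk = k; bxf = (pm <= py) ? 0 : 2;
                }
            }
            X[ID(i, j)] = bx;
            if (traceback) { Xk[ID(i, j)] = bxk; Xfrom[ID(i, j)] = bxf; }

            // gap run in a of length k, consuming b[j-k .. j-1]
            double by = INF; int byk = 0; signed char byf = 0;
            for (int k = 1; k <= j; ++k) {
                double pm = M[ID(i, j - k)], px = X[ID(i, j - k)];
                double p = pm <= px ? pm : px;
                if (p + Ck[k] < by) {
                    by = p + Ck[k]; byk = k; byf = (pm <= px) ? 0 : 1;
                }
            }
            Y[ID(i, j)] = by;
            if (traceback) { Yk[ID(i, j)] = byk; Yfrom[ID(i, j)] = byf; }
        }
    }

    // endpoint: with free ends any cell on the last row/column may end the
    // charged alignment, the remainder being a free trailing run
    double best = INF; int ei = n, ej = m; signed char est = 0;
    const signed char states[3] = {0, 1, 2};
    if (free_end) {
        for (int i = 0; i <= n; ++i) {
            double v[3] = {M[ID(i, m)], X[ID(i, m)], Y[ID(i, m)]};
            for (int s = 0; s < 3; ++s)
                if (v[s] < best) { best = v[s]; ei = i; ej = m; est = states[s]; }
        }
        for (int j = 0; j <= m; ++j) {
            double v[3] = {M[ID(n, j)], X[ID(n, j)], Y[ID(n, j)]};
            for (int s = 0; s < 3; ++s)
                if (v[s] < best) { best = v[s]; ei = n; ej = j; est = states[s]; }
        }
    } else {
        double v[3] = {M[ID(n, m)], X[ID(n, m)], Y[ID(n, m)]};
        for (int s = 0; s < 3; ++s)
            if (v[s] < best) { best = v[s]; est = states[s]; }
    }

    List out = List::create(Named("cost") = best);
    if (!traceback) return out;

    // rebuild aligned index vectors (-1 = gap), reversed at the end
    std::vector<int> ra, rb;
    for (int i = n; i > ei; --i) { ra.push_back(ai[i - 1]); rb.push_back(-1); }
    for (int j = m; j > ej; --j) { ra.push_back(-1); rb.push_back(bi[j - 1]); }
    int i = ei, j = ej; signed char st = est;
    while (i > 0 || j > 0) {
        if (st == 0) {
            signed char from = Mfrom[ID(i, j)];
            ra.push_back(ai[i - 1]); rb.push_back(bi[j - 1]);
            --i; --j; st = from;
        } else if (st == 1) {
            int k = Xk[ID(i, j)]; signed char from = Xfrom[ID(i, j)];
            for (int t = 0; t < k; ++t) {
                ra.push_back(ai[i - 1 - t]); rb.push_back(-1);
            }
            i -= k; st = from;
        } else {
            int k = Yk[ID(i, j)]; signed char from = Yfrom[ID(i, j)];
            for (int t = 0; t < k; ++t) {
                ra.push_back(-1); rb.push_back(bi[j - 1 - t]);
            }
            j -= k; st = from;
        }
    }
    IntegerVector av(ra.rbegin(), ra.rend()), bv(rb.rbegin(), rb.rend());
    out["a"] = av;
    out["b"] = bv;
    return out;
#undef ID
}
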