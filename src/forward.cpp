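#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Four latent states: 1 stopover, 2 offshore flight, 3 onshore flight, 4
// departed. Observation codes: 1 stopover, 2 offshore, 3 onshore, 4 not
// seen. The forward recursion is carried in log space throughout; -Inf
// marks impossible states and propagates safely through additions.
//
// Valid encounter histories are 1...1 [2|3|4] 4...4 (or all 1). Once the
// history leaves stopover the remaining transition and emission factors
// are exactly one (flight states absorb into "departed", which emits "not
// seen" with probability one), so the recursion can stop at the departure
// occasion; this is an exact shortcut, not an approximation.

static inline double lse2(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
    return lse2(lse2(a, b), c);
}

static inline double lse4(double a, double b, double c, double d) {
    return lse2(lse2(a, b), lse2(c, d));
}

// log(sigmoid(x)), stable for large |x|
static inline double log_sigmoid(double x) {
    return x > 0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// One individual's forward pass. codes: length-T observation vector;
// lpsi/lomp/lchi/lomc: log psi, log(1-psi), log chi, log(1-chi) for
// transitions t -> t+1. Conditions on z_1 = stopover; the occasion-1
// observation contributes nothing.
// earlyExit: stop at the departure occasion (exact only for valid
// histories; the generic entry point keeps the full recursion so that any
// code sequence, including invalid ones, gets its exact marginal).
static double forward_one(const int* codes, int T,
                          const double* lpsi, const double* lomp,
                          const double* lchi, const double* lomc,
                          double lpX, double l1pX, double lpC, double l1pC,
                          bool earlyExit) {
    double la1 = 0.0, la2 = R_NegInf, la3 = R_NegInf, la4 = R_NegInf;
    for (int t = 0; t < T - 1; ++t) {
        double n1 = la1 + lomp[t];
        double n2 = la1 + lpsi[t] + lchi[t];
        double n3 = la1 + lpsi[t] + lomc[t];
        double n4 = lse3(la2, la3, la4);
        int y = codes[t + 1];
        switch (y) {
        case 1:
            la1 = n1; la2 = la3 = la4 = R_NegInf;
            break;
        case 2:
            la2 = n2 + lpX; la1 = la3 = la4 = R_NegInf;
            break;
        case 3:
            la3 = n3 + lpC; la1 = la2 = la4 = R_NegInf;
            break;
        default: // not seen
            la2 = n2 + l1pX; la3 = n3 + l1pC; la4 = n4; la1 = R_NegInf;
            break;
        }
        if (earlyExit && y != 1) break; // departure occasion reached
    }
    return lse4(la1, la2, la3, la4);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_forward_loglik(IntegerMatrix codes,
                                 NumericMatrix psi, NumericMatrix chi,
                                 NumericVector pX, NumericVector pC) {
    int n = codes.nrow(), T = codes.ncol();
    NumericVector out(n);
    std::vector<double> lpsi(T - 1), lomp(T - 1), lchi(T - 1), lomc(T - 1);
    std::vector<int> y(T);
    for (int i = 0; i < n; ++i) {
        for (int t = 0; t < T; ++t) y[t] = codes(i, t);
        for (int t = 0; t < T - 1; ++t) {
            lpsi[t] = std::log(psi(i, t));
            lomp[t] = std::log1p(-psi(i, t));
            lchi[t] = std::log(chi(i, t));
            lomc[t] = std::log1p(-chi(i, t));
        }
        out[i] = forward_one(y.data(), T, lpsi.data(), lomp.data(),
                             lchi.data(), lomc.data(),
                             std::log(pX[i]), std::log1p(-pX[i]),
                             std::log(pC[i]), std::log1p(-pC[i]), false);
    }
    return out;
}

// Total marginal log-likelihood with the linear predictors evaluated in
// C++. Parameter vector layout (S species):
//   [0,S)    b0_psi      [S,2S)  bul_psi   [2S,3S) buq_psi
//   [3S,4S)  bvl_psi     [4S,5S) bvq_psi   [5S,6S) bdp_psi
//   [6S,7S)  bh_psi      [7S]    brain_psi (shared)
//   [7S+1, 8S+1) b0_chi  [8S+1,8S+5) bul/buq/bvl/bvq_chi (shared)
//   [8S+5] qX_ACT  [8S+6] qX_frac  [8S+7] qC_ACT  [8S+8] qC_frac
// Detection probabilities: pX_ACT = sigmoid(qX_ACT),
// pX_NTQB = pX_ACT * sigmoid(qX_frac) (ordering ACT >= NTQB by
// construction); likewise for pC.
//' @noRd
// [[Rcpp::export]]
double cpp_ms_loglik(NumericVector par, List data) {
    IntegerMatrix codes = data["codes"];
    IntegerVector species = data["species"]; // 0-based
    IntegerVector tag = data["tag"];         // 0 = ACT, 1 = NTQB
    NumericMatrix ul = data["ul"], uq = data["uq"], vl = data["vl"],
                  vq = data["vq"], dp = data["dp"], h = data["h"],
                  r = data["r"];
    int S = as<int>(data["nSpecies"]);
    int n = codes.nrow(), T = codes.ncol();

    const double* p = par.begin();
    double brain = p[7 * S];
    const double* b0c = p + 7 * S + 1;
    double bulc = p[8 * S + 1], buqc = p[8 * S + 2];
    double bvlc = p[8 * S + 3], bvqc = p[8 * S + 4];
    double pXa = 1.0 / (1.0 + std::exp(-p[8 * S + 5]));
    double pXn = pXa / (1.0 + std::exp(-p[8 * S + 6]));
    double pCa = 1.0 / (1.0 + std::exp(-p[8 * S + 7]));
    double pCn = pCa / (1.0 + std::exp(-p[8 * S + 8]));
    double lpX[2] = { std::log(pXa), std::log(pXn) };
    double l1pX[2] = { std::log1p(-pXa), std::log1p(-pXn) };
    double lpC[2] = { std::log(pCa), std::log(pCn) };
    double l1pC[2] = { std::log1p(-pCa), std::log1p(-pCn) };

    double total = 0.0;
    for (int i = 0; i < n; ++i) {
        int s = species[i], tg = tag[i];
        double b0 = p[s], bul = p[S + s], buq = p[2 * S + s],
               bvl = p[3 * S + s], bvq = p[4 * S + s],
               bdp = p[5 * S + s], bh = p[6 * S + s];
        double la1 = 0.0, la2 = R_NegInf, la3 = R_NegInf, la4 = R_NegInf;
        for (int t = 0; t < T - 1; ++t) {
            double ep = b0 + bul * ul(i, t) + buq * uq(i, t) +
                        bvl * vl(i, t) + bvq * vq(i, t) +
                        bdp * dp(i, t) + bh * h(i, t) + brain * r(i, t);
            double ec = b0c[s] + bulc * ul(i, t) + buqc * uq(i, t) +
                        bvlc * vl(i, t) + bvqc * vq(i, t);
            double lpsi = log_sigmoid(ep), lomp = log_sigmoid(-ep);
            double lchi = log_sigmoid(ec), lomc = log_sigmoid(-ec);
            double n1 = la1 + lomp;
            double n2 = la1 + lpsi + lchi;
            double n3 = la1 + lpsi + lomc;
            double n4 = lse3(la2, la3, la4);
            int y = codes(i, t + 1);
            switch (y) {
            case 1:
                la1 = n1; la2 = la3 = la4 = R_NegInf;
                break;
            case 2:
                la2 = n2 + lpX[tg]; la1 = la3 = la4 = R_NegInf;
                break;
            case 3:
                la3 = n3 + lpC[tg]; la1 = la2 = la4 = R_NegInf;
                break;
            default:
                la2 = n2 + l1pX[tg]; la3 = n3 + l1pC[tg]; la4 = n4;
                la1 = R_NegInf;
                break;
            }
            if (y != 1) break;
        }
        total += lse4(la1, la2, la3, la4);
    }
    return total;
}
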