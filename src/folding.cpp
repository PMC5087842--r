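#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Simplified stacking-only nearest-neighbor energy model shared by the
// hairpin folding DP and the intermolecular duplex DP.  Pair energies
// (kcal/mol, per stacked adjacency): GC/CG -3.0, AU/UA -2.0, GU/UG -1.0.
// A stacked adjacency contributes the mean of its two pair energies, so a
// uniform stem of k+1 pairs contributes k times the pair energy.  Loops are
// charged flat closure penalties (hairpin / interior-bulge / multiloop).

static const double INF = 1e9;
static const double EPS = 1e-7;

static inline char norm_base(char c) {
    if (c == 'u') c = 'U';
    if (c == 'U') return 'T';
    if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
    return c;
}

static inline double pair_energy(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
    return INF; // not pairable
}

static inline bool can_pair(char a, char b) {
    return pair_energy(a, b) < INF / 2;
}

struct FoldDP {
    int n;
    std::string s;
    double hairpinP, loopP, multiP;
    int maxLoop, minHairpin;
    std::vector<double> C, M1, M2;
    std::vector<int> partner;

    double &c(int i, int j) { return C[i * n + j]; }
    double &m1(int i, int j) { return M1[i * n + j]; }
    double &m2(int i, int j) { return M2[i * n + j]; }

    double stackE(int i, int j) {
        return 0.5 * (pair_energy(s[i], s[j]) + pair_energy(s[i + 1], s[j - 1]));
    }

    void fill() {
        C.assign((size_t)n * n, INF);
        M1.assign((size_t)n * n, INF);
        M2.assign((size_t)n * n, INF);
        for (int span = minHairpin + 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                // C(i,j): minimum energy with (i,j) paired
                if (can_pair(s[i], s[j]) && j - i - 1 >= minHairpin) {
                    double best = hairpinP;
                    if (j - i - 1 > minHairpin && can_pair(s[i + 1], s[j - 1]) &&
                        c(i + 1, j - 1) < INF / 2) {
                        double v = c(i + 1, j - 1) + stackE(i, j);
                        if (v < best) best = v;
                    }
                    // interior loops / bulges (>=1 unpaired, <= maxLoop total)
                    for (int p = i + 1; p <= j - 1 && p - i - 1 <= maxLoop; ++p) {
                        for (int q = j - 1; q > p; --q) {
                            int u = (p - i - 1) + (j - q - 1);
                            if (u < 1) continue;
                            if (u > maxLoop) break;
                            if (c(p, q) < INF / 2) {
                                double v = c(p, q) + loopP;
                                if (v < best) best = v;
                            }
                        }
                    }
                    // multiloop (>= 2 branches inside)
                    if (m2(i + 1, j - 1) < INF / 2) {
                        double v = m2(i + 1, j - 1) + multiP;
                        if (v < best) best = v;
                    }
                    c(i, j) = best;
                }
                // M1(i,j): exactly one branch, flanking unpaired free
                double b1 = (j > i) ? m1(i, j - 1) : INF;
                for (int p = i; p <= j - minHairpin - 1; ++p)
                    if (c(p, j) < b1) b1 = c(p, j);
                m1(i, j) = b1;
                // M2(i,j): two or more branches
                double b2 = INF;
                for (int k = i; k < j; ++k) {
                    if (m1(i, k) >= INF / 2) continue;
                    double rhs = std::min(m1(k + 1, j), m2(k + 1, j));
                    if (rhs >= INF / 2) continue;
                    double v = m1(i, k) + rhs;
                    if (v < b2) b2 = v;
                }
                m2(i, j) = b2;
            }
        }
    }

    void traceM1(int a, int b);
    void traceM2(int a, int b);

    void traceC(int i, int j) {
        partner[i] = j;
        partner[j] = i;
        double e = c(i, j);
        if (std::fabs(e - hairpinP) < EPS) return;
        if (j - i - 1 > minHairpin && can_pair(s[i + 1], s[j - 1]) &&
            c(i + 1, j - 1) < INF / 2 &&
            std::fabs(e - (c(i + 1, j - 1) + stackE(i, j))) < EPS) {
            traceC(i + 1, j - 1);
            return;
        }
        for (int p = i + 1; p <= j - 1 && p - i - 1 <= maxLoop; ++p) {
            for (int q = j - 1; q > p; --q) {
                int u = (p - i - 1) + (j - q - 1);
                if (u < 1) continue;
                if (u > maxLoop) break;
                if (c(p, q) < INF / 2 && std::fabs(e - (c(p, q) + loopP)) < EPS) {
                    traceC(p, q);
                    return;
                }
            }
        }
        if (m2(i + 1, j - 1) < INF / 2 &&
            std::fabs(e - (m2(i + 1, j - 1) + multiP)) < EPS) {
            traceM2(i + 1, j - 1);
            return;
        }
        Rcpp::stop("fold traceback failed (C)");
    }

    double mfe() {
        std::vector<double> W(n, 0.0);
        for (int j = 0; j < n; ++j) {
            double best = (j > 0) ? W[j - 1] : 0.0;
            for (int i = 0; i <= j - minHairpin - 1; ++i) {
                if (c(i, j) < INF / 2) {
                    double v = c(i, j) + (i > 0 ? W[i - 1] : 0.0);
                    if (v < best) best = v;
                }
            }
            W[j] = best;
        }
        // traceback over prefix decomposition
        partner.assign(n, -1);
        int j = n - 1;
        while (j >= 0) {
            if (j > 0 && std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
            bool found = false;
            for (int i = 0; i <= j - minHairpin - 1 && !found; ++i) {
                if (c(i, j) < INF / 2 &&
                    std::fabs(W[j] - (c(i, j) + (i > 0 ? W[i - 1] : 0.0))) < EPS) {
                    traceC(i, j);
                    j = i - 1;
                    found = true;
                }
            }
            if (!found) --j;
        }
        return W[n - 1];
    }
};

void FoldDP::traceM1(int a, int b) {
    while (b > a && std::fabs(m1(a, b) - m1(a, b - 1)) < EPS) --b;
    for (int p = a; p <= b - minHairpin - 1; ++p) {
        if (c(p, b) < INF / 2 && std::fabs(m1(a, b) - c(p, b)) < EPS) {
            traceC(p, b);
            return;
        }
    }
    Rcpp::stop("fold traceback failed (M1)");
}

void FoldDP::traceM2(int a, int b) {
    for (int k = a; k < b; ++k) {
        if (m1(a, k) >= INF / 2) continue;
        if (m1(k + 1, b) < INF / 2 &&
            std::fabs(m2(a, b) - (m1(a, k) + m1(k + 1, b))) < EPS) {
            traceM1(a, k);
            traceM1(k + 1, b);
            return;
        }
        if (m2(k + 1, b) < INF / 2 &&
            std::fabs(m2(a, b) - (m1(a, k) + m2(k + 1, b))) < EPS) {
            traceM1(a, k);
            traceM2(k + 1, b);
            return;
        }
    }
    Rcpp::stop("fold traceback failed (M2)");
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, double hairpinPenalty = 3.0,
                      double loopPenalty = 2.0, double multiPenalty = 3.0,
                      int maxLoop = 30, int minHairpin = 3) {
    FoldDP dp;
    dp.n = (int)seq.size();
    dp.s.resize(dp.n);
    for (int i = 0; i < dp.n; ++i) {
        char c = norm_base(seq[i]);
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
            Rcpp::stop("fold_hairpin: non-ACGU symbol at position %d", i + 1);
        dp.s[i] = c;
    }
    dp.hairpinP = hairpinPenalty;
    dp.loopP = loopPenalty;
    dp.multiP = multiPenalty;
    dp.maxLoop = maxLoop;
    dp.minHairpin = minHairpin;
    if (dp.n < minHairpin + 2) {
        return List::create(_["structure"] = std::string(dp.n, '.'),
                            _["mfe"] = 0.0,
                            _["partner"] = IntegerVector(dp.n, 0));
    }
    dp.fill();
    double e = dp.mfe();
    std::string db(dp.n, '.');
    IntegerVector part(dp.n, 0);
    for (int i = 0; i < dp.n; ++i) {
        if (dp.partner[i] >= 0) {
            part[i] = dp.partner[i] + 1;
            db[i] = (dp.partner[i] > i) ? '(' : ')';
        }
    }
    return List::create(_["structure"] = db, _["mfe"] = e, _["partner"] = part);
}

// Minimum-energy intermolecular duplex between a miRNA (5'->3') and a target
// window (5'->3'), antiparallel pairing, no intramolecular pairs.  The first
// pair is free; stacked adjacencies use the mean pair energy; asymmetric
// loops/bulges up to maxLoop unpaired bases cost loopPenalty each.
// [[Rcpp::export]]
double duplex_energy_cpp(std::string mirna, std::string window,
                         double loopPenalty = 2.0, int maxLoop = 8) {
    int m = (int)mirna.size(), w = (int)window.size();
    if (m == 0 || w == 0) return 0.0;
    std::string x(m, 'N'), z(w, 'N');
    for (int i = 0; i < m; ++i) x[i] = norm_base(mirna[i]);
    for (int j = 0; j < w; ++j) z[j] = norm_base(window[w - 1 - j]); // reversed
    std::vector<double> D((size_t)m * w, INF);
    double best = 0.0;
    for (int i = 0; i < m; ++i) {
        for (int k = 0; k < w; ++k) {
            if (!can_pair(x[i], z[k])) continue;
            double v = 0.0; // open a new duplex with this pair
            if (i > 0 && k > 0 && can_pair(x[i - 1], z[k - 1]) &&
                D[(size_t)(i - 1) * w + (k - 1)] < INF / 2) {
                double st = D[(size_t)(i - 1) * w + (k - 1)] +
                            0.5 * (pair_energy(x[i], z[k]) +
                                   pair_energy(x[i - 1], z[k - 1]));
                if (st < v) v = st;
            }
            for (int p = i - 1; p >= 0 && (i - 1 - p) <= maxLoop; --p) {
                for (int q = k - 1; q >= 0; --q) {
                    int u = (i - 1 - p) + (k - 1 - q);
                    if (u < 1) continue;
                    if (u > maxLoop) break;
                    double d = D[(size_t)p * w + q];
                    if (d < INF / 2 && d + loopPenalty < v) v = d + loopPenalty;
                }
            }
            D[(size_t)i * w + k] = v;
            if (v < best) best = v;
        }
    }
    return best;
}

// Local (Smith-Waterman) alignment of a miRNA against a UTR window scored by
// complementarity: +5 Watson-Crick, +1 G:U wobble, -3 mismatch, gap open -8,
// gap extend -2; positions 2-8 of the miRNA (the seed) are weighted x2.
// The miRNA is reversed internally so both strings run 5'->3'.
// [[Rcpp::export]]
double align_complement_cpp(std::string mirna, std::string window,
                            double matchScore = 5.0, double wobbleScore = 1.0,
                            double mismatchScore = -3.0, double gapOpen = -8.0,
                            double gapExtend = -2.0, int seedStart = 2,
                            int seedEnd = 8, double seedWeight = 2.0) {
    int m = (int)mirna.size(), w = (int)window.size();
    if (m == 0 || w == 0) return 0.0;
    std::string x(m, 'N'), y(w, 'N');
    for (int i = 0; i < m; ++i) x[i] = norm_base(mirna[m - 1 - i]); // 3'->5'
    for (int j = 0; j < w; ++j) y[j] = norm_base(window[j]);
    std::vector<double> H((size_t)(m + 1) * (w + 1), 0.0);
    std::vector<double> E((size_t)(m + 1) * (w + 1), -INF);
    std::vector<double> F((size_t)(m + 1) * (w + 1), -INF);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
        int mirPos = m - (i - 1); // 1-based position from miRNA 5' end
        double wgt = (mirPos >= seedStart && mirPos <= seedEnd) ? seedWeight : 1.0;
        for (int j = 1; j <= w; ++j) {
            char a = x[i - 1], b = y[j - 1];
            double sc;
            if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
                (a == 'G' && b == 'C') || (a == 'C' && b == 'G'))
                sc = matchScore;
            else if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))
                sc = wobbleScore;
            else
                sc = mismatchScore;
            sc *= wgt;
            size_t ij = (size_t)i * (w + 1) + j;
            size_t up = (size_t)(i - 1) * (w + 1) + j;
            size_t lf = (size_t)i * (w + 1) + (j - 1);
            size_t di = (size_t)(i - 1) * (w + 1) + (j - 1);
            E[ij] = std::max(H[lf] + gapOpen, E[lf] + gapExtend);
            F[ij] = std::max(H[up] + gapOpen, F[up] + gapExtend);
            double h = std::max(0.0, H[di] + sc);
            h = std::max(h, E[ij]);
            h = std::max(h, F[ij]);
            H[ij] = h;
            if (h > best) best = h;
        }
    }
    return best;
}
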