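#include <Rcpp.h>
using namespace Rcpp;

// Base codes: 0=A, 1=C, 2=G, 3=U. Watson-Crick plus G.U wobble.
static inline bool can_pair(int a, int b) {
    if (a > b) std::swap(a, b);
    return (a == 0 && b == 3) ||  // A-U
           (a == 1 && b == 2) ||  // C-G
           (a == 2 && b == 3);    // G-U
}

//' Maximum base-pairing partner vector (Nussinov dynamic program)
//'
//' @param codes integer vector, 0=A 1=C 2=G 3=U
//' @param min_loop minimum number of unpaired bases enclosed by a pair
//' @return integer vector of 1-based partner indices (0 = unpaired)
//' @keywords internal
// [[Rcpp::export]]
IntegerVector nussinov_pairs(IntegerVector codes, int min_loop) {
    const int n = codes.size();
    IntegerVector partner(n, 0);
    if (n < min_loop + 2) return partner;

    // E[i][j] = max pairs on subsequence i..j (0-based, j > i)
    std::vector<std::vector<int> > E(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = E[i][j - 1];  // j unpaired
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!can_pair(codes[k], codes[j])) continue;
                int v = 1 + (k > i ? E[i][k - 1] : 0)
                          + (j - k > 1 ? E[k + 1][j - 1] : 0);
                if (v > best) best = v;
            }
            E[i][j] = best;
        }
    }

    // Traceback; when pairing j is optimal, take the outermost partner so
    // complementary runs come out as stacked helices.
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        int target = E[i][j];
        if (target == 0) continue;
        bool paired = false;
        for (int k = i; k <= j - min_loop - 1; ++k) {
            if (!can_pair(codes[k], codes[j])) continue;
            int v = 1 + (k > i ? E[i][k - 1] : 0)
                      + (j - k > 1 ? E[k + 1][j - 1] : 0);
            if (v == target) {
                partner[k] = j + 1;
                partner[j] = k + 1;
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                if (j - k > 1) stack.push_back(std::make_pair(k + 1, j - 1));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i, j - 1));
    }
    return partner;
}

//' Maximum number of base pairs (no traceback)
//' @keywords internal
// [[Rcpp::export]]
int nussinov_max_pairs(IntegerVector codes, int min_loop) {
    const int n = codes.size();
    if (n < min_loop + 2) return 0;
    std::vector<std::vector<int> > E(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = E[i][j - 1];
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!can_pair(codes[k], codes[j])) continue;
                int v = 1 + (k > i ? E[i][k - 1] : 0)
                          + (j - k > 1 ? E[k + 1][j - 1] : 0);
                if (v > best) best = v;
            }
            E[i][j] = best;
        }
    }
    return E[0][n - 1];
}
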