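#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// n * log2(n) lookup for counts 0..w; exact doubles so the incremental
// accumulator adds/subtracts identical values on the way in and out.
static std::vector<double> nlog2n_table(int w) {
    std::vector<double> tab(w + 1, 0.0);
    for (int n = 2; n <= w; ++n) tab[n] = n * std::log2((double) n);
    return tab;
}

static double entropy_from_counts(const int *cnt, int w) {
    double H = 0.0;
    const double lw = std::log2((double) w);
    for (int a = 0; a < 256; ++a) {
        if (cnt[a] > 0) {
            double f = (double) cnt[a] / w;
            H -= f * (std::log2((double) cnt[a]) - lw);
        }
    }
    return H;
}

// [[Rcpp::export]]
double cpp_window_entropy(std::string window) {
    int w = (int) window.size();
    if (w < 1) stop("empty window");
    int cnt[256] = {0};
    for (int i = 0; i < w; ++i) cnt[(unsigned char) window[i]]++;
    return entropy_from_counts(cnt, w);
}

// Sliding-window Shannon entropy (bits) at stride 1: maintains residue counts
// and S = sum_a c_a log2 c_a incrementally, so each slide is O(1) and a whole
// protein costs O(L) per window length. H = log2(w) - S/w.
// Windows containing characters outside `alphabet` are returned as NA when
// alphabet is non-empty.
// [[Rcpp::export]]
NumericVector cpp_sliding_entropy(std::string seq, int w, std::string alphabet = "") {
    int L = (int) seq.size();
    if (w < 1) stop("window length must be >= 1");
    if (L < w) return NumericVector(0);
    int nwin = L - w + 1;
    NumericVector H(nwin);
    std::vector<double> tab = nlog2n_table(w);
    const double lw = std::log2((double) w);

    bool ok[256];
    bool restrict_alpha = !alphabet.empty();
    if (restrict_alpha) {
        for (int a = 0; a < 256; ++a) ok[a] = false;
        for (size_t i = 0; i < alphabet.size(); ++i) ok[(unsigned char) alphabet[i]] = true;
    }

    int cnt[256] = {0};
    double S = 0.0;
    int n_bad = 0;
    for (int i = 0; i < w; ++i) {
        unsigned char c = (unsigned char) seq[i];
        S -= tab[cnt[c]];
        cnt[c]++;
        S += tab[cnt[c]];
        if (restrict_alpha && !ok[c]) n_bad++;
    }
    H[0] = (restrict_alpha && n_bad > 0) ? NA_REAL : (lw - S / w);
    for (int s = 1; s < nwin; ++s) {
        unsigned char out = (unsigned char) seq[s - 1];
        unsigned char in = (unsigned char) seq[s + w - 1];
        S -= tab[cnt[out]]; cnt[out]--; S += tab[cnt[out]];
        S -= tab[cnt[in]];  cnt[in]++;  S += tab[cnt[in]];
        if (restrict_alpha) {
            if (!ok[out]) n_bad--;
            if (!ok[in]) n_bad++;
        }
        H[s] = (restrict_alpha && n_bad > 0) ? NA_REAL : (lw - S / w);
    }
    return H;
}

// All window entropies of one length across a set of sequences, concatenated
// (sequences shorter than w contribute nothing). Used by the calibration
// builder, which only needs the pooled per-w distribution.
// [[Rcpp::export]]
NumericVector cpp_entropies_for_w(CharacterVector seqs, int w, std::string alphabet = "") {
    R_xlen_t total = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        int L = LENGTH(STRING_ELT(seqs, i));
        if (L >= w) total += L - w + 1;
    }
    NumericVector out(total);
    R_xlen_t k = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        if ((int) s.size() < w) continue;
        NumericVector h = cpp_sliding_entropy(s, w, alphabet);
        for (R_xlen_t j = 0; j < h.size(); ++j) out[k++] = h[j];
    }
    return out;
}

// Flag every window of every length ws[i] whose entropy falls strictly below
// the matching threshold ts[i]. Returns parallel vectors (start 1-based, w, H).
// [[Rcpp::export]]
List cpp_detect_windows(std::string seq, IntegerVector ws, NumericVector ts,
                        std::string alphabet = "") {
    std::vector<int> start, wlen;
    std::vector<double> ent;
    int L = (int) seq.size();
    for (R_xlen_t i = 0; i < ws.size(); ++i) {
        int w = ws[i];
        double t = ts[i];
        if (ISNA(t) || L < w) continue;
        NumericVector h = cpp_sliding_entropy(seq, w, alphabet);
        for (int s = 0; s < (int) h.size(); ++s) {
            if (!ISNA(h[s]) && h[s] < t) {
                start.push_back(s + 1);
                wlen.push_back(w);
                ent.push_back(h[s]);
            }
        }
    }
    return List::create(_["start"] = wrap(start), _["w"] = wrap(wlen),
                        _["H"] = wrap(ent));
}
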