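#include <Rcpp.h>
using namespace Rcpp;

// Ungapped PSSM scan: score of the L-column matrix at every valid start
// of an integer-encoded amino-acid sequence. Encoding: 1..20 = column
// index, 0 = neutral residue (scores 0), -1 = stop codon (scores -100,
// vetoing the window). Summation order matches the naive per-letter R
// loop so results are bit-identical.
// [[Rcpp::export(name = ".pssmScanC")]]
NumericVector pssmScanC(NumericMatrix scores, IntegerVector idx) {
    const int L = scores.nrow();
    const int n = idx.size();
    const int m = n - L + 1;
    if (m < 1) return NumericVector(0);
    NumericVector out(m);
    for (int s = 0; s < m; ++s) {
        double tot = 0.0;
        for (int i = 0; i < L; ++i) {
            const int a = idx[s + i];
            if (a > 0) tot += scores(i, a - 1);
            else if (a < 0) tot += -100.0;
        }
        out[s] = tot;
    }
    return out;
}
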