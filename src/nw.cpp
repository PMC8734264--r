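#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Global alignment under a position-specific score matrix with affine gaps
// (Gotoh). A gap run of length d costs open + (d-1)*extend, so passing
// extend == open realises the linear model. Traceback preference when scores
// tie is fixed: diagonal > vertical (consume seq1) > horizontal (consume
// seq2), which makes results deterministic across platforms and batch
// layouts.
//
// States: 0 = M (last column is a line i~j), 1 = X (gap in seq2, consumed
// seq1 char), 2 = Y (gap in seq1, consumed seq2 char).

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(NumericMatrix S, double gapOpen, double gapExtend) {
    const int n1 = S.nrow(), n2 = S.ncol();
    const double NEG = -std::numeric_limits<double>::infinity();
    const int W = n2 + 1;

    std::vector<double> M((n1 + 1) * W, NEG), X((n1 + 1) * W, NEG),
        Y((n1 + 1) * W, NEG);
    // traceback: which predecessor state fed each cell's state
    std::vector<signed char> tbM((n1 + 1) * W, -1), tbX((n1 + 1) * W, -1),
        tbY((n1 + 1) * W, -1);

    M[0] = 0.0;
    for (int i = 1; i <= n1; ++i) {
        X[i * W] = gapOpen + (i - 1) * gapExtend;
        tbX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n2; ++j) {
        Y[j] = gapOpen + (j - 1) * gapExtend;
        tbY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n1; ++i) {
        for (int j = 1; j <= n2; ++j) {
            const int c = i * W + j, d = (i - 1) * W + (j - 1),
                      u = (i - 1) * W + j, l = i * W + (j - 1);
            // M: diagonal move, predecessor preference M > X > Y
            double best = M[d];
            signed char arg = 0;
            if (X[d] > best) { best = X[d]; arg = 1; }
            if (Y[d] > best) { best = Y[d]; arg = 2; }
            if (best > NEG) {
                M[c] = best + S(i - 1, j - 1);
                tbM[c] = arg;
            }
            // X: consume seq1 char against a gap
            best = (M[u] > NEG) ? M[u] + gapOpen : NEG;
            arg = 0;
            if (X[u] + gapExtend > best) { best = X[u] + gapExtend; arg = 1; }
            if (Y[u] + gapOpen > best) { best = Y[u] + gapOpen; arg = 2; }
            if (best > NEG) { X[c] = best; tbX[c] = arg; }
            // Y: consume seq2 char against a gap
            best = (M[l] > NEG) ? M[l] + gapOpen : NEG;
            arg = 0;
            if (X[l] + gapOpen > best) { best = X[l] + gapOpen; arg = 1; }
            if (Y[l] + gapExtend > best) { best = Y[l] + gapExtend; arg = 2; }
            if (best > NEG) { Y[c] = best; tbY[c] = arg; }
        }
    }

    const int end = n1 * W + n2;
    double score = M[end];
    int state = 0;
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }
    if (n1 == 0 && n2 == 0) { score = 0.0; state = 0; }

    // traceback
    std::vector<int> li, lj;           // active lines, 0-based
    std::vector<signed char> ops;      // 0 diag, 1 up, 2 left (reversed)
    int i = n1, j = n2;
    while (i > 0 || j > 0) {
        const int c = i * W + j;
        signed char prev;
        if (state == 0) {
            prev = tbM[c];
            li.push_back(i - 1);
            lj.push_back(j - 1);
            ops.push_back(0);
            --i; --j;
        } else if (state == 1) {
            prev = tbX[c];
            ops.push_back(1);
            --i;
        } else {
            prev = tbY[c];
            ops.push_back(2);
            --j;
        }
        state = prev;
    }

    const int k = (int)li.size();
    IntegerMatrix lines(k, 2);
    for (int r = 0; r < k; ++r) {  // reverse into ascending order
        lines(r, 0) = li[k - 1 - r];
        lines(r, 1) = lj[k - 1 - r];
    }
    const int no = (int)ops.size();
    IntegerVector opcodes(no);
    for (int r = 0; r < no; ++r) opcodes[r] = ops[no - 1 - r];

    return List::create(_["score"] = score, _["lines"] = lines,
                        _["ops"] = opcodes);
}
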