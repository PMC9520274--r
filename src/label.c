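#include <R.h>
#include <Rinternals.h>

/* Connected-component labeling of a binary mask (column-major integer
 * matrix) under 4- or 8-connectivity, by breadth-first flood fill.
 * Returns an integer matrix of labels (0 = background, 1..n components).
 */
SEXP cc_label(SEXP mask, SEXP sconn)
{
    SEXP dim = getAttrib(mask, R_DimSymbol);
    int nr = INTEGER(dim)[0], nc = INTEGER(dim)[1];
    int conn = asInteger(sconn);
    const int *m = INTEGER(mask);
    SEXP ans = PROTECT(allocMatrix(INTSXP, nr, nc));
    int *lab = INTEGER(ans);
    R_xlen_t n = (R_xlen_t) nr * nc;
    int *queue = (int *) R_alloc(n, sizeof(int));
    int next_label = 0;

    /* neighbour offsets as (dr, dc) pairs; first 4 are edge neighbours */
    static const int dr[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
    static const int dc[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
    int nnb = (conn == 8) ? 8 : 4;

    for (R_xlen_t i = 0; i < n; i++)
        lab[i] = 0;

    for (R_xlen_t s = 0; s < n; s++) {
        if (!m[s] || lab[s])
            continue;
        next_label++;
        lab[s] = next_label;
        int head = 0, tail = 0;
        queue[tail++] = (int) s;
        while (head < tail) {
            int cur = queue[head++];
            int r = cur % nr, c = cur / nr;
            for (int k = 0; k < nnb; k++) {
                int rr = r + dr[k], cc = c + dc[k];
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc)
                    continue;
                int idx = rr + cc * nr;
                if (m[idx] && !lab[idx]) {
                    lab[idx] = next_label;
                    queue[tail++] = idx;
                }
            }
        }
    }
    UNPROTECT(1);
    return ans;
}
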