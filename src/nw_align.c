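#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <string.h>

/* Semi-global Needleman-Wunsch alignment of seq against ref (end gaps in
 * ref are free: the fragment floats inside the reference), returning for
 * every position of seq the 1-based position of ref it aligns to, or
 * NA where seq carries an insertion relative to ref.  Linear gap cost;
 * 'N' scores neutrally (missing data must not attract gaps). */
SEXP C_nw_map(SEXP seq_, SEXP ref_, SEXP scores_)
{
    const char *seq = CHAR(STRING_ELT(seq_, 0));
    const char *ref = CHAR(STRING_ELT(ref_, 0));
    const int *sc = INTEGER(scores_); /* match, mismatch, gap */
    const int match = sc[0], mismatch = sc[1], gap = sc[2];
    const R_xlen_t n = (R_xlen_t) strlen(seq), m = (R_xlen_t) strlen(ref);

    if (n == 0 || m == 0) error("empty sequence in alignment");
    if ((double) n * (double) m > 2.5e7)
        error("sequences too long for exact anchoring; supply pre-aligned input");

    const R_xlen_t W = m + 1;
    int *S = (int *) R_alloc((size_t) (n + 1) * W, sizeof(int));
    unsigned char *T = (unsigned char *) R_alloc((size_t) (n + 1) * W, 1);

    for (R_xlen_t j = 0; j <= m; j++) { S[j] = 0; T[j] = 2; } /* free lead */
    for (R_xlen_t i = 1; i <= n; i++) { S[i * W] = (int) i * gap; T[i * W] = 1; }
    T[0] = 0;

    for (R_xlen_t i = 1; i <= n; i++) {
        const char a = seq[i - 1];
        int *row = S + i * W, *prev = S + (i - 1) * W;
        unsigned char *trow = T + i * W;
        for (R_xlen_t j = 1; j <= m; j++) {
            const char b = ref[j - 1];
            int sub = (a == 'N' || b == 'N') ? 0 : (a == b ? match : mismatch);
            int d = prev[j - 1] + sub;
            int u = prev[j] + gap;
            int l = row[j - 1] + gap;
            int best = d; unsigned char tb = 0;
            if (u > best) { best = u; tb = 1; }
            if (l > best) { best = l; tb = 2; }
            row[j] = best; trow[j] = tb;
        }
    }

    SEXP out = PROTECT(allocVector(INTSXP, n));
    int *o = INTEGER(out);
    for (R_xlen_t i = 0; i < n; i++) o[i] = NA_INTEGER;
    /* free trailing ref gaps: start traceback at the best column of the
     * last row (leftmost on ties) */
    R_xlen_t jbest = 0;
    for (R_xlen_t j = 1; j <= m; j++)
        if (S[n * W + j] > S[n * W + jbest]) jbest = j;
    R_xlen_t i = n, j = jbest;
    while (i > 0) {
        unsigned char tb = T[i * W + j];
        if (i > 0 && j > 0 && tb == 0) { o[i - 1] = (int) j; --i; --j; }
        else if (i > 0 && (j == 0 || tb == 1)) { --i; } /* insertion in seq */
        else { --j; }                                   /* deletion in seq */
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_nw_map", (DL_FUNC) &C_nw_map, 3},
    {NULL, NULL, 0}
};

void R_init_ovismthap(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
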