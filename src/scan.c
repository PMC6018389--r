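/* JSON-aware boundary scanner for BON streams.
 *
 * Processes one chunk of bytes while carrying scanner state across chunk
 * edges, so block boundaries ("}[", "]{") are found by brace-depth and
 * string-state tracking rather than substring search: the signal bytes
 * inside a JSON string value can never cause a mis-split.
 *
 * State vector (integer, length 6):
 *   [0] phase: 0 = expecting '{' of a header, 1 = inside header,
 *       2 = expecting '[' of a payload, 3 = inside payload
 *   [1] depth (brace/bracket nesting within the current phase)
 *   [2] in_string, [3] escape
 *   [4] unit_start: stream offset of the open header/object, -1 if none
 *   [5] pos: stream offset of the first byte of this chunk
 *
 * Events (integer triples): type, start, end (0-based, half-open,
 * stream offsets). type 1 = header span, 2 = payload object span,
 * 3 = payload closed (end of a block; start == end == offset past ']').
 *
 * Error codes: 1 = unexpected byte where a header '{' was required,
 * 2 = header not immediately followed by '[', 3 = payload element that
 * is not a JSON object.
 */

#include <R.h>
#include <Rinternals.h>
#include <string.h>

SEXP C_bon_scan_chunk(SEXP chunk, SEXP state)
{
    if (TYPEOF(chunk) != RAWSXP) error("chunk must be raw");
    if (TYPEOF(state) != INTSXP || XLENGTH(state) != 6)
        error("state must be integer(6)");

    const unsigned char *s = RAW(chunk);
    R_xlen_t n = XLENGTH(chunk);

    int phase = INTEGER(state)[0];
    int depth = INTEGER(state)[1];
    int in_string = INTEGER(state)[2];
    int escape = INTEGER(state)[3];
    int unit_start = INTEGER(state)[4];
    int base = INTEGER(state)[5];

    int *ev = (int *) R_alloc((size_t) (3 * (n + 1)), sizeof(int));
    int nev = 0;
    int err = 0, err_pos = -1, err_char = -1;

    for (R_xlen_t i = 0; i < n; i++) {
        unsigned char c = s[i];
        int pos = base + (int) i;

        if (in_string) {
            if (escape)          escape = 0;
            else if (c == '\\')  escape = 1;
            else if (c == '"')   in_string = 0;
            continue;
        }

        switch (phase) {
        case 0:                          /* between blocks */
            if (c == '{') {
                phase = 1; depth = 1; unit_start = pos;
            } else {
                err = 1; err_pos = pos; err_char = c; goto done;
            }
            break;

        case 1:                          /* inside header */
            if (c == '"') in_string = 1;
            else if (c == '{' || c == '[') depth++;
            else if (c == '}' || c == ']') {
                depth--;
                if (depth == 0) {
                    ev[nev++] = 1; ev[nev++] = unit_start; ev[nev++] = pos + 1;
                    unit_start = -1;
                    phase = 2;
                }
            }
            break;

        case 2:                          /* "}[" junction */
            if (c == '[') { phase = 3; depth = 1; }
            else { err = 2; err_pos = pos; err_char = c; goto done; }
            break;

        case 3:                          /* inside payload */
            if (depth == 1) {
                if (c == '{') { depth = 2; unit_start = pos; }
                else if (c == ']') {
                    depth = 0;
                    ev[nev++] = 3; ev[nev++] = pos + 1; ev[nev++] = pos + 1;
                    phase = 0;
                } else if (c != ',' && c != ' ' && c != '\t' &&
                           c != '\n' && c != '\r') {
                    err = 3; err_pos = pos; err_char = c; goto done;
                }
            } else {
                if (c == '"') in_string = 1;
                else if (c == '{' || c == '[') depth++;
                else if (c == '}' || c == ']') {
                    depth--;
                    if (depth == 1) {
                        ev[nev++] = 2; ev[nev++] = unit_start; ev[nev++] = pos + 1;
                        unit_start = -1;
                    }
                }
            }
            break;
        }
    }

done:;
    SEXP events = PROTECT(allocVector(INTSXP, nev));
    if (nev) memcpy(INTEGER(events), ev, nev * sizeof(int));

    SEXP newstate = PROTECT(allocVector(INTSXP, 6));
    INTEGER(newstate)[0] = phase;
    INTEGER(newstate)[1] = depth;
    INTEGER(newstate)[2] = in_string;
    INTEGER(newstate)[3] = escape;
    INTEGER(newstate)[4] = unit_start;
    INTEGER(newstate)[5] = err ? err_pos : base + (int) n;

    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, events);
    SET_VECTOR_ELT(out, 1, newstate);
    SET_VECTOR_ELT(out, 2, ScalarInteger(err));
    SET_VECTOR_ELT(out, 3, ScalarInteger(err_char));
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("events"));
    SET_STRING_ELT(nm, 1, mkChar("state"));
    SET_STRING_ELT(nm, 2, mkChar("err"));
    SET_STRING_ELT(nm, 3, mkChar("err_char"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}
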