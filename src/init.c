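#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_zlib_compress(SEXP, SEXP);
extern SEXP C_zlib_decompress(SEXP);
extern SEXP C_crc32(SEXP);
extern SEXP C_bon_scan_chunk(SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_zlib_compress",   (DL_FUNC) &C_zlib_compress,   2},
    {"C_zlib_decompress", (DL_FUNC) &C_zlib_decompress, 1},
    {"C_crc32",           (DL_FUNC) &C_crc32,           1},
    {"C_bon_scan_chunk",  (DL_FUNC) &C_bon_scan_chunk,  2},
    {NULL, NULL, 0}
};

void R_init_bon(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
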