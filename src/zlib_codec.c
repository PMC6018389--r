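/* Thin wrappers over the system zlib: RFC 1950 streams at a chosen
 * compression level, streaming inflate, and crc32 (for the gzip
 * container fallback). */

#include <R.h>
#include <Rinternals.h>
#include <zlib.h>
#include <string.h>

SEXP C_zlib_compress(SEXP from, SEXP level)
{
    if (TYPEOF(from) != RAWSXP) error("input must be a raw vector");
    int lvl = asInteger(level);
    if (lvl < 1 || lvl > 9) error("zlib level must be in 1..9");

    uLong srclen = (uLong) XLENGTH(from);
    uLong bound = compressBound(srclen);
    SEXP out = PROTECT(allocVector(RAWSXP, bound));
    uLongf destlen = bound;
    int ret = compress2(RAW(out), &destlen, RAW(from), srclen, lvl);
    if (ret != Z_OK) {
        UNPROTECT(1);
        error("zlib compression failed (code %d)", ret);
    }
    SEXP trimmed = PROTECT(allocVector(RAWSXP, destlen));
    memcpy(RAW(trimmed), RAW(out), destlen);
    UNPROTECT(2);
    return trimmed;
}

SEXP C_zlib_decompress(SEXP from)
{
    if (TYPEOF(from) != RAWSXP) error("input must be a raw vector");
    uLong srclen = (uLong) XLENGTH(from);

    z_stream strm;
    memset(&strm, 0, sizeof(strm));
    if (inflateInit(&strm) != Z_OK) error("inflateInit failed");

    size_t cap = srclen > 1024 ? srclen * 4 : 4096;
    unsigned char *buf = (unsigned char *) R_alloc(cap, 1);
    size_t used = 0;

    strm.next_in = RAW(from);
    strm.avail_in = srclen;

    int ret = Z_OK;
    while (ret != Z_STREAM_END) {
        if (used == cap) {
            size_t newcap = cap * 2;
            unsigned char *nb = (unsigned char *) R_alloc(newcap, 1);
            memcpy(nb, buf, used);
            buf = nb;
            cap = newcap;
        }
        strm.next_out = buf + used;
        strm.avail_out = cap - used;
        ret = inflate(&strm, Z_NO_FLUSH);
        used = cap - strm.avail_out;
        if (ret == Z_BUF_ERROR && strm.avail_in == 0) {
            inflateEnd(&strm);
            error("truncated zlib stream");
        }
        if (ret != Z_OK && ret != Z_STREAM_END) {
            inflateEnd(&strm);
            error("invalid zlib stream (code %d)", ret);
        }
    }
    inflateEnd(&strm);

    SEXP out = PROTECT(allocVector(RAWSXP, used));
    memcpy(RAW(out), buf, used);
    UNPROTECT(1);
    return out;
}

SEXP C_crc32(SEXP from)
{
    if (TYPEOF(from) != RAWSXP) error("input must be a raw vector");
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, RAW(from), (uInt) XLENGTH(from));
    return ScalarReal((double) crc);
}
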