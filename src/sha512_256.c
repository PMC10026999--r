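/* SHA-512/256 (FIPS 180-4): SHA-512 compression with the 512/256 initial
 * hash values, output truncated to the first 256 bits. Needed because the
 * pseudonymization profile hashes identifiers with this specific variant. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>
#include <string.h>

static const uint64_t K[80] = {
    0x428a2f98d728ae22ULL, 0x7137449123ef65cdULL, 0xb5c0fbcfec4d3b2fULL, 0xe9b5dba58189dbbcULL,
    0x3956c25bf348b538ULL, 0x59f111f1b605d019ULL, 0x923f82a4af194f9bULL, 0xab1c5ed5da6d8118ULL,
    0xd807aa98a3030242ULL, 0x12835b0145706fbeULL, 0x243185be4ee4b28cULL, 0x550c7dc3d5ffb4e2ULL,
    0x72be5d74f27b896fULL, 0x80deb1fe3b1696b1ULL, 0x9bdc06a725c71235ULL, 0xc19bf174cf692694ULL,
    0xe49b69c19ef14ad2ULL, 0xefbe4786384f25e3ULL, 0x0fc19dc68b8cd5b5ULL, 0x240ca1cc77ac9c65ULL,
    0x2de92c6f592b0275ULL, 0x4a7484aa6ea6e483ULL, 0x5cb0a9dcbd41fbd4ULL, 0x76f988da831153b5ULL,
    0x983e5152ee66dfabULL, 0xa831c66d2db43210ULL, 0xb00327c898fb213fULL, 0xbf597fc7beef0ee4ULL,
    0xc6e00bf33da88fc2ULL, 0xd5a79147930aa725ULL, 0x06ca6351e003826fULL, 0x142929670a0e6e70ULL,
    0x27b70a8546d22ffcULL, 0x2e1b21385c26c926ULL, 0x4d2c6dfc5ac42aedULL, 0x53380d139d95b3dfULL,
    0x650a73548baf63deULL, 0x766a0abb3c77b2a8ULL, 0x81c2c92e47edaee6ULL, 0x92722c851482353bULL,
    0xa2bfe8a14cf10364ULL, 0xa81a664bbc423001ULL, 0xc24b8b70d0f89791ULL, 0xc76c51a30654be30ULL,
    0xd192e819d6ef5218ULL, 0xd69906245565a910ULL, 0xf40e35855771202aULL, 0x106aa07032bbd1b8ULL,
    0x19a4c116b8d2d0c8ULL, 0x1e376c085141ab53ULL, 0x2748774cdf8eeb99ULL, 0x34b0bcb5e19b48a8ULL,
    0x391c0cb3c5c95a63ULL, 0x4ed8aa4ae3418acbULL, 0x5b9cca4f7763e373ULL, 0x682e6ff3d6b2b8a3ULL,
    0x748f82ee5defb2fcULL, 0x78a5636f43172f60ULL, 0x84c87814a1f0ab72ULL, 0x8cc702081a6439ecULL,
    0x90befffa23631e28ULL, 0xa4506cebde82bde9ULL, 0xbef9a3f7b2c67915ULL, 0xc67178f2e372532bULL,
    0xca273eceea26619cULL, 0xd186b8c721c0c207ULL, 0xeada7dd6cde0eb1eULL, 0xf57d4f7fee6ed178ULL,
    0x06f067aa72176fbaULL, 0x0a637dc5a2c898a6ULL, 0x113f9804bef90daeULL, 0x1b710b35131c471bULL,
    0x28db77f523047d84ULL, 0x32caab7b40c72493ULL, 0x3c9ebe0a15c9bebcULL, 0x431d67c49c100d4cULL,
    0x4cc5d4becb3e42b6ULL, 0x597f299cfc657e2aULL, 0x5fcb6fab3ad6faecULL, 0x6c44198c4a475817ULL
};

/* Initial hash values specific to SHA-512/256 (FIPS 180-4 sec. 5.3.6.2). */
static const uint64_t H0[8] = {
    0x22312194fc2bf72cULL, 0x9f555fa3c84c64c2ULL, 0x2393b86b6f53b151ULL, 0x963877195940eabdULL,
    0x96283ee2a88effe3ULL, 0xbe5e1e2553863992ULL, 0x2b0199fc2c85b8aaULL, 0x0eb72ddc81c52ca2ULL
};

#define ROTR(x, n) (((x) >> (n)) | ((x) << (64 - (n))))
#define CH(x, y, z) (((x) & (y)) ^ (~(x) & (z)))
#define MAJ(x, y, z) (((x) & (y)) ^ ((x) & (z)) ^ ((y) & (z)))
#define S0(x) (ROTR(x, 28) ^ ROTR(x, 34) ^ ROTR(x, 39))
#define S1(x) (ROTR(x, 14) ^ ROTR(x, 18) ^ ROTR(x, 41))
#define s0(x) (ROTR(x, 1) ^ ROTR(x, 8) ^ ((x) >> 7))
#define s1(x) (ROTR(x, 19) ^ ROTR(x, 61) ^ ((x) >> 6))

static void compress(uint64_t h[8], const unsigned char block[128])
{
    uint64_t w[80], a, b, c, d, e, f, g, hh, t1, t2;
    int t;
    for (t = 0; t < 16; t++) {
        w[t] = ((uint64_t)block[t * 8] << 56) | ((uint64_t)block[t * 8 + 1] << 48) |
               ((uint64_t)block[t * 8 + 2] << 40) | ((uint64_t)block[t * 8 + 3] << 32) |
               ((uint64_t)block[t * 8 + 4] << 24) | ((uint64_t)block[t * 8 + 5] << 16) |
               ((uint64_t)block[t * 8 + 6] << 8) | (uint64_t)block[t * 8 + 7];
    }
    for (t = 16; t < 80; t++)
        w[t] = s1(w[t - 2]) + w[t - 7] + s0(w[t - 15]) + w[t - 16];
    a = h[0]; b = h[1]; c = h[2]; d = h[3];
    e = h[4]; f = h[5]; g = h[6]; hh = h[7];
    for (t = 0; t < 80; t++) {
        t1 = hh + S1(e) + CH(e, f, g) + K[t] + w[t];
        t2 = S0(a) + MAJ(a, b, c);
        hh = g; g = f; f = e; e = d + t1;
        d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
}

static void sha512_256(const unsigned char *msg, size_t len, unsigned char out[32])
{
    uint64_t h[8];
    unsigned char block[128];
    size_t i, rem;
    uint64_t bitlen_lo = (uint64_t)len << 3; /* message sizes here are far below 2^61 bytes */

    memcpy(h, H0, sizeof(h));
    for (i = 0; i + 128 <= len; i += 128)
        compress(h, msg + i);
    rem = len - i;
    memset(block, 0, 128);
    memcpy(block, msg + i, rem);
    block[rem] = 0x80;
    if (rem >= 112) {
        compress(h, block);
        memset(block, 0, 128);
    }
    block[120] = (unsigned char)(bitlen_lo >> 56);
    block[121] = (unsigned char)(bitlen_lo >> 48);
    block[122] = (unsigned char)(bitlen_lo >> 40);
    block[123] = (unsigned char)(bitlen_lo >> 32);
    block[124] = (unsigned char)(bitlen_lo >> 24);
    block[125] = (unsigned char)(bitlen_lo >> 16);
    block[126] = (unsigned char)(bitlen_lo >> 8);
    block[127] = (unsigned char)(bitlen_lo);
    compress(h, block);
    for (i = 0; i < 4; i++) { /* first 256 bits only */
        out[i * 8]     = (unsigned char)(h[i] >> 56);
        out[i * 8 + 1] = (unsigned char)(h[i] >> 48);
        out[i * 8 + 2] = (unsigned char)(h[i] >> 40);
        out[i * 8 + 3] = (unsigned char)(h[i] >> 32);
        out[i * 8 + 4] = (unsigned char)(h[i] >> 24);
        out[i * 8 + 5] = (unsigned char)(h[i] >> 16);
        out[i * 8 + 6] = (unsigned char)(h[i] >> 8);
        out[i * 8 + 7] = (unsigned char)(h[i]);
    }
}

SEXP C_sha512_256(SEXP data)
{
    unsigned char out[32];
    SEXP res;
    if (TYPEOF(data) != RAWSXP)
        error("input must be a raw vector");
    sha512_256(RAW(data), (size_t)XLENGTH(data), out);
    res = PROTECT(allocVector(RAWSXP, 32));
    memcpy(RAW(res), out, 32);
    UNPROTECT(1);
    return res;
}
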