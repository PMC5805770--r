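#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// MSB-first bit streams. All variable-length side streams of the container
// (contig metadata, differential offsets, error records, multiplicities,
// N positions) go through these.

struct BitWriter {
  std::vector<uint8_t> bytes;
  int nbits_in_last; // 0..7, bits used in the byte being filled
  BitWriter() : nbits_in_last(0) {}
  void put_bit(int b) {
    if (nbits_in_last == 0) bytes.push_back(0);
    if (b) bytes.back() |= (uint8_t)(1u << (7 - nbits_in_last));
    nbits_in_last = (nbits_in_last + 1) & 7;
  }
  void put_bits(uint64_t v, int width) { // MSB first
    for (int i = width - 1; i >= 0; --i) put_bit((int)((v >> i) & 1u));
  }
  void put_gamma(uint64_t v) { // v >= 1
    int nb = 0;
    uint64_t t = v;
    while (t > 1) { t >>= 1; ++nb; }
    for (int i = 0; i < nb; ++i) put_bit(0);
    put_bits(v, nb + 1);
  }
  size_t bit_length() const {
    if (bytes.empty()) return 0;
    return (bytes.size() - 1) * 8 + (nbits_in_last == 0 ? 8 : (size_t) nbits_in_last);
  }
};

struct BitReader {
  std::vector<uint8_t> bytes;
  size_t pos; // bit position
  BitReader(const RawVector& r) : bytes(r.begin(), r.end()), pos(0) {}
  int get_bit() {
    if (pos >= bytes.size() * 8) stop("bit stream truncated");
    int b = (bytes[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
  uint64_t get_bits(int width) {
    uint64_t v = 0;
    for (int i = 0; i < width; ++i) v = (v << 1) | (uint64_t) get_bit();
    return v;
  }
  uint64_t get_gamma() {
    int nb = 0;
    while (get_bit() == 0) {
      if (++nb > 62) stop("corrupt gamma code");
    }
    uint64_t v = 1;
    for (int i = 0; i < nb; ++i) v = (v << 1) | (uint64_t) get_bit();
    return v;
  }
};

// ---- canonical Huffman codebook for differential offsets ----------------
// Alphabet {1..L}; weights follow a truncated geometric profile
// P(d) proportional to 0.85^(d-1), so both ends derive the identical
// codebook from L alone and no codebook is transmitted.

struct Codebook {
  std::vector<int> len;       // code length per symbol 1..L (index 0 unused)
  std::vector<uint64_t> code; // canonical code per symbol
};

static void huffman_lengths(int L, std::vector<int>& len) {
  len.assign((size_t) L + 1, 0);
  if (L == 1) { len[1] = 0; return; } // degenerate: nothing to transmit
  // leaves in ascending weight = descending symbol (0.85^(d-1) decreasing in d)
  struct Item { double w; std::vector<int> syms; };
  std::vector<Item> leafq((size_t) L), nodeq;
  for (int d = 0; d < L; ++d) {
    leafq[(size_t) d].w = std::pow(0.85, (double)(L - 1 - d));
    leafq[(size_t) d].syms.assign(1, L - d);
  }
  size_t li = 0, ni = 0;
  // two-queue Huffman; ties prefer the leaf queue (deterministic)
  while ((leafq.size() - li) + (nodeq.size() - ni) > 1) {
    Item a, b;
    for (int pick = 0; pick < 2; ++pick) {
      bool from_leaf;
      if (li >= leafq.size()) from_leaf = false;
      else if (ni >= nodeq.size()) from_leaf = true;
      else from_leaf = leafq[li].w <= nodeq[ni].w;
      Item& dst = pick == 0 ? a : b;
      if (from_leaf) dst = leafq[li++];
      else dst = nodeq[ni++];
    }
    for (size_t t = 0; t < a.syms.size(); ++t) len[(size_t) a.syms[t]]++;
    for (size_t t = 0; t < b.syms.size(); ++t) len[(size_t) b.syms[t]]++;
    Item m;
    m.w = a.w + b.w;
    m.syms.reserve(a.syms.size() + b.syms.size());
    m.syms.insert(m.syms.end(), a.syms.begin(), a.syms.end());
    m.syms.insert(m.syms.end(), b.syms.begin(), b.syms.end());
    nodeq.push_back(m);
  }
}

static void build_codebook(int L, Codebook& cb) {
  huffman_lengths(L, cb.len);
  cb.code.assign((size_t) L + 1, 0);
  if (L == 1) return;
  // canonical assignment: sort symbols by (length, symbol)
  std::vector<int> order((size_t) L);
  for (int d = 1; d <= L; ++d) order[(size_t)(d - 1)] = d;
  std::vector<int>& len = cb.len;
  std::sort(order.begin(), order.end(), [&len](int a, int b) {
    if (len[(size_t) a] != len[(size_t) b]) return len[(size_t) a] < len[(size_t) b];
    return a < b;
  });
  uint64_t code = 0;
  int prev_len = len[(size_t) order[0]];
  for (size_t i = 0; i < order.size(); ++i) {
    int s = order[i];
    code <<= (len[(size_t) s] - prev_len);
    cb.code[(size_t) s] = code;
    prev_len = len[(size_t) s];
    ++code;
  }
}

// [[Rcpp::export(name = ".huff_codebook_cpp")]]
List huff_codebook_cpp(int L) {
  if (L < 1) stop("L must be >= 1");
  Codebook cb;
  build_codebook(L, cb);
  IntegerVector lens(L);
  CharacterVector codes(L);
  for (int d = 1; d <= L; ++d) {
    lens[d - 1] = cb.len[(size_t) d];
    std::string s;
    for (int i = cb.len[(size_t) d] - 1; i >= 0; --i)
      s.push_back(((cb.code[(size_t) d] >> i) & 1u) ? '1' : '0');
    codes[d - 1] = s;
  }
  return List::create(_["symbol"] = seq_len(L), _["length"] = lens, _["code"] = codes);
}

// canonical decoding tables
struct Decoder {
  // per length: first canonical code value and index into sym_by_order
  std::vector<int> lens_present;
  std::vector<uint64_t> first_code;
  std::vector<int> first_index;
  std::vector<int> syms; // symbols in canonical order
  int L;
};

static void build_decoder(int L, Decoder& dec) {
  Codebook cb;
  build_codebook(L, cb);
  dec.L = L;
  if (L == 1) return;
  std::vector<int> order((size_t) L);
  for (int d = 1; d <= L; ++d) order[(size_t)(d - 1)] = d;
  std::vector<int>& len = cb.len;
  std::sort(order.begin(), order.end(), [&len](int a, int b) {
    if (len[(size_t) a] != len[(size_t) b]) return len[(size_t) a] < len[(size_t) b];
    return a < b;
  });
  dec.syms = order;
  int cur_len = -1;
  for (size_t i = 0; i < order.size(); ++i) {
    int l = cb.len[(size_t) order[i]];
    if (l != cur_len) {
      dec.lens_present.push_back(l);
      dec.first_code.push_back(cb.code[(size_t) order[i]]);
      dec.first_index.push_back((int) i);
      cur_len = l;
    }
  }
}

static int decode_symbol(BitReader& br, const Decoder& dec) {
  if (dec.L == 1) return 1;
  uint64_t code = 0;
  int len = 0;
  size_t li = 0;
  while (true) {
    int step = dec.lens_present[li] - len;
    for (int i = 0; i < step; ++i) code = (code << 1) | (uint64_t) br.get_bit();
    len = dec.lens_present[li];
    // number of codes of this length
    size_t next_idx = (li + 1 < dec.first_index.size())
      ? (size_t) dec.first_index[li + 1] : dec.syms.size();
    uint64_t count = (uint64_t)(next_idx - (size_t) dec.first_index[li]);
    if (code >= dec.first_code[li] && code < dec.first_code[li] + count)
      return dec.syms[(size_t) dec.first_index[li] + (size_t)(code - dec.first_code[li])];
    if (++li >= dec.lens_present.size()) stop("corrupt Huffman stream");
  }
}

// ---- R-facing writer/reader handles -------------------------------------

// [[Rcpp::export(name = ".bw_new")]]
SEXP bw_new() {
  XPtr<BitWriter> p(new BitWriter(), true);
  return p;
}

// [[Rcpp::export(name = ".bw_gamma")]]
void bw_gamma(SEXP bw, IntegerVector v) {
  XPtr<BitWriter> p(bw);
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] < 1) stop("gamma codes require values >= 1");
    p->put_gamma((uint64_t) v[i]);
  }
}

// [[Rcpp::export(name = ".bw_fixed")]]
void bw_fixed(SEXP bw, IntegerVector v, int width) {
  XPtr<BitWriter> p(bw);
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] < 0 || (width < 31 && v[i] >= (1 << width)))
      stop("value out of range for fixed-width field");
    p->put_bits((uint64_t) v[i], width);
  }
}

// [[Rcpp::export(name = ".bw_huff")]]
void bw_huff(SEXP bw, IntegerVector v, int L) {
  XPtr<BitWriter> p(bw);
  Codebook cb;
  build_codebook(L, cb);
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] < 1 || v[i] > L) stop("differential offset outside [1, L]");
    p->put_bits(cb.code[(size_t) v[i]], cb.len[(size_t) v[i]]);
  }
}

// [[Rcpp::export(name = ".bw_raw")]]
RawVector bw_raw(SEXP bw) {
  XPtr<BitWriter> p(bw);
  RawVector out((R_xlen_t) p->bytes.size());
  std::copy(p->bytes.begin(), p->bytes.end(), out.begin());
  out.attr("nbits") = (double) p->bit_length();
  return out;
}

// [[Rcpp::export(name = ".br_new")]]
SEXP br_new(RawVector r) {
  XPtr<BitReader> p(new BitReader(r), true);
  return p;
}

// [[Rcpp::export(name = ".br_gamma")]]
IntegerVector br_gamma(SEXP br, int n) {
  XPtr<BitReader> p(br);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t v = p->get_gamma();
    if (v > 2147483647ull) stop("corrupt gamma code");
    out[i] = (int) v;
  }
  return out;
}

// [[Rcpp::export(name = ".br_fixed")]]
IntegerVector br_fixed(SEXP br, int n, int width) {
  XPtr<BitReader> p(br);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (int) p->get_bits(width);
  return out;
}

// [[Rcpp::export(name = ".br_huff")]]
IntegerVector br_huff(SEXP br, int n, int L) {
  XPtr<BitReader> p(br);
  Decoder dec;
  build_decoder(L, dec);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = decode_symbol(*p, dec);
  return out;
}

// ---- 2-bit base packing --------------------------------------------------

// [[Rcpp::export(name = ".pack_bases_cpp")]]
RawVector pack_bases_cpp(std::string s) {
  size_t n = s.size();
  RawVector out((R_xlen_t)((n + 3) / 4));
  for (size_t i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: stop("only A,C,G,T can be 2-bit packed");
    }
    out[i >> 2] |= (Rbyte)(v << (6 - 2 * (i & 3)));
  }
  return out;
}

// [[Rcpp::export(name = ".unpack_bases_cpp")]]
std::string unpack_bases_cpp(RawVector r, double n) {
  size_t nn = (size_t) n;
  if (r.size() * 4 < (R_xlen_t) nn) stop("packed base stream truncated");
  static const char* bases = "ACGT";
  std::string s(nn, 'A');
  for (size_t i = 0; i < nn; ++i)
    s[i] = bases[(r[i >> 2] >> (6 - 2 * (i & 3))) & 3];
  return s;
}
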