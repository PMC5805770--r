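#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Exact-seed, mismatch-tolerant overlap validation.
// Overlap of length l: child[0..l-1] aligned to par[L-l..L-1].
// The last K overlap positions (the seed window) must match exactly;
// at most eps mismatches are allowed among the remaining l-K positions.
static inline bool validate_overlap(const std::string& par, const std::string& child,
                                    int l, int K, int eps) {
  const int L = (int) par.size();
  const int off = L - l;
  for (int t = l - K; t < l; ++t)
    if (child[(size_t) t] != par[(size_t)(off + t)]) return false;
  int mm = 0;
  for (int t = 0; t < l - K; ++t)
    if (child[(size_t) t] != par[(size_t)(off + t)] && ++mm > eps) return false;
  return true;
}

// [[Rcpp::export(name = ".spov_cpp")]]
IntegerVector spov_cpp(std::string u_seq, std::string v_seq, int K, int eps) {
  const int L = (int) u_seq.size();
  if ((int) v_seq.size() != L) stop("sequences must have equal length");
  if (K < 1 || K > L) stop("K must satisfy 1 <= K <= L");
  if (eps < 0) stop("eps must be >= 0");
  for (int l = L; l >= K; --l)
    if (validate_overlap(u_seq, v_seq, l, K, eps))
      return IntegerVector::create(l);
  return IntegerVector::create(NA_INTEGER);
}

typedef std::unordered_map<std::string, std::vector<int> > kmer_index;

struct orient_hit { int node; int orient; }; // orient: 0 fwd, 1 rev (relative to node seq)

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N'; default: return c;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Parent search: slide the K-window over cand right-to-left (l = L-1 .. K),
// query the suffix index, extend with validate_overlap. First success wins
// (longest overlap); within one window position candidates are tried in
// ascending node id (index vectors are kept in insertion order).
// l = L (a zero-weight edge) is excluded: distinct nodes only fully match
// via N-placeholder collisions or eps > 0, and edge weights live in [1, L].
static bool parent_search(const std::string& cand, const std::vector<std::string>& seqs,
                          const kmer_index& suf_idx, int K, int eps,
                          int& best_l, int& best_parent) {
  const int L = (int) cand.size();
  for (int l = L - 1; l >= K; --l) {
    kmer_index::const_iterator it = suf_idx.find(cand.substr((size_t)(l - K), (size_t) K));
    if (it == suf_idx.end()) continue;
    const std::vector<int>& bucket = it->second;
    for (size_t b = 0; b < bucket.size(); ++b) {
      int u = bucket[b];
      if (validate_overlap(seqs[(size_t) u], cand, l, K, eps)) {
        best_l = l; best_parent = u;
        return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export(name = ".integrate_reads_cpp")]]
List integrate_reads_cpp(CharacterVector reads,
                         int K, int eps, bool strand_correct,
                         CharacterVector init_seq, IntegerVector init_parent,
                         IntegerVector init_weight, IntegerVector init_fwd,
                         IntegerVector init_rev, List init_noffsets) {
  const int n0 = init_seq.size();
  std::vector<std::string> seqs;
  std::vector<int> parent, weight, fwd_mult, rev_mult;
  std::vector<std::vector<int> > noff;
  kmer_index pref_idx, suf_idx;
  std::unordered_map<std::string, std::pair<int,int> > node_of; // key -> (id, orient)

  int L = -1;
  if (reads.size() > 0) L = (int) std::string(reads[0]).size();
  if (n0 > 0) L = (int) std::string(init_seq[0]).size();
  if (L >= 0) {
    if (K < 1) stop("K must be >= 1");
    if (K > L) stop("K must satisfy K <= L");
    if (eps < 0) stop("eps must be >= 0");
  }

  seqs.reserve(n0 + reads.size());
  // Rebuild state for an existing forest (forest_insert); an empty forest
  // (n0 = 0) is the plain build path.
  for (int i = 0; i < n0; ++i) {
    std::string s = as<std::string>(init_seq[i]);
    seqs.push_back(s);
    parent.push_back(init_parent[i] == NA_INTEGER ? -1 : init_parent[i] - 1);
    weight.push_back(init_weight[i]);
    fwd_mult.push_back(init_fwd[i]);
    rev_mult.push_back(init_rev[i]);
    IntegerVector no = init_noffsets[i];
    noff.push_back(std::vector<int>(no.begin(), no.end()));
    pref_idx[s.substr(0, (size_t) K)].push_back(i);
    suf_idx[s.substr((size_t)(L - K), (size_t) K)].push_back(i);
    // reconstruct dedup keys from stored state
    std::string orig = s;
    for (size_t t = 0; t < noff[(size_t) i].size(); ++t) orig[(size_t) noff[(size_t) i][t]] = 'N';
    node_of.insert(std::make_pair(orig, std::make_pair(i, 0)));
    if (strand_correct) node_of.insert(std::make_pair(revcomp_str(orig), std::make_pair(i, 1)));
  }

  for (int r = 0; r < reads.size(); ++r) {
    std::string orig = as<std::string>(reads[r]);
    if ((int) orig.size() != L) stop("all reads must have the same length");

    // duplicate collapse (exact input string; with strand correction also its
    // reverse complement, i.e. the orientations the builder could commit)
    std::unordered_map<std::string, std::pair<int,int> >::iterator dit = node_of.find(orig);
    if (dit != node_of.end()) {
      if (dit->second.second == 0) fwd_mult[(size_t) dit->second.first]++;
      else                         rev_mult[(size_t) dit->second.first]++;
      continue;
    }

    // N positions (0-based, input orientation); placeholder base is 'A'
    std::vector<int> npos;
    std::string fseq = orig;
    for (int t = 0; t < L; ++t) if (fseq[(size_t) t] == 'N') { npos.push_back(t); fseq[(size_t) t] = 'A'; }

    // (1) parent search, in both orientations when strand correction is on;
    // the orientation with the longer validated overlap is committed (ties
    // and the no-hit case keep the input orientation) and never changes.
    int lf = -1, pf = -1, lr = -1, pr = -1;
    bool hitf = parent_search(fseq, seqs, suf_idx, K, eps, lf, pf);
    std::string rseq;
    bool reversed = false;
    if (strand_correct) {
      rseq = revcomp_str(fseq);
      bool hitr = parent_search(rseq, seqs, suf_idx, K, eps, lr, pr);
      if (hitr && (!hitf || lr > lf)) reversed = true;
    }
    const std::string seq = reversed ? rseq : fseq;
    const int par = reversed ? pr : (hitf ? pf : -1);
    const int ovl = reversed ? lr : (hitf ? lf : -1);

    int vid = (int) seqs.size();
    seqs.push_back(seq);
    parent.push_back(par);
    weight.push_back(par >= 0 ? L - ovl : L);
    fwd_mult.push_back(reversed ? 0 : 1);
    rev_mult.push_back(reversed ? 1 : 0);
    if (reversed) for (size_t t = 0; t < npos.size(); ++t) npos[t] = L - 1 - npos[t];
    noff.push_back(npos);

    // (2) children search: slide the K-window left-to-right (overlap l = L-j
    // decreasing), query the prefix index; a validated hit u is reassigned
    // when the new weight beats its current one, at most once per call.
    std::vector<char> reassigned((size_t) vid + 1, 0);
    for (int l = L - 1; l >= K; --l) {
      int j = L - l;
      kmer_index::const_iterator it = pref_idx.find(seq.substr((size_t) j, (size_t) K));
      if (it == pref_idx.end()) continue;
      const std::vector<int>& bucket = it->second;
      for (size_t b = 0; b < bucket.size(); ++b) {
        int u = bucket[b];
        if (u == vid || reassigned[(size_t) u]) continue;
        int new_w = L - l;
        if (new_w >= weight[(size_t) u]) continue;
        if (!validate_overlap(seq, seqs[(size_t) u], l, K, eps)) continue;
        parent[(size_t) u] = vid;
        weight[(size_t) u] = new_w;
        reassigned[(size_t) u] = 1;
      }
    }

    // (3) insert the node's K-prefix and K-suffix into the indices
    pref_idx[seq.substr(0, (size_t) K)].push_back(vid);
    suf_idx[seq.substr((size_t)(L - K), (size_t) K)].push_back(vid);
    node_of.insert(std::make_pair(orig, std::make_pair(vid, reversed ? 1 : 0)));
    if (strand_correct)
      node_of.insert(std::make_pair(revcomp_str(orig), std::make_pair(vid, reversed ? 0 : 1)));
  }

  const int n = (int) seqs.size();
  CharacterVector out_seq(n);
  IntegerVector out_parent(n), out_weight(n), out_fwd(n), out_rev(n);
  List out_noff(n);
  for (int i = 0; i < n; ++i) {
    out_seq[i] = seqs[(size_t) i];
    out_parent[i] = parent[(size_t) i] < 0 ? NA_INTEGER : parent[(size_t) i] + 1;
    out_weight[i] = weight[(size_t) i];
    out_fwd[i] = fwd_mult[(size_t) i];
    out_rev[i] = rev_mult[(size_t) i];
    out_noff[i] = IntegerVector(noff[(size_t) i].begin(), noff[(size_t) i].end());
  }
  return List::create(_["seq"] = out_seq, _["parent"] = out_parent,
                      _["weight"] = out_weight, _["fwd_mult"] = out_fwd,
                      _["rev_mult"] = out_rev, _["n_offsets"] = out_noff);
}
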