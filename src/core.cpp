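// Hash-based exact-seed ungapped read mapper and large-k k-mer counter.
// Contract (shared with the pure-R test oracles): a read of length L is
// reported at reference position t (0-based, end-to-end, per strand) iff
//   (a) some seed_k-mer of the read matches the reference exactly at the
//       corresponding offset on that diagonal, and
//   (b) the full-length Hamming distance at t is <= max_mm.
// Characters are compared literally after uppercasing; any non-ACGT letter
// (e.g. N) never participates in a seed and mismatches everything but itself.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char upc(char c) { return (c >= 'a' && c <= 'z') ? c - 32 : c; }

// Collect the packed k-mer at every valid position of seq into out
// (position -> key); invalid windows get valid=false.
static void roll_kmers(const std::string& seq, int k,
                       std::vector<uint64_t>& keys, std::vector<char>& valid) {
  size_t n = seq.size();
  size_t npos = n >= (size_t)k ? n - k + 1 : 0;
  keys.assign(npos, 0);
  valid.assign(npos, 0);
  if (npos == 0) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int since_bad = k; // #positions since last invalid base (saturating)
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { since_bad = 0; key = 0; }
    else { key = ((key << 2) | (uint64_t)c) & mask; if (since_bad < k) ++since_bad; }
    if (i + 1 >= (size_t)k) {
      size_t pos = i + 1 - k;
      if (since_bad >= k) { keys[pos] = key; valid[pos] = 1; }
    }
  }
}

static inline uint64_t revcomp_key(uint64_t key, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (key & 3ULL));
    key >>= 2;
  }
  return rc;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (upc(c)) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = upc(c);
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > SeedIndex;

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                   int seed_k, int max_mm) {
  if (seed_k < 1 || seed_k > 32) stop("seed_k must be in 1..32");
  int n_ref = ref_seqs.size();
  std::vector<std::string> refs(n_ref);
  for (int i = 0; i < n_ref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  SeedIndex index;
  std::vector<uint64_t> keys; std::vector<char> valid;
  for (int c = 0; c < n_ref; ++c) {
    roll_kmers(refs[c], seed_k, keys, valid);
    for (size_t pos = 0; pos < keys.size(); ++pos)
      if (valid[pos])
        index[keys[pos]].push_back(((uint64_t)c << 40) | (uint64_t)pos);
  }

  std::vector<int> out_read, out_contig, out_start, out_mm, out_len;
  std::vector<char> out_strand;
  int skipped = 0;

  int n_reads = read_seqs.size();
  std::vector<uint64_t> cand;
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int L = (int)fwd.size();
    if (L < seed_k) { ++skipped; continue; }
    for (int strand = 0; strand < 2; ++strand) {
      const std::string rd = strand == 0 ? fwd : revcomp_str(fwd);
      roll_kmers(rd, seed_k, keys, valid);
      cand.clear();
      for (size_t o = 0; o < keys.size(); ++o) {
        if (!valid[o]) continue;
        SeedIndex::const_iterator it = index.find(keys[o]);
        if (it == index.end()) continue;
        for (uint64_t hit : it->second) {
          int c = (int)(hit >> 40);
          long long pos = (long long)(hit & ((1ULL << 40) - 1));
          long long t = pos - (long long)o;
          if (t < 0 || t + L > (long long)refs[c].size()) continue;
          cand.push_back(((uint64_t)c << 40) | (uint64_t)t);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t ct : cand) {
        int c = (int)(ct >> 40);
        int t = (int)(ct & ((1ULL << 40) - 1));
        const std::string& ref = refs[c];
        int mm = 0;
        for (int j = 0; j < L && mm <= max_mm; ++j)
          if (upc(ref[t + j]) != upc(rd[j])) ++mm;
        if (mm <= max_mm) {
          out_read.push_back(r + 1);
          out_contig.push_back(c + 1);
          out_start.push_back(t);
          out_strand.push_back(strand == 0 ? '+' : '-');
          out_mm.push_back(mm);
          out_len.push_back(L);
        }
      }
    }
  }

  int nhit = (int)out_read.size();
  CharacterVector strand_out(nhit);
  for (int i = 0; i < nhit; ++i)
    strand_out[i] = out_strand[i] == '+' ? "+" : "-";
  return List::create(
    _["read"] = wrap(out_read), _["contig"] = wrap(out_contig),
    _["start"] = wrap(out_start), _["strand"] = strand_out,
    _["mismatches"] = wrap(out_mm), _["length"] = wrap(out_len),
    _["skipped"] = skipped);
}

// Canonical (min of forward / reverse-complement) k-mer multiplicity
// histogram over a set of sequences. Returns the histogram plus totals.
// [[Rcpp::export]]
List cpp_kmer_hist(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::unordered_map<uint64_t, uint32_t> counts;
  std::vector<uint64_t> keys; std::vector<char> valid;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    roll_kmers(s, k, keys, valid);
    for (size_t pos = 0; pos < keys.size(); ++pos)
      if (valid[pos]) {
        uint64_t key = keys[pos], rc = revcomp_key(key, k);
        ++counts[key < rc ? key : rc];
      }
  }
  std::unordered_map<uint32_t, uint64_t> hist;
  uint64_t total = 0;
  for (auto& kv : counts) { ++hist[kv.second]; total += kv.second; }
  std::vector<uint32_t> mult; mult.reserve(hist.size());
  for (auto& kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  IntegerVector m(mult.size()); NumericVector n(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[i] = (int)mult[i];
    n[i] = (double)hist[mult[i]];
  }
  return List::create(_["multiplicity"] = m, _["count"] = n,
                      _["distinct"] = (double)counts.size(),
                      _["total"] = (double)total);
}

// For each k-mer window of `region`, its canonical multiplicity in the
// reference sequence set (-1 for windows containing non-ACGT letters).
// [[Rcpp::export]]
IntegerVector cpp_kmer_ref_counts(std::string region, CharacterVector ref_seqs,
                                  int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::unordered_map<uint64_t, uint32_t> counts;
  std::vector<uint64_t> keys; std::vector<char> valid;
  for (int i = 0; i < ref_seqs.size(); ++i) {
    std::string s = as<std::string>(ref_seqs[i]);
    roll_kmers(s, k, keys, valid);
    for (size_t pos = 0; pos < keys.size(); ++pos)
      if (valid[pos]) {
        uint64_t key = keys[pos], rc = revcomp_key(key, k);
        ++counts[key < rc ? key : rc];
      }
  }
  roll_kmers(region, k, keys, valid);
  IntegerVector out(keys.size());
  for (size_t pos = 0; pos < keys.size(); ++pos) {
    if (!valid[pos]) { out[pos] = -1; continue; }
    uint64_t key = keys[pos], rc = revcomp_key(key, k);
    auto it = counts.find(key < rc ? key : rc);
    out[pos] = it == counts.end() ? 0 : (int)it->second;
  }
  return out;
}
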