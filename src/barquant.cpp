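#include <Rcpp.h>
#include <cstring>
#include <string>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    buf.resize(L);
    for (size_t j = 0; j < L; ++j) buf[L - 1 - j] = comp_base(s[j]);
    out[i] = buf;
  }
  return out;
}

// Quality-aware suffix-prefix overlap merge.
//
// read2 is reverse-complemented (qualities reversed) so both reads are in
// template orientation, then every overlap length ov in
// [min_overlap, min(len1, len2)] is scored by the number of equal non-N
// bases between the read1 suffix and the read2 prefix of length ov.
// Candidates with mismatches/ov <= max_mismatch_frac compete; the highest
// match count wins, ties go to the longer overlap.  Consensus keeps the
// higher-quality base (N has quality 0); equal-quality disagreements keep
// read1's base with quality max(q1, q2) - 3.
//
// status: 0 = merged, 1 = no_overlap, 2 = too_short_after_merge
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac,
                     int min_merged_len) {
  R_xlen_t n = seq1.size();
  if (qual1.size() != n || seq2.size() != n || qual2.size() != n)
    stop("seq/qual vectors must have equal length");
  if (min_overlap < 1) stop("min_overlap must be >= 1");

  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mism(n), status(n);
  std::string r2, q2r, cons, consq;

  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r1 = CHAR(seq1[i]);
    const char *q1 = CHAR(qual1[i]);
    const char *s2 = CHAR(seq2[i]);
    const char *qs2 = CHAR(qual2[i]);
    int l1 = (int) std::strlen(r1);
    int l2 = (int) std::strlen(s2);
    if ((int) std::strlen(q1) != l1 || (int) std::strlen(qs2) != l2)
      stop("sequence and quality lengths differ at record %d", (int) (i + 1));

    r2.resize(l2); q2r.resize(l2);
    for (int j = 0; j < l2; ++j) {
      r2[l2 - 1 - j] = comp_base(s2[j]);
      q2r[l2 - 1 - j] = qs2[j];
    }

    int ovmax = l1 < l2 ? l1 : l2;
    int best_ov = -1, best_matches = -1;
    for (int ov = ovmax; ov >= min_overlap; --ov) {
      const char *a = r1 + (l1 - ov);
      int allowed = (int) (max_mismatch_frac * ov + 1e-9);
      int matches = 0, mm = 0;
      for (int j = 0; j < ov; ++j) {
        if (a[j] == r2[j] && a[j] != 'N') ++matches;
        else if (++mm > allowed) break;
      }
      if (mm <= allowed && matches > best_matches) {
        best_matches = matches;
        best_ov = ov;
      }
    }

    if (best_ov < 0) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = NA_INTEGER; mism[i] = NA_INTEGER;
      status[i] = 1;
      continue;
    }

    int ov = best_ov;
    int L = l1 + l2 - ov;
    cons.assign(r1, (size_t) (l1 - ov));
    consq.assign(q1, (size_t) (l1 - ov));
    cons.reserve(L); consq.reserve(L);
    for (int j = 0; j < ov; ++j) {
      char b1 = r1[l1 - ov + j], b2 = r2[j];
      int iq1 = b1 == 'N' ? 0 : (int) q1[l1 - ov + j] - 33;
      int iq2 = b2 == 'N' ? 0 : (int) q2r[j] - 33;
      char b; int q;
      if (b1 == b2) {
        b = b1; q = iq1 > iq2 ? iq1 : iq2;
      } else if (iq1 > iq2) {
        b = b1; q = iq1;
      } else if (iq2 > iq1) {
        b = b2; q = iq2;
      } else {
        b = b1; q = iq1 - 3; if (q < 0) q = 0;
      }
      cons.push_back(b);
      consq.push_back((char) (q + 33));
    }
    cons.append(r2, (size_t) ov, std::string::npos);
    consq.append(q2r, (size_t) ov, std::string::npos);

    mseq[i] = cons; mqual[i] = consq;
    overlap[i] = ov; mism[i] = ov - best_matches;
    status[i] = L < min_merged_len ? 2 : 0;
  }

  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap_len"] = overlap,
                      _["n_mismatches"] = mism,
                      _["status"] = status);
}

// Best approximate (Hamming) occurrence of a short anchor in each sequence.
//
// Scans windows starting at `from` (1-based).  Among windows with the
// minimal mismatch count, returns the leftmost when prefer < 1, otherwise
// the one whose start is closest to `prefer` (ties: smaller start).
// Returns an n x 2 matrix: start position (1-based, -1 if the sequence is
// shorter than the anchor) and mismatch count at that position.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_anchor(CharacterVector seqs, std::string anchor,
                              IntegerVector from, IntegerVector prefer) {
  R_xlen_t n = seqs.size();
  int a = (int) anchor.size();
  if (a < 1) stop("anchor must be non-empty");
  bool from1 = from.size() == 1, pref1 = prefer.size() == 1;
  IntegerMatrix out(n, 2);

  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out(i, 0) = -1; out(i, 1) = a + 1; continue; }
    const char *s = CHAR(seqs[i]);
    int L = (int) std::strlen(s);
    int f0 = (from1 ? from[0] : from[i]) - 1;
    if (f0 < 0) f0 = 0;
    int pref = pref1 ? prefer[0] : prefer[i];
    int best_mm = a + 1, best_pos = -1;
    for (int p = f0; p + a <= L; ++p) {
      int mm = 0;
      for (int j = 0; j < a; ++j) {
        if (s[p + j] != anchor[(size_t) j]) {
          if (++mm >= best_mm && !(mm == best_mm && pref >= 1)) break;
        }
      }
      if (mm < best_mm) {
        best_mm = mm; best_pos = p + 1;
        if (mm == 0 && pref < 1) break;
      } else if (mm == best_mm && pref >= 1 && best_pos > 0) {
        int dnew = p + 1 - pref; if (dnew < 0) dnew = -dnew;
        int dold = best_pos - pref; if (dold < 0) dold = -dold;
        if (dnew < dold) best_pos = p + 1;
      }
    }
    out(i, 0) = best_pos;
    out(i, 1) = best_mm;
  }
  return out;
}

// Apply substitution and indel sequencing errors per base, assigning a
// two-tier quality: q_hi for faithful bases, q_lo for substituted or
// inserted bases.  Deletions drop the base; insertions add one random base
// before the current one.  Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List cpp_mutate_reads(CharacterVector seqs, double sub_rate,
                      double indel_rate, int q_hi, int q_lo) {
  R_xlen_t n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  char chi = (char) (q_hi + 33), clo = (char) (q_lo + 33);
  std::string s, q;
  RNGScope scope;

  for (R_xlen_t i = 0; i < n; ++i) {
    const char *t = CHAR(seqs[i]);
    int L = (int) std::strlen(t);
    s.clear(); q.clear();
    s.reserve(L + 4); q.reserve(L + 4);
    for (int j = 0; j < L; ++j) {
      if (indel_rate > 0 && unif_rand() < indel_rate) {
        if (unif_rand() < 0.5) {
          continue;  // deletion
        } else {     // insertion before current base
          s.push_back(bases[(int) (unif_rand() * 4) & 3]);
          q.push_back(clo);
        }
      }
      char c = t[j];
      if (sub_rate > 0 && unif_rand() < sub_rate) {
        char nc;
        do { nc = bases[(int) (unif_rand() * 4) & 3]; } while (nc == c);
        s.push_back(nc);
        q.push_back(clo);
      } else {
        s.push_back(c);
        q.push_back(chi);
      }
    }
    oseq[i] = s; oqual[i] = q;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}
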