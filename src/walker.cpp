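#include <Rcpp.h>
#include <cctype>
#include <cstring>
using namespace Rcpp;

// Base codes: A=1, C=2, G=3, T=4, anything else (N, ambiguity) = 0.
static inline int base_code(char c) {
  switch (toupper(c)) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 3;
  case 'T': return 4;
  default:  return 0;
  }
}

static inline int complement_code(int b) {
  // A<->T, C<->G, 0 stays 0
  static const int comp[5] = {0, 4, 3, 2, 1};
  return comp[b];
}

// Growable event buffers kept as std::vectors, copied out once at the end.
struct EventBuf {
  std::vector<int> read_idx, ref_pos, cycle, ref_b, read_b, qual, flank5, flank3, orient;
};

// [[Rcpp::export]]
List walk_reads_cpp(CharacterVector ref_seqs,
                    IntegerVector tid,       // 1-based index into ref_seqs
                    IntegerVector pos,       // 1-based leftmost aligned position
                    LogicalVector reverse,
                    IntegerVector orient,    // 1=R1F 2=R1R 3=R2F 4=R2R
                    CharacterVector cigar,
                    CharacterVector seq,
                    CharacterVector qual,    // Phred+33 ASCII, may be "*"
                    int max_len) {
  const int n = tid.size();
  const int nref = ref_seqs.size();

  // cache reference C strings and lengths
  std::vector<const char*> refp(nref);
  std::vector<int> reflen(nref);
  for (int k = 0; k < nref; ++k) {
    refp[k] = CHAR(STRING_ELT(ref_seqs, k));
    reflen[k] = (int) strlen(refp[k]);
  }

  EventBuf mm;
  std::vector<int> ins_len, del_len;
  std::vector<int> r_nmm(n, 0), r_clip5(n, 0), r_clip3(n, 0),
    r_aligned(n, 0), r_nins(n, 0), r_ndel(n, 0), r_insbases(n, 0), r_nN(n, 0);

  // per-cycle accumulators
  IntegerMatrix cycle_cov(max_len, 4);     // aligned non-N comparisons, per orientation
  IntegerMatrix nt_cycle(max_len, 5);      // as-sequenced base content A,C,G,T,N
  NumericMatrix qual_cycle_sum(max_len, 1);
  IntegerMatrix qual_cycle_n(max_len, 1);
  IntegerVector qual_hist(94);             // Phred 0..93, all read bases
  IntegerVector gc_count(n), at_count(n);

  for (int i = 0; i < n; ++i) {
    const char* s  = CHAR(STRING_ELT(seq, i));
    const char* q  = CHAR(STRING_ELT(qual, i));
    const char* cg = CHAR(STRING_ELT(cigar, i));
    const int L = (int) strlen(s);
    const bool has_q = !(q[0] == '*' && q[1] == '\0');
    const int k = tid[i] - 1;
    if (k < 0 || k >= nref) stop("read %d: contig index out of range", i + 1);
    const char* R = refp[k];
    const int RL = reflen[k];
    const bool rev = reverse[i];
    const int ori = orient[i];

    // whole-read per-cycle base content, GC, quality
    for (int j = 0; j < L; ++j) {
      int b = base_code(s[j]);
      int cyc = rev ? (L - j) : (j + 1);          // sequencing-order cycle
      int bs = rev ? complement_code(b) : b;      // as-sequenced basecall
      if (cyc >= 1 && cyc <= max_len) {
        nt_cycle(cyc - 1, bs == 0 ? 4 : bs - 1) += 1;
        if (has_q) {
          int ph = q[j] - 33;
          if (ph < 0) ph = 0; if (ph > 93) ph = 93;
          qual_cycle_sum(cyc - 1, 0) += ph;
          qual_cycle_n(cyc - 1, 0) += 1;
          qual_hist[ph] += 1;
        }
      }
      if (b == 2 || b == 3) gc_count[i] += 1;
      else if (b == 1 || b == 4) at_count[i] += 1;
    }

    // CIGAR walk
    int qi = 0;               // 0-based query index
    int rp = pos[i] - 1;      // 0-based reference index
    int oplen = 0;
    bool seen_aligned_or_indel = false;
    for (const char* p = cg; *p; ++p) {
      char c = *p;
      if (c >= '0' && c <= '9') { oplen = oplen * 10 + (c - '0'); continue; }
      switch (c) {
      case 'M': case '=': case 'X': {
        for (int t = 0; t < oplen; ++t, ++qi, ++rp) {
          if (qi >= L) stop("read %d: CIGAR consumes more query than SEQ length", i + 1);
          if (rp < 0 || rp >= RL)
            stop("read %d: alignment walks off contig end (pos %d, contig length %d)",
                 i + 1, rp + 1, RL);
          int rb = base_code(R[rp]);
          int qb = base_code(s[qi]);
          int cyc = rev ? (L - qi) : (qi + 1);
          if (rb == 0 || qb == 0) { r_nN[i] += 1; continue; }  // N-involving: separate tally
          cycle_cov(cyc - 1, ori - 1) += 1;
          r_aligned[i] += 1;
          if (rb != qb) {
            mm.read_idx.push_back(i + 1);
            mm.ref_pos.push_back(rp + 1);
            mm.cycle.push_back(cyc);
            mm.ref_b.push_back(rb);
            mm.read_b.push_back(qb);
            mm.qual.push_back(has_q ? (q[qi] - 33) : NA_INTEGER);
            mm.flank5.push_back(rp > 0 ? base_code(R[rp - 1]) : 0);
            mm.flank3.push_back(rp + 1 < RL ? base_code(R[rp + 1]) : 0);
            mm.orient.push_back(ori);
            r_nmm[i] += 1;
          }
        }
        seen_aligned_or_indel = true;
        break;
      }
      case 'I':
        ins_len.push_back(oplen);
        r_nins[i] += 1;
        r_insbases[i] += oplen;
        qi += oplen;
        seen_aligned_or_indel = true;
        break;
      case 'D':
        del_len.push_back(oplen);
        r_ndel[i] += 1;
        rp += oplen;
        seen_aligned_or_indel = true;
        break;
      case 'N':
        rp += oplen;  // reference skip (spliced); not a deletion
        break;
      case 'S':
        if (!seen_aligned_or_indel) {
          if (rev) r_clip3[i] += oplen; else r_clip5[i] += oplen;
        } else {
          if (rev) r_clip5[i] += oplen; else r_clip3[i] += oplen;
        }
        qi += oplen;
        break;
      case 'H':
        if (!seen_aligned_or_indel) {
          if (rev) r_clip3[i] += oplen; else r_clip5[i] += oplen;
        } else {
          if (rev) r_clip5[i] += oplen; else r_clip3[i] += oplen;
        }
        break;
      case 'P':
        break;
      default:
        stop("read %d: unsupported CIGAR op '%c'", i + 1, c);
      }
      oplen = 0;
    }
    if (qi != L)
      stop("read %d: CIGAR query length (%d) differs from SEQ length (%d)", i + 1, qi, L);
  }

  return List::create(
    _["mm"] = List::create(
      _["read_idx"] = wrap(mm.read_idx),
      _["ref_pos"]  = wrap(mm.ref_pos),
      _["cycle"]    = wrap(mm.cycle),
      _["ref_code"] = wrap(mm.ref_b),
      _["read_code"] = wrap(mm.read_b),
      _["qual"]     = wrap(mm.qual),
      _["flank5"]   = wrap(mm.flank5),
      _["flank3"]   = wrap(mm.flank3),
      _["orient"]   = wrap(mm.orient)),
    _["reads"] = List::create(
      _["n_mismatch"] = wrap(r_nmm),
      _["clip5"] = wrap(r_clip5),
      _["clip3"] = wrap(r_clip3),
      _["aligned_len"] = wrap(r_aligned),
      _["n_ins"] = wrap(r_nins),
      _["n_del"] = wrap(r_ndel),
      _["ins_bases"] = wrap(r_insbases),
      _["n_n_positions"] = wrap(r_nN),
      _["gc_count"] = gc_count,
      _["at_count"] = at_count),
    _["ins_len"] = wrap(ins_len),
    _["del_len"] = wrap(del_len),
    _["cycle_cov"] = cycle_cov,
    _["nt_cycle"] = nt_cycle,
    _["qual_cycle_sum"] = qual_cycle_sum,
    _["qual_cycle_n"] = qual_cycle_n,
    _["qual_hist"] = qual_hist);
}
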