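#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Exhaustive ungapped overlap scan over all offsets with overlap >= min_overlap,
// scored as matches - mismatches (N never matches), ties broken toward the longer
// overlap. On the best offset the pair is fused with a posterior quality rule:
// agreeing bases get min(q1+q2, qual_cap); disagreeing columns keep the
// higher-quality base with quality max(2, |q1-q2|).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fwdq,
                     CharacterVector rev, CharacterVector revq,
                     int min_overlap, int qual_cap) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), diffs(n), score(n);
  for (int i = 0; i < n; i++) {
    std::string f  = as<std::string>(fwd[i]);
    std::string fq = as<std::string>(fwdq[i]);
    std::string r0 = as<std::string>(rev[i]);
    std::string rq0 = as<std::string>(revq[i]);
    int nf = f.size(), nr = r0.size();
    std::string r(nr, 'N'), rq(nr, '!');
    for (int j = 0; j < nr; j++) {
      r[j]  = comp_base(r0[nr - 1 - j]);
      rq[j] = rq0[nr - 1 - j];
    }
    int best_o = -1, best_score = INT_MIN, best_d = 0;
    int omax = std::min(nf, nr);
    for (int o = min_overlap; o <= omax; o++) {
      int d = 0, m = 0;
      const char *fp = f.data() + (nf - o);
      for (int j = 0; j < o; j++) {
        char a = fp[j], b = r[j];
        if (a == b && a != 'N') m++; else d++;
      }
      int sc = m - d;
      if (sc > best_score || (sc == best_score && o > best_o)) {
        best_score = sc; best_o = o; best_d = d;
      }
    }
    if (best_o < 0) {
      overlap[i] = 0; diffs[i] = NA_INTEGER; score[i] = NA_INTEGER;
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      continue;
    }
    std::string s, q;
    s.reserve(nf + nr - best_o); q.reserve(nf + nr - best_o);
    s.append(f, 0, nf - best_o);
    q.append(fq, 0, nf - best_o);
    for (int j = 0; j < best_o; j++) {
      char a = f[nf - best_o + j], b = r[j];
      int qa = fq[nf - best_o + j] - 33, qb = rq[j] - 33;
      if (a == b) {
        int qp = qa + qb; if (qp > qual_cap) qp = qual_cap;
        s.push_back(a); q.push_back((char)(qp + 33));
      } else {
        int qp = qa >= qb ? qa - qb : qb - qa;
        if (qp < 2) qp = 2; if (qp > qual_cap) qp = qual_cap;
        s.push_back(qa >= qb ? a : b);
        q.push_back((char)(qp + 33));
      }
    }
    s.append(r, best_o, nr - best_o);
    q.append(rq, best_o, nr - best_o);
    overlap[i] = best_o; diffs[i] = best_d; score[i] = best_score;
    mseq[i] = s; mqual[i] = q;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap, _["diffs"] = diffs,
                      _["score"] = score);
}

// Hamming mismatch counts, queries x refs; NA when lengths differ.
// N matches nothing, including another N.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector queries, CharacterVector refs) {
  int n = queries.size(), k = refs.size();
  std::vector<std::string> R2(k);
  for (int j = 0; j < k; j++) R2[j] = as<std::string>(refs[j]);
  IntegerMatrix out(n, k);
  for (int i = 0; i < n; i++) {
    std::string qy = as<std::string>(queries[i]);
    int L = qy.size();
    for (int j = 0; j < k; j++) {
      if ((int)R2[j].size() != L) { out(i, j) = NA_INTEGER; continue; }
      int d = 0;
      const char *a = qy.data(), *b = R2[j].data();
      for (int p = 0; p < L; p++) {
        if (a[p] != b[p] || a[p] == 'N') d++;
      }
      out(i, j) = d;
    }
  }
  return out;
}

// Mismatches of an IUPAC primer against each sequence, anchored at the 5'
// start (from_end = false) or flush with the 3' end (from_end = true).
// A read position matches when its base is in the primer code's allowed set;
// an N in the read never matches. Sequences shorter than the primer get NA.
// [[Rcpp::export]]
IntegerVector cpp_primer_mismatch(CharacterVector seqs, std::string primer,
                                  bool from_end) {
  // IUPAC bitmask: A=1, C=2, G=4, T=8
  int mask[256]; for (int i = 0; i < 256; i++) mask[i] = 0;
  mask['A'] = 1; mask['C'] = 2; mask['G'] = 4; mask['T'] = 8;
  mask['R'] = 1 | 4; mask['Y'] = 2 | 8; mask['S'] = 2 | 4; mask['W'] = 1 | 8;
  mask['K'] = 4 | 8; mask['M'] = 1 | 2;
  mask['B'] = 2 | 4 | 8; mask['D'] = 1 | 4 | 8; mask['H'] = 1 | 2 | 8;
  mask['V'] = 1 | 2 | 4; mask['N'] = 15;
  int base[256]; for (int i = 0; i < 256; i++) base[i] = 0;
  base['A'] = 1; base['C'] = 2; base['G'] = 4; base['T'] = 8;
  int plen = primer.size();
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    int L = s.size();
    if (L < plen) { out[i] = NA_INTEGER; continue; }
    int off = from_end ? (L - plen) : 0;
    int d = 0;
    for (int p = 0; p < plen; p++) {
      unsigned char pc = primer[p], sc = s[off + p];
      if (!(mask[pc] & base[sc])) d++;
    }
    out[i] = d;
  }
  return out;
}

// Expected errors: sum of 10^(-Q/10) over the first trunc positions
// (trunc <= 0 means the whole string). Qualities are Phred+33 characters.
// [[Rcpp::export]]
NumericVector cpp_expected_errors(CharacterVector quals, int trunc) {
  int n = quals.size();
  NumericVector out(n);
  double tab[128];
  for (int q = 0; q < 128; q++) tab[q] = std::pow(10.0, -q / 10.0);
  for (int i = 0; i < n; i++) {
    std::string q = as<std::string>(quals[i]);
    int L = q.size();
    if (trunc > 0 && trunc < L) L = trunc;
    double ee = 0.0;
    for (int p = 0; p < L; p++) {
      int ph = q[p] - 33; if (ph < 0) ph = 0; if (ph > 93) ph = 93;
      ee += tab[ph];
    }
    out[i] = ee;
  }
  return out;
}
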