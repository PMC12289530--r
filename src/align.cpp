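#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with match +1, mismatch 0, gap -1
// (linear gap). Returns the identity count of the best-scoring local
// alignment; among co-optimal alignments the one with the most identities
// is taken, which makes the value well-defined (lexicographic (score,
// identities) maximisation is compatible with the DP because every
// extension adds the same increment to both co-optimal predecessors).

// [[Rcpp::export(name = ".sw_identity")]]
IntegerVector sw_identity(std::string peptide, std::string protein) {
  const int m = peptide.size(), n = protein.size();
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Mprev(n + 1, 0), Mcur(n + 1, 0);
  int best_h = 0, best_m = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Mcur[0] = 0;
    const char pi = peptide[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int match = (pi == protein[j - 1]) ? 1 : 0;
      int h = 0, mm = 0;  // start-anew option
      int cand_h = Hprev[j - 1] + match;
      int cand_m = Mprev[j - 1] + match;
      if (cand_h > h || (cand_h == h && cand_m > mm)) { h = cand_h; mm = cand_m; }
      cand_h = Hprev[j] - 1; cand_m = Mprev[j];
      if (cand_h > h || (cand_h == h && cand_m > mm)) { h = cand_h; mm = cand_m; }
      cand_h = Hcur[j - 1] - 1; cand_m = Mcur[j - 1];
      if (cand_h > h || (cand_h == h && cand_m > mm)) { h = cand_h; mm = cand_m; }
      Hcur[j] = h; Mcur[j] = mm;
      if (h > best_h || (h == best_h && mm > best_m)) { best_h = h; best_m = mm; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Mprev, Mcur);
  }
  return IntegerVector::create(Named("score") = best_h,
                               Named("identities") = best_m);
}

// Best identity count of each peptide against each of a set of proteins.
// Returns an m x 2 matrix: identities and index (1-based) of the first
// protein attaining the maximum identity count.
// [[Rcpp::export(name = ".sw_identity_many")]]
IntegerMatrix sw_identity_many(CharacterVector peptides,
                               CharacterVector proteins) {
  const int np = peptides.size(), nk = proteins.size();
  std::vector<std::string> prot(nk);
  for (int k = 0; k < nk; ++k) prot[k] = as<std::string>(proteins[k]);
  IntegerMatrix out(np, 2);
  for (int i = 0; i < np; ++i) {
    std::string pep = as<std::string>(peptides[i]);
    int best = 0, arg = NA_INTEGER;
    for (int k = 0; k < nk; ++k) {
      IntegerVector r = sw_identity(pep, prot[k]);
      if (arg == NA_INTEGER || r[1] > best) { best = r[1]; arg = k + 1; }
    }
    out(i, 0) = best;
    out(i, 1) = arg;
  }
  return out;
}
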