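#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>

// Base-pair maximisation (Nussinov) secondary-structure prediction with a
// minimum hairpin loop of `min_loop` unpaired nucleotides. Allowed pairs are
// Watson-Crick plus G:T (G:U in RNA). This is the bundled fold_fn fallback:
// the hairpin validation contract is about counting duplex mismatches in a
// returned dot-bracket string, not about a specific thermodynamic model.

static inline bool can_pair(char a, char b) {
  switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'T';
    case 'C': return b == 'G';
    default:  return false; // N never pairs
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n == 0) return "";
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 1; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      int best = M[i + 1][j];                       // i unpaired
      if (M[i][j - 1] > best) best = M[i][j - 1];   // j unpaired
      if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
        int v = (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {             // bifurcation
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // traceback; prefer pairing (i,j), then i-unpaired, then j-unpaired,
  // then the first admissible bifurcation point: deterministic structure.
  std::string db(n, '.');
  std::stack<std::pair<int, int>> st;
  st.push({0, n - 1});
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (i >= j) continue;
    int target = M[i][j];
    if (target == 0) continue;
    if (can_pair(seq[i], seq[j]) && j - i > min_loop &&
        target == (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1) {
      db[i] = '(';
      db[j] = ')';
      st.push({i + 1, j - 1});
      continue;
    }
    if (target == M[i + 1][j]) { st.push({i + 1, j}); continue; }
    if (target == M[i][j - 1]) { st.push({i, j - 1}); continue; }
    bool done = false;
    for (int k = i + 1; k < j && !done; ++k) {
      if (target == M[i][k] + M[k + 1][j]) {
        st.push({i, k});
        st.push({k + 1, j});
        done = true;
      }
    }
  }
  return db;
}
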