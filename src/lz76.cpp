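#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// Lempel-Ziv 1976 complexity: the number of components of the exhaustive
// production history. A component starting at p ends at the first position
// q where s[p..q] is not a substring of s[1..q-1]; the final, possibly
// reproducible, component counts as one phrase.
//
// Substring queries against the growing prefix are answered with an online
// suffix automaton, giving linear total time (the direct quadratic scan is
// prohibitively slow on long low-entropy spike sequences). The current
// match state is renormalised along suffix links after clone splits so it
// always represents the active phrase prefix.
namespace {

struct SuffixAutomaton {
  std::vector<std::array<int, 2>> nxt;
  std::vector<int> link, len;
  int last;

  explicit SuffixAutomaton(int n_reserve) {
    nxt.reserve(2 * n_reserve + 2);
    link.reserve(2 * n_reserve + 2);
    len.reserve(2 * n_reserve + 2);
    nxt.push_back({-1, -1});
    link.push_back(-1);
    len.push_back(0);
    last = 0;
  }

  int new_state(int l, int lk, const std::array<int, 2>& tr) {
    nxt.push_back(tr);
    link.push_back(lk);
    len.push_back(l);
    return (int)nxt.size() - 1;
  }

  void extend(int c) {
    int cur = new_state(len[last] + 1, -1, {-1, -1});
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q], nxt[q]);
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

}  // namespace

// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  SuffixAutomaton sam(n);
  int c = 0;       // completed phrases
  int st = 0;      // automaton state of the active phrase prefix
  int L = 0;       // length of the active phrase prefix
  for (int q = 0; q < n; ++q) {
    const int ch = s[q];
    // keep st valid for a match of length L after clone splits
    while (sam.link[st] != -1 && sam.len[sam.link[st]] >= L)
      st = sam.link[st];
    if (L > 0 || q > 0) {
      // is phrase-prefix + ch a substring of s[0..q-1]?
      int to = sam.nxt[st][ch];
      if (to != -1) {
        st = to;
        ++L;
      } else {
        ++c;       // innovation: phrase ends here
        st = 0;
        L = 0;
      }
    } else {
      ++c;         // very first symbol is always a new phrase
    }
    sam.extend(ch);
  }
  if (L > 0) ++c;  // unterminated final phrase
  return c;
}
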