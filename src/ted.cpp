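#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha ordered tree edit distance, unit costs
// (insert = delete = relabel = 1).
//
// Trees arrive as postorder arrays: label[i] is an integer node label and
// lml[i] the (1-based) postorder index of the leftmost leaf of the subtree
// rooted at i+1. Keyroots are the nodes with no left sibling on the path
// to the root, i.e. the last node of each distinct lml value in postorder.

static std::vector<int> keyroots(const IntegerVector& lml) {
  int n = lml.size();
  std::vector<int> kr;
  std::vector<bool> seen(n + 2, false);
  for (int i = n - 1; i >= 0; --i) {
    if (!seen[lml[i]]) {
      kr.push_back(i + 1);  // 1-based postorder index
      seen[lml[i]] = true;
    }
  }
  std::sort(kr.begin(), kr.end());
  return kr;
}

// [[Rcpp::export(name = ".zs_tree_distance")]]
int zs_tree_distance(IntegerVector label1, IntegerVector lml1,
                     IntegerVector label2, IntegerVector lml2) {
  int n1 = label1.size(), n2 = label2.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;
  std::vector<int> kr1 = keyroots(lml1), kr2 = keyroots(lml2);
  std::vector<std::vector<int> > td(n1 + 1, std::vector<int>(n2 + 1, 0));
  // forest distance table, reused; indices offset by keyroot's leftmost leaf
  std::vector<std::vector<int> > fd(n1 + 2, std::vector<int>(n2 + 2, 0));

  for (size_t a = 0; a < kr1.size(); ++a) {
    int i = kr1[a];
    int li = lml1[i - 1];
    for (size_t b = 0; b < kr2.size(); ++b) {
      int j = kr2[b];
      int lj = lml2[j - 1];
      fd[li - 1][lj - 1] = 0;
      for (int x = li; x <= i; ++x) fd[x][lj - 1] = fd[x - 1][lj - 1] + 1;
      for (int y = lj; y <= j; ++y) fd[li - 1][y] = fd[li - 1][y - 1] + 1;
      for (int x = li; x <= i; ++x) {
        for (int y = lj; y <= j; ++y) {
          if (lml1[x - 1] == li && lml2[y - 1] == lj) {
            int rel = (label1[x - 1] == label2[y - 1]) ? 0 : 1;
            int d = std::min(std::min(fd[x - 1][y] + 1, fd[x][y - 1] + 1),
                             fd[x - 1][y - 1] + rel);
            fd[x][y] = d;
            td[x][y] = d;
          } else {
            int lx = lml1[x - 1], ly = lml2[y - 1];
            int d = std::min(std::min(fd[x - 1][y] + 1, fd[x][y - 1] + 1),
                             fd[lx - 1][ly - 1] + td[x][y]);
            fd[x][y] = d;
          }
        }
      }
    }
  }
  return td[n1][n2];
}
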