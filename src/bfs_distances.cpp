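#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs shortest path lengths on an unweighted undirected graph given as
// a 0/1 adjacency matrix. Unreachable pairs are returned as NA_integer_.
// Breadth-first search from every node; adjacency lists are built once.
// [[Rcpp::export]]
IntegerMatrix bfs_distance_matrix(IntegerMatrix adj) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency matrix must be square");

  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbr[i].push_back(j);

  IntegerMatrix dist(n, n);
  std::fill(dist.begin(), dist.end(), NA_INTEGER);
  std::vector<int> queue(n);

  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    dist(s, s) = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      int du = dist(u, s);
      for (int v : nbr[u]) {
        if (dist(v, s) == NA_INTEGER) {
          dist(v, s) = du + 1;
          queue[tail++] = v;
        }
      }
    }
  }
  return dist;
}
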