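#include <Rcpp.h>
#include <queue>
#include <vector>

// Meyer's marker-based flooding on a relief surface.
//
// Seeded pixels (labels > 0) initialise the priority queue; pixels are popped
// in order of increasing relief and claim the label of the front that pushed
// them. Ties on the relief value are broken by the row-major linear index
// (lowest index wins), then by insertion order, so the result is fully
// deterministic. 4-connectivity.

struct Node {
  double value;
  int idx;        // row-major linear index (r * ncol + c)
  long long ord;  // insertion counter
  int label;
};

struct NodeCompare {
  bool operator()(const Node &a, const Node &b) const {
    if (a.value != b.value) return a.value > b.value;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.ord > b.ord;
  }
};

// [[Rcpp::export]]
Rcpp::IntegerMatrix watershed_flood(Rcpp::NumericMatrix relief,
                                    Rcpp::IntegerMatrix seeds) {
  const int nr = relief.nrow(), nc = relief.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    Rcpp::stop("relief and seed label matrices must have identical shapes");

  Rcpp::IntegerMatrix labels(nr, nc);
  std::priority_queue<Node, std::vector<Node>, NodeCompare> queue;
  long long counter = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (seeds(r, c) > 0)
        queue.push(Node{relief(r, c), r * nc + c, counter++, seeds(r, c)});

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!queue.empty()) {
    Node node = queue.top();
    queue.pop();
    const int r = node.idx / nc, c = node.idx % nc;
    if (labels(r, c) != 0) continue;
    labels(r, c) = node.label;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) != 0) continue;
      queue.push(Node{relief(rr, cc), rr * nc + cc, counter++, node.label});
    }
  }
  return labels;
}
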