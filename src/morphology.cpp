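#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Centred sliding extremum with edge replication, O(n) independent of the
// window width (monotonic wedge / deque; same output as the van Herk
// block algorithm). Replicating edge samples is equivalent to clamping the
// window to the signal domain, which is what is done here.
// [[Rcpp::export]]
NumericVector sliding_extremum_cpp(NumericVector x, int k, bool take_max) {
  const int n = x.size();
  if (n == 0) stop("empty signal");
  if (k < 1 || k % 2 == 0) stop("window must be a positive odd sample count");
  const int r = (k - 1) / 2;
  NumericVector out(n);
  std::vector<int> dq(n);
  int head = 0, tail = 0, j = 0;
  for (int i = 0; i < n; ++i) {
    const int hi = std::min(n - 1, i + r);
    const int lo = std::max(0, i - r);
    while (j <= hi) {
      if (take_max) {
        while (tail > head && x[dq[tail - 1]] <= x[j]) --tail;
      } else {
        while (tail > head && x[dq[tail - 1]] >= x[j]) --tail;
      }
      dq[tail++] = j;
      ++j;
    }
    while (dq[head] < lo) ++head;
    out[i] = x[dq[head]];
  }
  return out;
}
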