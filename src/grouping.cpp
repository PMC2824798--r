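#include <Rcpp.h>
using namespace Rcpp;

// Contrast maximization over candidate contiguous partitions.
//
// sat: (n+1)x(n+1) summed-area table of the ordered similarity matrix.
// ends_list: one candidate per element, the sorted 1-based end indices of
// its boxes (the last entry is n). For each candidate, boxes smaller than
// min_box are first merged with the neighbor sharing the higher mean
// cross-similarity; the candidate maximizing D_in - D_out wins (first
// encountered on ties beyond 1e-12).

static inline double block_sum(const NumericMatrix& sat, int r0, int r1,
                               int c0, int c1) {
  // rows r0..r1, cols c0..c1, all 1-based inclusive
  return sat(r1, c1) - sat(r0 - 1, c1) - sat(r1, c0 - 1) + sat(r0 - 1, c0 - 1);
}

// [[Rcpp::export]]
List best_candidate_cpp(NumericMatrix sat, List ends_list, int min_box) {
  const int n = sat.nrow() - 1;
  const double tot = sat(n, n);

  double best_score = R_NegInf, best_din = 0, best_dout = 0;
  std::vector<int> best_start, best_end;

  for (int ci = 0; ci < ends_list.size(); ++ci) {
    IntegerVector ends0 = ends_list[ci];
    std::vector<int> start, end;
    start.reserve(ends0.size());
    end.reserve(ends0.size());
    int prev = 0;
    for (int b = 0; b < ends0.size(); ++b) {
      start.push_back(prev + 1);
      end.push_back(ends0[b]);
      prev = ends0[b];
    }

    // merge boxes below min_box into their more similar neighbor
    bool again = true;
    while (again && start.size() > 1) {
      again = false;
      for (size_t b = 0; b < start.size(); ++b) {
        if (end[b] - start[b] + 1 >= min_box) continue;
        double left = R_NegInf, right = R_NegInf;
        int len_b = end[b] - start[b] + 1;
        if (b > 0)
          left = block_sum(sat, start[b], end[b], start[b - 1], end[b - 1]) /
                 (double(len_b) * (end[b - 1] - start[b - 1] + 1));
        if (b + 1 < start.size())
          right = block_sum(sat, start[b], end[b], start[b + 1], end[b + 1]) /
                  (double(len_b) * (end[b + 1] - start[b + 1] + 1));
        if (left >= right) {
          end[b - 1] = end[b];
        } else {
          start[b + 1] = start[b];
        }
        start.erase(start.begin() + b);
        end.erase(end.begin() + b);
        again = true;
        break;
      }
    }

    double s_in = 0;
    double c_in = 0;
    for (size_t b = 0; b < start.size(); ++b) {
      s_in += block_sum(sat, start[b], end[b], start[b], end[b]);
      double len = end[b] - start[b] + 1;
      c_in += len * len;
    }
    double c_out = double(n) * n - c_in;
    double d_in = s_in / c_in;
    double d_out = c_out > 0 ? (tot - s_in) / c_out : 0.0;
    double score = d_in - d_out;
    if (score > best_score + 1e-12) {
      best_score = score;
      best_din = d_in;
      best_dout = d_out;
      best_start.assign(start.begin(), start.end());
      best_end.assign(end.begin(), end.end());
    }
  }

  return List::create(_["start"] = wrap(best_start), _["end"] = wrap(best_end),
                      _["d_in"] = best_din, _["d_out"] = best_dout,
                      _["contrast"] = best_score);
}
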