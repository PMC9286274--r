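#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Current-based LIF with a shared single-exponential synaptic kernel.
// eCounts/iCounts are input spike counts per integration step. The
// synaptic current jumps by wE (resp. -wI) per input spike and decays with
// tauSyn; the membrane is advanced with the exact exponential update
// treating the current as constant over one step.
// [[Rcpp::export]]
NumericVector lif_core(IntegerVector eCounts, IntegerVector iCounts,
                       double dt, double tauM, double tauSyn, double wE,
                       double wI, double vThresh, double vReset,
                       double vRest, double refractory) {
  int n = eCounts.size();
  if (iCounts.size() != n)
    stop("E and I count vectors must have equal length");
  double v = vRest, cur = 0.0;
  const double decV = std::exp(-dt / tauM);
  const double decS = std::exp(-dt / tauSyn);
  const int refSteps = (int)std::lround(refractory / dt);
  int refLeft = 0;
  std::vector<double> spikes;
  for (int k = 0; k < n; ++k) {
    cur = cur * decS + wE * eCounts[k] - wI * iCounts[k];
    if (refLeft > 0) {
      --refLeft;
      continue;
    }
    v = vRest + cur + (v - vRest - cur) * decV;
    if (v >= vThresh) {
      spikes.push_back((k + 1) * dt);
      v = vReset;
      refLeft = refSteps;
    }
  }
  return wrap(spikes);
}
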