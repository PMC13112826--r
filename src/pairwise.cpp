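#include <Rcpp.h>
using namespace Rcpp;

// Pairwise win/loss/tie counting for the hierarchical composite endpoint.
//
// Every notification-arm patient i is compared with every control-arm
// patient j.  With tau = min(censor_i, censor_j) the shared follow-up of the
// pair, an event counts only if it occurs by tau.  Valve intervention is
// compared first: i wins the valve level if i has a valve event at t_i <= tau
// and j has no valve event at or before t_i (symmetrically for j).  If the
// valve level is indeterminate (neither wins, including exact ties), the
// same rule is applied to the heart-team visit times; otherwise the pair is
// a tie.  Category coding: 1 = notified valve first (win), 2 = control valve
// first (loss), 3 = notified MHT first (win), 4 = control MHT first (loss),
// 5 = tie.
//
// Besides the totals, per-patient win/loss row and column sums are returned;
// these are the Hajek projections used by the closed-form large-sample
// variance of the log win ratio.
// [[Rcpp::export(name = ".pairwise_counts_cpp")]]
List pairwise_counts_cpp(NumericVector tv1, IntegerVector dv1,
                         NumericVector tm1, IntegerVector dm1,
                         NumericVector c1,
                         NumericVector tv0, IntegerVector dv0,
                         NumericVector tm0, IntegerVector dm0,
                         NumericVector c0) {
  const int n1 = tv1.size(), n0 = tv0.size();
  NumericVector rowWin(n1), rowLoss(n1), colWin(n0), colLoss(n0);
  NumericVector cat(5);
  for (int i = 0; i < n1; ++i) {
    const double tvi = tv1[i], tmi = tm1[i], ci = c1[i];
    const bool dvi = dv1[i] == 1, dmi = dm1[i] == 1;
    for (int j = 0; j < n0; ++j) {
      const double tau = ci < c0[j] ? ci : c0[j];
      const bool aV = dvi && tvi <= tau;
      const bool bV = (dv0[j] == 1) && tv0[j] <= tau;
      int category = 5;
      if (aV && (!bV || tv0[j] > tvi)) category = 1;
      else if (bV && (!aV || tvi > tv0[j])) category = 2;
      else {
        const bool aM = dmi && tmi <= tau;
        const bool bM = (dm0[j] == 1) && tm0[j] <= tau;
        if (aM && (!bM || tm0[j] > tmi)) category = 3;
        else if (bM && (!aM || tmi > tm0[j])) category = 4;
      }
      cat[category - 1] += 1.0;
      if (category == 1 || category == 3) {
        rowWin[i] += 1.0; colWin[j] += 1.0;
      } else if (category == 2 || category == 4) {
        rowLoss[i] += 1.0; colLoss[j] += 1.0;
      }
    }
  }
  const double wins = cat[0] + cat[2], losses = cat[1] + cat[3];
  return List::create(_["wins"] = wins, _["losses"] = losses,
                      _["ties"] = cat[4], _["categories"] = cat,
                      _["row_win"] = rowWin, _["row_loss"] = rowLoss,
                      _["col_win"] = colWin, _["col_loss"] = colLoss);
}
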