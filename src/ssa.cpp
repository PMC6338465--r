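#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of a mechano-chemical cycle whose rates
// depend on the enzyme position only through a precomputed propensity
// table. Rows of A index discrete enzyme positions (net ratchet steps,
// offset so row 1 is the most backward position reachable); columns index
// directed transitions. `from`/`to` are 1-based state labels (`to == 0`
// marks a dissociation/absorbing transition), `dpos` the position change
// in steps. With `clamp = true` the position is tracked but row 1 of A is
// used throughout (constant-force operation).
//
// Only position-changing events are recorded; the measured channels change
// only when the position does.
// [[Rcpp::export]]
List ssa_run_cpp(int n_states, IntegerVector from, IntegerVector to,
                 IntegerVector dpos, NumericMatrix A, int state0, int pos0,
                 double t_max, double max_events, bool clamp) {
  int n_trans = from.size();
  int n_pos = A.nrow();
  std::vector<std::vector<int> > by_state(n_states + 1);
  for (int i = 0; i < n_trans; ++i) by_state[from[i]].push_back(i);

  std::vector<double> ev_t;
  std::vector<int> ev_p;
  ev_t.reserve(1024);
  ev_p.reserve(1024);

  double t = 0.0;
  int state = state0, pos = pos0, code = 0;
  double n_ev = 0.0;

  for (;;) {
    int row = clamp ? 0 : pos - 1;
    const std::vector<int>& tr = by_state[state];
    double tot = 0.0;
    for (size_t k = 0; k < tr.size(); ++k) tot += A(row, tr[k]);
    if (tot <= 0.0) { code = 4; break; }  // kinetically trapped (e.g. ATP = 0 dead end)
    t += R::exp_rand() / tot;
    if (t >= t_max) { t = t_max; code = 0; break; }
    double r = R::unif_rand() * tot, acc = 0.0;
    int pick = tr.back();
    for (size_t k = 0; k < tr.size(); ++k) {
      acc += A(row, tr[k]);
      if (r <= acc) { pick = tr[k]; break; }
    }
    state = to[pick];
    if (state == 0) { code = 3; break; }  // dissociated
    if (dpos[pick] != 0) {
      pos += dpos[pick];
      ev_t.push_back(t);
      ev_p.push_back(pos);
      if (!clamp && (pos < 1 || pos > n_pos)) { code = 1; break; }  // table edge
    }
    if (++n_ev >= max_events) { code = 2; break; }
  }

  return List::create(_["time"] = ev_t, _["pos"] = ev_p, _["t_end"] = t,
                      _["state_end"] = state, _["code"] = code,
                      _["n_events"] = n_ev);
}
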