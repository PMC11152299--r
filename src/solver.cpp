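// Core numerical routines: active-set nodal analysis for the rectified
// (diode-like) resistive state network, in-place weight updates for the
// agent's hot loop, and a tabular Q-learning episode runner.
//
// All random draws go through R's RNG so that set.seed() in R controls
// every stochastic choice.

#include <RcppArmadillo.h>
#include <vector>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Solve node potentials of a directed, rectified resistive network by an
// active-set fixed point. Sources are pinned at `vsrc`; the implicit ground
// node is at potential 0 and couples to node i with conductance ground[i].
// An edge (i,j) conducts only while V_i > V_j; the set of conducting edges
// is re-classified after each linear solve until it is self-consistent.
//
// Only the undirected connected component containing the sources is solved;
// all other nodes are held at potential 0 with zero current.
// [[Rcpp::export(name = ".solve_rectified_cpp")]]
List solve_rectified_cpp(NumericMatrix W, NumericVector ground,
                         IntegerVector sources, double vsrc = 1.0,
                         double tol = 1e-10, int max_iter = 100,
                         double tie_tol = 1e-12) {
  const int n = W.nrow();
  std::vector<bool> is_source(n, false);
  for (int s : sources) is_source[s - 1] = true;  // 1-based from R

  // undirected BFS from the sources over all edges with positive conductance
  std::vector<int> comp;
  std::vector<int> local(n, -1);
  {
    std::vector<bool> seen(n, false);
    std::queue<int> q;
    for (int s : sources) {
      if (!seen[s - 1]) { seen[s - 1] = true; q.push(s - 1); }
    }
    while (!q.empty()) {
      int u = q.front(); q.pop();
      local[u] = (int)comp.size();
      comp.push_back(u);
      for (int v = 0; v < n; ++v) {
        if (!seen[v] && (W(u, v) > 0.0 || W(v, u) > 0.0)) {
          seen[v] = true; q.push(v);
        }
      }
    }
  }
  const int m = (int)comp.size();

  NumericVector V(n, 0.0);
  for (int s : sources) V[s - 1] = vsrc;

  // no grounded node in the component: no current can flow anywhere, and
  // every node reachable from the sources through forward-conducting
  // edges floats up to the source potential (nodes attached only through
  // reverse diodes stay at 0)
  bool any_ground = false;
  for (int p = 0; p < m; ++p)
    if (ground[comp[p]] > 0.0) { any_ground = true; break; }
  if (!any_ground) {
    std::vector<bool> fwd(n, false);
    std::queue<int> q;
    for (int s : sources) { fwd[s - 1] = true; q.push(s - 1); }
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v = 0; v < n; ++v)
        if (!fwd[v] && W(u, v) > 0.0) { fwd[v] = true; q.push(v); }
    }
    for (int v = 0; v < n; ++v) if (fwd[v]) V[v] = vsrc;
    return List::create(_["potentials"] = V, _["converged"] = true,
                        _["iterations"] = 0, _["component"] = comp,
                        _["grounded"] = false);
  }

  arma::mat Wl(m, m);
  arma::vec gl(m);
  for (int p = 0; p < m; ++p) gl[p] = ground[comp[p]];
  for (int q = 0; q < m; ++q) {      // column-major fill: W's column stays hot
    const int cq = comp[q];
    for (int p = 0; p < m; ++p) Wl(p, q) = W(comp[p], cq);
  }
  std::vector<bool> src_l(m, false);
  for (int p = 0; p < m; ++p) src_l[p] = is_source[comp[p]];

  // active(p,q): edge p->q currently classified as conducting. Start
  // with every existing edge active (a plain bidirectional network),
  // solve, then prune edges that would conduct against their diode.
  // Deliberately cold-started every call: warm-starting from a previous
  // decision's potentials lands on numerically different (equally valid)
  // fixed points whose near-tie edge powers systematically perturb
  // subgoal selection on weakly learned graphs.
  std::vector<bool> active(m * m, false);
  for (int p = 0; p < m; ++p)
    for (int q = 0; q < m; ++q) active[p * m + q] = Wl(p, q) > 0.0;

  arma::vec Vl(m, arma::fill::zeros);
  for (int p = 0; p < m; ++p) if (src_l[p]) Vl[p] = vsrc;
  arma::vec Vl_prev = Vl;

  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // nodes reachable from a source through currently-active edges
    // (treated undirected for solvability); the rest float at 0
    std::vector<bool> reach(m, false);
    {
      std::queue<int> q;
      for (int p = 0; p < m; ++p) if (src_l[p]) { reach[p] = true; q.push(p); }
      while (!q.empty()) {
        int u = q.front(); q.pop();
        for (int v = 0; v < m; ++v) {
          if (!reach[v] && (active[u * m + v] || active[v * m + u])) {
            reach[v] = true; q.push(v);
          }
        }
      }
    }

    std::vector<int> unk;                       // reachable non-source nodes
    std::vector<int> uidx(m, -1);
    for (int p = 0; p < m; ++p)
      if (reach[p] && !src_l[p]) { uidx[p] = (int)unk.size(); unk.push_back(p); }

    arma::vec Vnew(m, arma::fill::zeros);
    for (int p = 0; p < m; ++p) if (src_l[p]) Vnew[p] = vsrc;

    if (!unk.empty()) {
      const int k = (int)unk.size();
      arma::mat A(k, k, arma::fill::zeros);
      arma::vec b(k, arma::fill::zeros);
      for (int a_ = 0; a_ < k; ++a_) {
        int p = unk[a_];
        A(a_, a_) += gl[p];                      // conductance to ground
        for (int q = 0; q < m; ++q) {
          double c = 0.0;
          if (active[p * m + q]) c += Wl(p, q);
          if (active[q * m + p]) c += Wl(q, p);
          if (c == 0.0) continue;
          A(a_, a_) += c;
          if (src_l[q]) b[a_] += c * vsrc;
          else if (uidx[q] >= 0) A(a_, uidx[q]) -= c;
          // q unreachable: floats at 0, contributes nothing to b
        }
      }
      arma::vec x;
      bool ok = arma::solve(x, A, b, arma::solve_opts::likely_sympd +
                                         arma::solve_opts::fast);
      if (!ok) {  // nearly-singular active set: tiny ridge keeps it solvable
        A.diag() += 1e-12;
        ok = arma::solve(x, A, b);
        if (!ok) break;
      }
      for (int a_ = 0; a_ < k; ++a_) Vnew[unk[a_]] = x[a_];
    }

    // damped classification guard against active-set cycling
    arma::vec Vc = (it > 40) ? arma::vec(0.5 * (Vnew + Vl)) : Vnew;

    // hysteresis: an inactive edge activates only on a strictly positive
    // drop; an active edge deactivates only on a strictly negative drop.
    // An active edge at zero bias carries zero current and is harmless,
    // and keeping it prevents flip-flop cycling on equal-potential
    // plateaus.
    bool changed = false;
    for (int p = 0; p < m; ++p) {
      for (int q = 0; q < m; ++q) {
        if (Wl(p, q) <= 0.0) continue;
        double dv = Vc[p] - Vc[q];
        bool a_old = active[p * m + q];
        bool a_new = a_old ? (dv > -tie_tol) : (dv > tie_tol);
        if (a_new != a_old) { active[p * m + q] = a_new; changed = true; }
      }
    }
    Vl_prev = Vl;
    Vl = Vnew;
    // an unchanged classification means Vnew was solved under exactly the
    // set it implies: a genuine fixed point, no further solve needed
    if (!changed) { converged = true; break; }
  }

  for (int p = 0; p < m; ++p) V[comp[p]] = Vl[p];
  return List::create(_["potentials"] = V, _["converged"] = converged,
                      _["iterations"] = it, _["component"] = comp,
                      _["grounded"] = true);
}

// In-place entry assignment; avoids R's copy-on-write in the per-step
// learning loop (the matrices live in the agent's environment).
// [[Rcpp::export(name = ".set_entry_cpp")]]
void set_entry_cpp(NumericMatrix M, int i, int j, double v) {
  M(i - 1, j - 1) = v;
}

// [[Rcpp::export(name = ".set_flat_cpp")]]
void set_flat_cpp(NumericVector x, double idx, double v) {
  x[(R_xlen_t)(idx - 1)] = v;
}

// [[Rcpp::export(name = ".get_flat_cpp")]]
double get_flat_cpp(NumericVector x, double idx) {
  return x[(R_xlen_t)(idx - 1)];
}

static int draw_action(const NumericMatrix &Q, int s, int n_avail,
                       double epsilon, bool tie_first) {
  if (unif_rand() < epsilon)
    return (int)(unif_rand() * n_avail) % n_avail;
  double best = R_NegInf;
  int n_tie = 0, pick = 0;
  for (int a = 0; a < n_avail; ++a) {
    double v = Q(s, a);
    if (v > best) { best = v; n_tie = 1; pick = a; }
    else if (v == best) {
      ++n_tie;
      if (!tie_first && unif_rand() < 1.0 / n_tie) pick = a;  // reservoir
    }
  }
  return pick;
}

// One tabular Q-learning episode over precomputed transition tables
// (0-based `nxt`), updating Q in place. Returns per-episode accounting.
// [[Rcpp::export(name = ".qlearn_episode_cpp")]]
List qlearn_episode_cpp(NumericMatrix Q, IntegerMatrix nxt,
                        NumericMatrix reward, LogicalMatrix done,
                        LogicalMatrix illegal, IntegerVector n_avail,
                        int s0, int step_cap, double lr, double gamma,
                        double epsilon, bool tie_first) {
  int s = s0;
  int steps = 0, n_illegal = 0;
  double train_reward = 0.0;
  bool reached = false;
  while (steps < step_cap) {
    int a = draw_action(Q, s, n_avail[s], epsilon, tie_first);
    int s2 = nxt(s, a);
    double r = reward(s, a);
    bool d = done(s, a);
    if (illegal(s, a)) ++n_illegal;
    double target = r;
    if (!d) {
      double mx = Q(s2, 0);
      for (int k = 1; k < n_avail[s2]; ++k) if (Q(s2, k) > mx) mx = Q(s2, k);
      target += gamma * mx;
    }
    Q(s, a) += lr * (target - Q(s, a));
    train_reward += r;
    ++steps;
    s = s2;
    if (d) { reached = true; break; }
  }
  return List::create(_["steps"] = steps, _["end_state"] = s + 1,
                      _["train_reward"] = train_reward,
                      _["n_illegal"] = n_illegal, _["reached"] = reached,
                      _["cap_hit"] = !reached);
}

// Greedy (epsilon = 0, deterministic-tie) policy rollout used by the
// dense-reward sanity check.
// [[Rcpp::export(name = ".greedy_episode_cpp")]]
List greedy_episode_cpp(NumericMatrix Q, IntegerMatrix nxt,
                        NumericMatrix reward, LogicalMatrix done,
                        IntegerVector n_avail, int s0, int step_cap) {
  int s = s0, steps = 0;
  double total = 0.0;
  bool reached = false;
  while (steps < step_cap) {
    int a = 0;
    double best = Q(s, 0);
    for (int k = 1; k < n_avail[s]; ++k)
      if (Q(s, k) > best) { best = Q(s, k); a = k; }
    total += reward(s, a);
    bool d = done(s, a);
    s = nxt(s, a);
    ++steps;
    if (d) { reached = true; break; }
  }
  return List::create(_["steps"] = steps, _["total_reward"] = total,
                      _["reached"] = reached);
}

// Latent-learning random walk over a location transition table: repeatedly
// take uniform random actions and apply the first-order conductance update
// W[i,j] += dt*alpha*(w1max - W[i,j]) on every actual state change.
// Used by the graph-recovery demonstrations; W is updated in place.
// [[Rcpp::export(name = ".random_walk_learn_cpp")]]
void random_walk_learn_cpp(NumericMatrix W, IntegerMatrix nxt, int s0,
                           int steps, double dt, double alpha, double w1max) {
  int s = s0;
  const int n_a = nxt.ncol();
  const double rate = dt * alpha;
  for (int t = 0; t < steps; ++t) {
    int a = (int)(unif_rand() * n_a) % n_a;
    int s2 = nxt(s, a);
    if (s2 != s) W(s, s2) += rate * (w1max - W(s, s2));
    s = s2;
  }
}
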