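// Geometry kernels for dense surface correspondence: exact closest point on
// a triangle mesh, brute-force kNN for candidate generation, and the
// annealed discrete relaxation of the MRF correspondence energy.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, ch. 5). Writes the footpoint into out[3] and barycentric
// coordinates (w.r.t. a,b,c) into bary[3].
static void closest_pt_triangle(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// Globally nearest point on the mesh for each query; ties broken by lowest
// face index (faces are scanned in ascending order and only a strictly
// smaller distance replaces the incumbent).
// [[Rcpp::export]]
NumericMatrix closest_point_cpp(NumericMatrix queries, NumericMatrix V,
                                IntegerMatrix F) {
  int nq = queries.nrow(), nf = F.nrow();
  NumericMatrix out(nq, 8);  // x,y,z,face(1-based),b0,b1,b2,dist
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    double best = R_PosInf, bpt[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    int bface = -1;
    for (int f = 0; f < nf; ++f) {
      const double *a = &vx[3 * F(f, 0)];
      const double *b = &vx[3 * F(f, 1)];
      const double *c = &vx[3 * F(f, 2)];
      double pt[3], bar[3];
      closest_pt_triangle(p, a, b, c, pt, bar);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) d2 += (pt[i] - p[i]) * (pt[i] - p[i]);
      if (d2 < best) {
        best = d2;
        for (int i = 0; i < 3; ++i) { bpt[i] = pt[i]; bb[i] = bar[i]; }
        bface = f;
      }
    }
    out(q, 0) = bpt[0]; out(q, 1) = bpt[1]; out(q, 2) = bpt[2];
    out(q, 3) = bface + 1;
    out(q, 4) = bb[0]; out(q, 5) = bb[1]; out(q, 6) = bb[2];
    out(q, 7) = std::sqrt(best);
  }
  return out;
}

// k nearest rows of `pool` for each row of `queries` (1-based indices).
// [[Rcpp::export]]
IntegerMatrix knn_cpp(NumericMatrix queries, NumericMatrix pool, int k) {
  int nq = queries.nrow(), np = pool.nrow();
  if (k > np) k = np;
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int>> d(np);
  for (int q = 0; q < nq; ++q) {
    double x = queries(q, 0), y = queries(q, 1), z = queries(q, 2);
    for (int i = 0; i < np; ++i) {
      double dx = pool(i, 0) - x, dy = pool(i, 1) - y, dz = pool(i, 2) - z;
      d[i] = {dx * dx + dy * dy + dz * dz, i};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int i = 0; i < k; ++i) out(q, i) = d[i].second + 1;
  }
  return out;
}

// Annealed iterated conditional updates of the discrete MRF labelling.
// cand_xyz holds the candidate footpoints of vertex v in rows v*C .. v*C+C-1;
// the energy is
//   prior_weight * sum_edges ||d_u - d_v||^2 + sum_v obs(v, label_v)
// with d_v = candidate - warped_v. Vertices are visited in a seeded random
// order; a random alternative label is proposed and accepted by the
// Metropolis rule at a geometrically cooled temperature. The best labelling
// seen (including the initial one) is returned, so the reported energy never
// exceeds the initial energy.
// [[Rcpp::export]]
List mrf_sweeps_cpp(NumericMatrix cand_xyz, NumericMatrix cand_obs,
                    NumericMatrix warped, IntegerMatrix edges,
                    double prior_weight, IntegerVector init_idx,
                    int max_sweeps, double temp0, double cooling, int seed) {
  int nv = warped.nrow();
  int C = cand_obs.ncol();
  int ne = edges.nrow();
  std::vector<std::vector<int>> adj(nv);
  for (int e = 0; e < ne; ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  // current displacement per vertex
  std::vector<double> disp(nv * 3);
  std::vector<int> cur(nv);
  for (int v = 0; v < nv; ++v) {
    cur[v] = init_idx[v];
    for (int j = 0; j < 3; ++j)
      disp[3 * v + j] = cand_xyz(v * C + cur[v], j) - warped(v, j);
  }
  auto pair_energy = [&](int v, const double *dv) {
    double s = 0.0;
    for (int u : adj[v]) {
      double acc = 0.0;
      for (int j = 0; j < 3; ++j) {
        double df = dv[j] - disp[3 * u + j];
        acc += df * df;
      }
      s += acc;
    }
    return s;
  };
  double energy = 0.0;
  for (int v = 0; v < nv; ++v) energy += cand_obs(v, cur[v]);
  for (int e = 0; e < ne; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    double acc = 0.0;
    for (int j = 0; j < 3; ++j) {
      double df = disp[3 * u + j] - disp[3 * v + j];
      acc += df * df;
    }
    energy += prior_weight * acc;
  }
  double init_energy = energy;
  double best_energy = energy;
  std::vector<int> best = cur;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> order(nv);
  for (int v = 0; v < nv; ++v) order[v] = v;
  NumericVector trace(max_sweeps, NA_REAL);
  int sweeps_done = 0;
  double temp = temp0;
  std::vector<double> elocal(C), prob(C);
  for (int sweep = 0; sweep < max_sweeps && C > 1; ++sweep) {
    std::shuffle(order.begin(), order.end(), rng);
    int accepted = 0;
    for (int vi = 0; vi < nv; ++vi) {
      int v = order[vi];
      // local energy of every candidate label given the neighbours
      double emin = R_PosInf;
      for (int c = 0; c < C; ++c) {
        double d[3];
        for (int j = 0; j < 3; ++j)
          d[j] = cand_xyz(v * C + c, j) - warped(v, j);
        elocal[c] = cand_obs(v, c) + prior_weight * pair_energy(v, d);
        if (elocal[c] < emin) emin = elocal[c];
      }
      int pick;
      if (temp > 1e-12) {
        // annealed heat-bath update (Gibbs sample at temperature `temp`)
        double tot = 0.0;
        for (int c = 0; c < C; ++c) {
          prob[c] = std::exp(-(elocal[c] - emin) / temp);
          tot += prob[c];
        }
        double r = unif(rng) * tot, acc = 0.0;
        pick = C - 1;
        for (int c = 0; c < C; ++c) {
          acc += prob[c];
          if (r <= acc) { pick = c; break; }
        }
      } else {
        // frozen: iterated conditional modes (first minimizer wins)
        pick = 0;
        for (int c = 1; c < C; ++c)
          if (elocal[c] < elocal[pick]) pick = c;
      }
      if (pick != cur[v]) {
        double dE = elocal[pick] - elocal[cur[v]];
        cur[v] = pick;
        for (int j = 0; j < 3; ++j)
          disp[3 * v + j] = cand_xyz(v * C + pick, j) - warped(v, j);
        energy += dE;
        ++accepted;
        if (energy < best_energy) {
          best_energy = energy;
          best = cur;
        }
      }
    }
    trace[sweep] = energy;
    sweeps_done = sweep + 1;
    temp *= cooling;
    if (accepted == 0) break;
  }
  IntegerVector assign(nv);
  for (int v = 0; v < nv; ++v) assign[v] = best[v] + 1;  // 1-based
  NumericVector tr_out =
      sweeps_done > 0 ? NumericVector(trace[Rcpp::Range(0, sweeps_done - 1)])
                      : NumericVector(0);
  return List::create(_["assignment"] = assign,
                      _["energy"] = best_energy,
                      _["init_energy"] = init_energy,
                      _["trace"] = tr_out,
                      _["sweeps"] = sweeps_done);
}
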