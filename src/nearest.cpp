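#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact closest point on triangle (a,b,c) to p, after Ericson,
// "Real-Time Collision Detection" 5.1.5. Returns squared distance and
// fills cp (closest point) and bary (barycentric coords w.r.t. a,b,c).
// Clamped regions produce exact 0/1 barycentric coordinates, which the
// caller relies on for edge/vertex classification.
static double closest_on_triangle(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *cp, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) cp[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) cp[k] = b[k];
      bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) cp[k] = a[k] + v * ab[k];
        bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
      } else {
        double cpv[3];
        for (int k = 0; k < 3; ++k) cpv[k] = p[k] - c[k];
        double d5 = ab[0] * cpv[0] + ab[1] * cpv[1] + ab[2] * cpv[2];
        double d6 = ac[0] * cpv[0] + ac[1] * cpv[1] + ac[2] * cpv[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) cp[k] = c[k];
          bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) cp[k] = a[k] + w * ac[k];
            bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k)
                cp[k] = b[k] + w * (c[k] - b[k]);
              bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k)
                cp[k] = a[k] + ab[k] * v + ac[k] * w;
              bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - cp[0], dy = p[1] - cp[1], dz = p[2] - cp[2];
  return dx * dx + dy * dy + dz * dz;
}

struct Candidate {
  double d;
  double cp[3];
  int tri;
};

// Batch exact nearest-point-on-surface queries.
//
// Triangles are visited in ascending order of the provable lower bound
// max(0, |q - centroid| - circumradius); the scan stops once the bound
// exceeds the best distance plus the tie allowance, which guarantees the
// result equals an exhaustive scan and that every tie candidate is seen.
//
// F is 0-based. edge_boundary(t, k) flags the edge (F(t,k), F(t,(k+1)%3));
// vert_boundary flags vertices incident to a boundary edge.
// [[Rcpp::export]]
List cpp_nearest_batch(NumericMatrix V, IntegerMatrix F,
                       NumericMatrix centroids, NumericVector radii,
                       LogicalMatrix edge_boundary,
                       LogicalVector vert_boundary,
                       NumericMatrix Q, double tie_rel, double tie_sep) {
  const int nt = F.nrow(), nq = Q.nrow(), nv = V.nrow();
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  std::vector<double> cx(nt), cy(nt), cz(nt), rr(nt);
  for (int t = 0; t < nt; ++t) {
    cx[t] = centroids(t, 0); cy[t] = centroids(t, 1);
    cz[t] = centroids(t, 2); rr[t] = radii[t];
  }

  NumericMatrix closest(nq, 3), bary_out(nq, 3);
  NumericVector dist_out(nq);
  IntegerVector tri_out(nq);
  LogicalVector uniq_out(nq), bnd_out(nq);

  std::vector<double> lb(nt);
  std::vector<int> order(nt);
  std::vector<Candidate> cands;
  const double tie_abs = 1e-12;
  const int kSeed = nt < 32 ? nt : 32;

  for (int q = 0; q < nq; ++q) {
    double p[3] = { Q(q, 0), Q(q, 1), Q(q, 2) };
    for (int t = 0; t < nt; ++t) {
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rr[t];
      lb[t] = dc > 0.0 ? dc : 0.0;
      order[t] = t;
    }
    // seed the best distance from the triangles with the smallest lower
    // bounds, then sweep the rest with the bound as a filter; exactness
    // is preserved because every triangle whose bound does not exceed
    // the (tie-allowing) threshold is still examined exactly
    std::nth_element(order.begin(), order.begin() + (kSeed - 1),
                     order.end(),
                     [&lb](int i, int j) { return lb[i] < lb[j]; });

    double best = R_PosInf;
    double best_cp[3] = { 0, 0, 0 }, best_bary[3] = { 0, 0, 0 };
    int best_tri = -1;
    cands.clear();

    auto examine = [&](int t) {
      int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
      double a[3] = { vx[ia], vy[ia], vz[ia] };
      double b[3] = { vx[ib], vy[ib], vz[ib] };
      double c[3] = { vx[ic], vy[ic], vz[ic] };
      double cp[3], bc[3];
      double d2 = closest_on_triangle(p, a, b, c, cp, bc);
      double d = std::sqrt(d2);
      if (d < best) {
        best = d;
        best_tri = t;
        for (int k = 0; k < 3; ++k) {
          best_cp[k] = cp[k];
          best_bary[k] = bc[k];
        }
      }
      if (d <= best * (1.0 + tie_rel) + tie_abs) {
        Candidate cand;
        cand.d = d;
        cand.tri = t;
        for (int k = 0; k < 3; ++k) cand.cp[k] = cp[k];
        cands.push_back(cand);
      }
    };

    for (int s = 0; s < kSeed; ++s) examine(order[s]);
    if (kSeed < nt) {
      for (int s = kSeed; s < nt; ++s) {
        int t = order[s];
        if (lb[t] <= best * (1.0 + tie_rel) + tie_abs) examine(t);
      }
    }

    // tie: another triangle attains (relatively) the same minimum at a
    // genuinely different surface point
    bool unique = true;
    double thr = best * (1.0 + tie_rel) + tie_abs;
    for (size_t i = 0; i < cands.size() && unique; ++i) {
      if (cands[i].tri == best_tri) continue;
      if (cands[i].d > thr) continue;
      double dx = cands[i].cp[0] - best_cp[0];
      double dy = cands[i].cp[1] - best_cp[1];
      double dz = cands[i].cp[2] - best_cp[2];
      if (dx * dx + dy * dy + dz * dz > tie_sep * tie_sep) unique = false;
    }

    // boundary: closest point on a boundary edge or at a boundary vertex
    bool on_bnd = false;
    const double eps_b = 1e-9;
    int nzero = 0, zero_at = -1, nonzero_at = -1;
    for (int k = 0; k < 3; ++k) {
      if (best_bary[k] <= eps_b) {
        ++nzero;
        zero_at = k;
      } else {
        nonzero_at = k;
      }
    }
    if (nzero == 1) {
      int edge = (zero_at + 1) % 3;  // edge opposite the zero coordinate
      on_bnd = edge_boundary(best_tri, edge);
    } else if (nzero == 2) {
      on_bnd = vert_boundary[F(best_tri, nonzero_at)];
    }

    closest(q, 0) = best_cp[0];
    closest(q, 1) = best_cp[1];
    closest(q, 2) = best_cp[2];
    dist_out[q] = best;
    tri_out[q] = best_tri + 1;  // 1-based for R
    bary_out(q, 0) = best_bary[0];
    bary_out(q, 1) = best_bary[1];
    bary_out(q, 2) = best_bary[2];
    uniq_out[q] = unique;
    bnd_out[q] = on_bnd;
  }

  return List::create(_["closest"] = closest, _["distance"] = dist_out,
                      _["triangle"] = tri_out, _["bary"] = bary_out,
                      _["unique"] = uniq_out, _["on_boundary"] = bnd_out);
}
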