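#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Structured-coalescent machinery shared by the isolation-with-migration
// simulator and the HKA null generator.
//
// Time is measured in units of 2N generations of the reference deme (the
// deme whose relative size is 1), so the coalescence rate for k lineages in
// a deme of relative size r is k(k-1)/(2r), and a locus-wide mutation rate
// of theta/2 per lineage per unit time gives E[pairwise differences] = theta
// for a panmictic pair.

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector tip_deme,     // 0-based deme per tip
                       NumericVector rel_size,     // relative size per deme
                       NumericMatrix mig,          // mig(d,e): backwards rate d -> e per lineage
                       NumericVector merge_time,   // nondecreasing
                       IntegerVector merge_from,   // 0-based
                       IntegerVector merge_into) {
  const int n = tip_deme.size();
  const int ndeme = rel_size.size();
  if (n < 2) stop("need at least 2 tips");
  for (int d = 0; d < ndeme; ++d)
    if (rel_size[d] <= 0) stop("relative deme sizes must be positive");

  const int nnode = 2 * n - 1;
  IntegerVector parent(nnode, NA_INTEGER);
  NumericVector node_time(nnode, 0.0);
  IntegerVector node_deme(nnode, NA_INTEGER);

  std::vector<int> lin_node, lin_deme;     // active lineages
  lin_node.reserve(n); lin_deme.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (tip_deme[i] < 0 || tip_deme[i] >= ndeme) stop("tip deme out of range");
    lin_node.push_back(i);
    lin_deme.push_back(tip_deme[i]);
    node_deme[i] = tip_deme[i];
  }

  double t = 0.0;
  int next_node = n;
  int jm = 0;
  const int nmerge = merge_time.size();
  std::vector<int> count(ndeme);
  std::vector<double> wcoal(ndeme), wmig(ndeme * ndeme);

  while ((int)lin_node.size() > 1) {
    // deme occupancy
    std::fill(count.begin(), count.end(), 0);
    for (size_t i = 0; i < lin_deme.size(); ++i) count[lin_deme[i]]++;

    double total = 0.0;
    for (int d = 0; d < ndeme; ++d) {
      wcoal[d] = count[d] * (count[d] - 1) / (2.0 * rel_size[d]);
      total += wcoal[d];
    }
    for (int d = 0; d < ndeme; ++d)
      for (int e = 0; e < ndeme; ++e) {
        double w = (d == e) ? 0.0 : count[d] * mig(d, e);
        wmig[d * ndeme + e] = w;
        total += w;
      }

    if (total <= 0.0) {
      if (jm >= nmerge)
        stop("non-terminating configuration: no coalescence, migration or deme merge possible");
      t = merge_time[jm];
      while (jm < nmerge && merge_time[jm] <= t) {
        for (size_t i = 0; i < lin_deme.size(); ++i)
          if (lin_deme[i] == merge_from[jm]) lin_deme[i] = merge_into[jm];
        ++jm;
      }
      continue;
    }

    double dt = exp_rand() / total;
    if (jm < nmerge && t + dt >= merge_time[jm]) {
      t = merge_time[jm];
      while (jm < nmerge && merge_time[jm] <= t) {
        for (size_t i = 0; i < lin_deme.size(); ++i)
          if (lin_deme[i] == merge_from[jm]) lin_deme[i] = merge_into[jm];
        ++jm;
      }
      continue;
    }
    t += dt;

    // pick event
    double u = unif_rand() * total, acc = 0.0;
    int ev_deme = -1; bool is_coal = false; int mig_from = -1, mig_to = -1;
    for (int d = 0; d < ndeme && ev_deme < 0; ++d) {
      acc += wcoal[d];
      if (u <= acc) { ev_deme = d; is_coal = true; }
    }
    if (ev_deme < 0) {
      for (int d = 0; d < ndeme && ev_deme < 0; ++d)
        for (int e = 0; e < ndeme; ++e) {
          acc += wmig[d * ndeme + e];
          if (u <= acc) { ev_deme = d; mig_from = d; mig_to = e; break; }
        }
      if (ev_deme < 0) { is_coal = true; for (int d = ndeme - 1; d >= 0; --d) if (wcoal[d] > 0) { ev_deme = d; break; } }
    }

    if (is_coal) {
      // choose two distinct lineages in ev_deme
      int k = count[ev_deme];
      int a = (int)(unif_rand() * k), b;
      do { b = (int)(unif_rand() * k); } while (b == a);
      int ia = -1, ib = -1, seen = 0;
      for (size_t i = 0; i < lin_deme.size(); ++i) {
        if (lin_deme[i] == ev_deme) {
          if (seen == a) ia = (int)i;
          if (seen == b) ib = (int)i;
          ++seen;
        }
      }
      int v = next_node++;
      node_time[v] = t;
      node_deme[v] = ev_deme;
      parent[lin_node[ia]] = v + 1;  // 1-based for R
      parent[lin_node[ib]] = v + 1;
      // replace ia by new node, drop ib
      lin_node[ia] = v;
      lin_node.erase(lin_node.begin() + ib);
      lin_deme.erase(lin_deme.begin() + ib);
    } else {
      int k = count[mig_from];
      int a = (int)(unif_rand() * k), seen = 0;
      for (size_t i = 0; i < lin_deme.size(); ++i) {
        if (lin_deme[i] == mig_from) {
          if (seen == a) { lin_deme[i] = mig_to; break; }
          ++seen;
        }
      }
    }
  }

  return List::create(_["parent"] = parent,
                      _["time"] = node_time,
                      _["node_deme"] = node_deme,
                      _["n_tips"] = n);
}

// Poisson mutations on branches; returns per-mutation branch (child node,
// 1-based) and the tip-by-mutation 0/1 incidence matrix.
// [[Rcpp::export(name = ".drop_mutations_cpp")]]
List drop_mutations_cpp(IntegerVector parent, NumericVector node_time,
                        int n_tips, double theta) {
  const int nnode = parent.size();
  std::vector<double> len(nnode, 0.0);
  double total = 0.0;
  for (int i = 0; i < nnode; ++i) {
    if (parent[i] != NA_INTEGER) {
      len[i] = node_time[parent[i] - 1] - node_time[i];
      total += len[i];
    }
  }
  int nmut = (int)R::rpois(theta / 2.0 * total);

  // descendant tip lists (internal nodes are created in increasing time
  // order, so children always precede parents)
  std::vector< std::vector<int> > tips(nnode);
  for (int i = 0; i < n_tips; ++i) tips[i].push_back(i);
  for (int i = 0; i < nnode; ++i) {
    if (parent[i] != NA_INTEGER) {
      std::vector<int> &dst = tips[parent[i] - 1];
      dst.insert(dst.end(), tips[i].begin(), tips[i].end());
    }
  }

  std::vector<double> cum(nnode);
  double acc = 0.0;
  for (int i = 0; i < nnode; ++i) { acc += len[i]; cum[i] = acc; }

  IntegerVector mut_node(nmut);
  IntegerMatrix geno(n_tips, nmut);
  for (int m = 0; m < nmut; ++m) {
    double u = unif_rand() * total;
    int br = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (br >= nnode) br = nnode - 1;
    mut_node[m] = br + 1;
    for (size_t j = 0; j < tips[br].size(); ++j) geno(tips[br][j], m) = 1;
  }

  return List::create(_["node"] = mut_node,
                      _["geno"] = geno,
                      _["total_length"] = total);
}

// Lean batch simulator for the HKA null: two species of relative sizes 1 and
// f splitting at time T (ancestral relative size (1+f)/2), locus-wise theta
// already inheritance-scaled.  Returns segregating sites within each species
// and the mean pairwise between-species divergence, per locus and replicate.
// [[Rcpp::export(name = ".hka_null_counts_cpp")]]
List hka_null_counts_cpp(int nsims, IntegerVector n1, IntegerVector n2,
                         NumericVector phi, double T, double f) {
  const int nloci = n1.size();
  NumericMatrix S1(nloci, nsims), S2(nloci, nsims), D(nloci, nsims);
  const double ranc = (1.0 + f) / 2.0;

  for (int s = 0; s < nsims; ++s) {
    for (int l = 0; l < nloci; ++l) {
      const int m1 = n1[l], m2 = n2[l];
      const int ntot = m1 + m2;
      // lineage state: d1 = tip descendants in species 1, d2 in species 2
      std::vector<int> d1, d2, deme;
      d1.reserve(ntot); d2.reserve(ntot); deme.reserve(ntot);
      for (int i = 0; i < m1; ++i) { d1.push_back(1); d2.push_back(0); deme.push_back(0); }
      for (int i = 0; i < m2; ++i) { d1.push_back(0); d2.push_back(1); deme.push_back(1); }
      // branch records: length and (d1, d2)
      std::vector<double> blen; std::vector<int> bd1, bd2;
      std::vector<double> born(ntot, 0.0);

      double t = 0.0;
      bool merged = (T <= 0.0);
      int k = ntot;
      std::vector<int> idx;
      while (k > 1) {
        int k0 = 0, k1 = 0;
        if (!merged) {
          for (int i = 0; i < k; ++i) (deme[i] == 0 ? k0 : k1)++;
        }
        double rate = merged ? k * (k - 1) / (2.0 * ranc)
                             : k0 * (k0 - 1) / 2.0 + k1 * (k1 - 1) / (2.0 * f);
        double dt = (rate > 0) ? exp_rand() / rate : R_PosInf;
        if (!merged && t + dt >= T) {
          t = T; merged = true;
          continue;
        }
        t += dt;
        // choose deme for the coalescence
        int dsel;
        if (merged) dsel = -1;
        else {
          double w0 = k0 * (k0 - 1) / 2.0;
          dsel = (unif_rand() * rate <= w0) ? 0 : 1;
        }
        // pick two distinct lineages (within dsel if not merged)
        idx.clear();
        for (int i = 0; i < k; ++i)
          if (merged || deme[i] == dsel) idx.push_back(i);
        int kk = (int)idx.size();
        int a = (int)(unif_rand() * kk), b;
        do { b = (int)(unif_rand() * kk); } while (b == a);
        int ia = idx[a], ib = idx[b];
        // close both branches
        blen.push_back(t - born[ia]); bd1.push_back(d1[ia]); bd2.push_back(d2[ia]);
        blen.push_back(t - born[ib]); bd1.push_back(d1[ib]); bd2.push_back(d2[ib]);
        d1[ia] += d1[ib]; d2[ia] += d2[ib];
        born[ia] = t;
        d1.erase(d1.begin() + ib); d2.erase(d2.begin() + ib);
        deme.erase(deme.begin() + ib); born.erase(born.begin() + ib);
        --k;
      }

      double total = 0.0;
      for (size_t i = 0; i < blen.size(); ++i) total += blen[i];
      int nmut = (int)R::rpois(phi[l] / 2.0 * total);
      double s1 = 0, s2 = 0, dxy = 0;
      if (nmut > 0) {
        std::vector<double> cum(blen.size());
        double acc = 0.0;
        for (size_t i = 0; i < blen.size(); ++i) { acc += blen[i]; cum[i] = acc; }
        for (int m = 0; m < nmut; ++m) {
          double u = unif_rand() * total;
          int br = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
          if (br >= (int)blen.size()) br = (int)blen.size() - 1;
          int a1c = bd1[br], a2c = bd2[br];
          if (a1c > 0 && a1c < m1) s1 += 1;
          if (a2c > 0 && a2c < m2) s2 += 1;
          dxy += (double)(a1c * (m2 - a2c) + a2c * (m1 - a1c)) / ((double)m1 * m2);
        }
      }
      S1(l, s) = s1; S2(l, s) = s2; D(l, s) = dxy;
    }
  }
  return List::create(_["S1"] = S1, _["S2"] = S2, _["D"] = D);
}
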