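// Pedigree-conditioned gene dropping, run backward in time.
//
// Forward-simulated pedigrees fix who the parents of every individual are;
// the only genetic randomness left is meiosis (crossovers and which
// parental haplotype each locus is copied from).  Tracing sampled
// haplotypes backward through the pedigree is therefore an exact
// realisation of segment transmission: a lineage sitting in haplotype h of
// individual i jumps, at i's birth year, into one of the two haplotypes of
// the corresponding parent, with the choice at each locus determined by a
// shared per-meiosis crossover pattern.  Two lineages of the same locus
// that land in the same parental haplotype have coalesced.  Lineages that
// reach founder haplotypes are left "open" and are completed later by a
// coalescent process (see cpp_recapitate).
//
// Loci are point loci (windows short enough that within-window
// recombination is negligible); loci on the same chromosome share meioses
// and are therefore correctly linked through the pedigree epoch.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_trace_ancestry(IntegerVector mother, IntegerVector father,
                        IntegerVector birth, IntegerVector sample_ids,
                        NumericVector locus_pos, double chrom_len,
                        double rec_rate, int duration) {
  const int n_ind = mother.size();
  const int n_loc = locus_pos.size();
  const int n_samp = sample_ids.size();
  const int n_leaf = 2 * n_samp;

  // per-haplotype pending records, appended as lineages arrive, consumed
  // when the haplotype's owner is processed.  meioses counts the
  // transmissions accumulated on the lineage's open edge (per locus).
  struct Rec {
    int locus, node, meioses;
    bool operator<(const Rec& o) const {
      return locus < o.locus || (locus == o.locus && node < o.node);
    }
  };
  std::vector<std::vector<Rec>> content(2 * (size_t)n_ind);
  std::vector<uint8_t> processed(2 * (size_t)n_ind, 0);
  std::vector<std::vector<int64_t>> bucket(duration + 1);

  auto arrive = [&](int64_t hap, int locus, int node, int meioses) {
    if (content[hap].empty()) {
      int ind = (int)(hap >> 1);
      int by = birth[ind];
      if (by > duration) by = duration;
      bucket[by].push_back(hap);
    }
    content[hap].push_back(Rec{locus, node, meioses});
  };

  // seed the leaves: sample i contributes leaf nodes 2i (maternal hap) and
  // 2i+1 (paternal hap) at every locus
  for (int i = 0; i < n_samp; ++i) {
    int ind = sample_ids[i] - 1;
    for (int h = 0; h < 2; ++h) {
      int64_t hap = 2 * (int64_t)ind + h;
      for (int l = 0; l < n_loc; ++l) arrive(hap, l, 2 * i + h, 0);
    }
  }

  int next_node = n_leaf;

  // edge output (pedigree epoch): child, parent (-1 = still open), meioses
  std::vector<int> e_child, e_parent, e_meio, e_locus, e_year;
  // open lineage output (o_hap: founder haplotype the lineage sits in)
  std::vector<int> o_locus, o_node, o_hap;

  std::vector<double> bp;  // crossover breakpoints, reused

  for (int y = 0; y <= duration; ++y) {
    for (size_t bi = 0; bi < bucket[y].size(); ++bi) {
      int64_t hap = bucket[y][bi];
      std::vector<Rec>& recs = content[hap];
      if (recs.empty()) continue;
      if (processed[hap]) stop("internal error: haplotype processed twice");
      processed[hap] = 1;
      std::sort(recs.begin(), recs.end());
      // coalesce multiple arrivals at the same locus
      size_t w = 0;
      for (size_t r = 0; r < recs.size(); ++r) {
        if (w > 0 && recs[w - 1].locus == recs[r].locus) {
          int c = next_node++;
          e_child.push_back(recs[w - 1].node); e_parent.push_back(c);
          e_meio.push_back(recs[w - 1].meioses);
          e_locus.push_back(recs[r].locus); e_year.push_back(y);
          e_child.push_back(recs[r].node); e_parent.push_back(c);
          e_meio.push_back(recs[r].meioses);
          e_locus.push_back(recs[r].locus); e_year.push_back(y);
          recs[w - 1].node = c;
          recs[w - 1].meioses = 0;
        } else {
          recs[w++] = recs[r];
        }
      }
      recs.resize(w);

      int ind = (int)(hap >> 1);
      int par = (hap & 1) == 0 ? mother[ind] : father[ind];
      if (par == 0) {
        // founder haplotype: lineages stay open for the coalescent stage
        for (size_t r = 0; r < recs.size(); ++r) {
          e_child.push_back(recs[r].node); e_parent.push_back(-1);
          e_meio.push_back(recs[r].meioses);
          e_locus.push_back(recs[r].locus);
          e_year.push_back(y);
          o_locus.push_back(recs[r].locus); o_node.push_back(recs[r].node);
          o_hap.push_back((int)hap);
        }
      } else {
        // one meiosis for this gamete, shared by all loci it carries
        int k = (int)R::rpois(rec_rate * chrom_len);
        bp.clear();
        for (int i = 0; i < k; ++i) bp.push_back(unif_rand() * chrom_len);
        std::sort(bp.begin(), bp.end());
        int coin = unif_rand() < 0.5 ? 0 : 1;
        for (size_t r = 0; r < recs.size(); ++r) {
          int l = recs[r].locus;
          int below = (int)(std::lower_bound(bp.begin(), bp.end(),
                                             locus_pos[l]) - bp.begin());
          int hp = (coin + below) & 1;
          arrive(2 * (int64_t)(par - 1) + hp, l, recs[r].node,
                 recs[r].meioses + 1);
        }
      }
      std::vector<Rec>().swap(recs);  // release memory
    }
    std::vector<int64_t>().swap(bucket[y]);
  }

  return List::create(
    _["edge_child"] = wrap(e_child), _["edge_parent"] = wrap(e_parent),
    _["edge_meioses"] = wrap(e_meio), _["edge_locus"] = wrap(e_locus),
    _["edge_year"] = wrap(e_year),
    _["open_locus"] = wrap(o_locus), _["open_node"] = wrap(o_node),
    _["open_hap"] = wrap(o_hap),
    _["n_leaves"] = n_leaf, _["next_node"] = next_node);
}

// Linked backward Wright-Fisher extension beyond the founders.
//
// Continues the open founder lineages for `gens` further generations in a
// virtual random-mating diploid population of constant size `ne`,
// preserving linkage between loci: each haplotype draws one random parent
// per generation and a shared meiosis decides, per locus, which parental
// haplotype is copied.  This carries the linked-ancestry signal (and
// hence long-range LD) back to the time horizon the binned-LD estimator
// probes; the remaining lineages are then finished by the single-locus
// coalescent (cpp_recapitate), whose marginal distribution is identical.
// Emits coalescence edges in the same (child, parent, meioses, locus)
// format as the pedigree tracer.
// [[Rcpp::export]]
List cpp_virtual_ancestry(IntegerVector open_locus, IntegerVector open_node,
                          IntegerVector open_hap, int next_node,
                          NumericVector locus_pos, double chrom_len,
                          double rec_rate, double ne, int gens) {
  struct VRec { int carrier, locus, node, meioses; };
  std::vector<VRec> recs(open_locus.size());
  for (int i = 0; i < open_locus.size(); ++i) {
    recs[i] = VRec{open_hap[i], open_locus[i], open_node[i], 0};
  }
  std::vector<int> e_child, e_parent, e_meio, e_locus, e_gen;
  std::vector<int> o_locus2, o_node2;
  std::vector<int> o_meio2;
  std::vector<double> bp;
  long long n_par = (long long)std::max(1.0, std::floor(ne + 0.5));
  auto by_carrier_locus = [](const VRec& a, const VRec& b) {
    return a.carrier < b.carrier ||
           (a.carrier == b.carrier && a.locus < b.locus);
  };
  for (int g = 1; g <= gens; ++g) {
    std::sort(recs.begin(), recs.end(), by_carrier_locus);
    // coalesce records sharing (carrier, locus)
    size_t w = 0;
    for (size_t r = 0; r < recs.size(); ++r) {
      if (w > 0 && recs[w - 1].carrier == recs[r].carrier &&
          recs[w - 1].locus == recs[r].locus) {
        int c = next_node++;
        e_child.push_back(recs[w - 1].node); e_parent.push_back(c);
        e_meio.push_back(recs[w - 1].meioses);
        e_locus.push_back(recs[r].locus); e_gen.push_back(g);
        e_child.push_back(recs[r].node); e_parent.push_back(c);
        e_meio.push_back(recs[r].meioses);
        e_locus.push_back(recs[r].locus); e_gen.push_back(g);
        recs[w - 1].node = c;
        recs[w - 1].meioses = 0;
      } else {
        recs[w++] = recs[r];
      }
    }
    recs.resize(w);
    // one meiosis per distinct carrier haplotype
    size_t i = 0;
    while (i < recs.size()) {
      size_t j = i;
      while (j < recs.size() && recs[j].carrier == recs[i].carrier) ++j;
      long long par = (long long)(unif_rand() * n_par);
      if (par == n_par) par = n_par - 1;
      int k = (int)R::rpois(rec_rate * chrom_len);
      bp.clear();
      for (int q = 0; q < k; ++q) bp.push_back(unif_rand() * chrom_len);
      std::sort(bp.begin(), bp.end());
      int coin = unif_rand() < 0.5 ? 0 : 1;
      for (size_t r = i; r < j; ++r) {
        int below = (int)(std::lower_bound(bp.begin(), bp.end(),
                                           locus_pos[recs[r].locus]) -
                          bp.begin());
        recs[r].carrier = (int)(2 * par + ((coin + below) & 1));
        recs[r].meioses++;
      }
      i = j;
    }
  }
  // final within-carrier coalescences, then emit the still-open lineages
  std::sort(recs.begin(), recs.end(), by_carrier_locus);
  size_t w = 0;
  for (size_t r = 0; r < recs.size(); ++r) {
    if (w > 0 && recs[w - 1].carrier == recs[r].carrier &&
        recs[w - 1].locus == recs[r].locus) {
      int c = next_node++;
      e_child.push_back(recs[w - 1].node); e_parent.push_back(c);
      e_meio.push_back(recs[w - 1].meioses);
      e_locus.push_back(recs[r].locus); e_gen.push_back(gens);
      e_child.push_back(recs[r].node); e_parent.push_back(c);
      e_meio.push_back(recs[r].meioses);
      e_locus.push_back(recs[r].locus); e_gen.push_back(gens);
      recs[w - 1].node = c;
      recs[w - 1].meioses = 0;
    } else {
      recs[w++] = recs[r];
    }
  }
  recs.resize(w);
  for (size_t r = 0; r < recs.size(); ++r) {
    e_child.push_back(recs[r].node); e_parent.push_back(-1);
    e_meio.push_back(recs[r].meioses);
    e_locus.push_back(recs[r].locus); e_gen.push_back(gens);
    o_locus2.push_back(recs[r].locus); o_node2.push_back(recs[r].node);
  }
  return List::create(
    _["edge_child"] = wrap(e_child), _["edge_parent"] = wrap(e_parent),
    _["edge_meioses"] = wrap(e_meio), _["edge_locus"] = wrap(e_locus),
    _["edge_gen"] = wrap(e_gen),
    _["open_locus"] = wrap(o_locus2), _["open_node"] = wrap(o_node2),
    _["next_node"] = next_node);
}

// Complete open founder lineages with a single-locus Kingman coalescent
// under a piecewise-constant diploid size history: size ne_h from the
// hand-off time g0 (generations) back to t_anc, size ne_a earlier.
// Loci are completed independently: by the hand-off time most lineages
// have coalesced inside the pedigree, and the estimators evaluated here
// read population size at time points well inside the pedigree epoch.
//
// open_locus/open_node must be grouped by locus (ascending), as produced
// by cpp_trace_ancestry after an order() in R.
// [[Rcpp::export]]
List cpp_recapitate(IntegerVector open_locus, IntegerVector open_node,
                    int next_node, double g0, double ne_h, double ne_a,
                    double t_anc) {
  std::vector<int> r_child, r_parent, r_locus;
  std::vector<double> r_len;    // branch length in generations
  std::vector<double> r_time;   // time of the parent node, generations
  int n = open_locus.size();
  int i = 0;
  std::vector<int> nodes;
  std::vector<double> times;
  while (i < n) {
    int l = open_locus[i];
    nodes.clear(); times.clear();
    while (i < n && open_locus[i] == l) {
      nodes.push_back(open_node[i]);
      times.push_back(g0);
      ++i;
    }
    double t = g0;
    while (nodes.size() > 1) {
      int k = nodes.size();
      double ne = t < t_anc ? ne_h : ne_a;
      double rate = k * (k - 1.0) / 2.0 / (2.0 * ne);
      double dt = R::exp_rand() / rate;
      if (t < t_anc && t + dt > t_anc) {
        // rescale the residual waiting time across the size change
        double frac = (t_anc - t) / dt;
        t = t_anc;
        dt = (1.0 - frac) * dt * (ne_a / ne_h);
        t += dt;
      } else {
        t += dt;
      }
      int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
      int b = (int)(unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
      if (b >= a) ++b;
      int c = next_node++;
      r_child.push_back(nodes[a]); r_parent.push_back(c);
      r_len.push_back(t - times[a]); r_locus.push_back(l);
      r_child.push_back(nodes[b]); r_parent.push_back(c);
      r_len.push_back(t - times[b]); r_locus.push_back(l);
      r_time.push_back(t); r_time.push_back(t);
      if (a > b) std::swap(a, b);
      nodes[a] = c; times[a] = t;
      nodes[b] = nodes.back(); times[b] = times.back();
      nodes.pop_back(); times.pop_back();
    }
  }
  return List::create(
    _["child"] = wrap(r_child), _["parent"] = wrap(r_parent),
    _["length_gen"] = wrap(r_len), _["locus"] = wrap(r_locus),
    _["time_gen"] = wrap(r_time), _["next_node"] = next_node);
}

// Drop infinite-sites mutations on a completed forest and emit segregating
// sites.  Pedigree-epoch edges carry Binomial(meioses, mu * locus_len)
// mutations (one Bernoulli trial per meiosis); coalescent-epoch edges
// carry Poisson(mu * locus_len * length_gen).  Each mutation is placed at
// a unique integer position inside its locus and its carriers are the
// leaves below the child end of the edge.  Sites monomorphic across all
// sampled haplotypes are not emitted.
// [[Rcpp::export]]
List cpp_drop_mutations(IntegerVector e_child, IntegerVector e_parent,
                        IntegerVector e_meioses, IntegerVector e_locus,
                        IntegerVector r_child, IntegerVector r_parent,
                        NumericVector r_len, IntegerVector r_locus,
                        int n_leaves, int next_node,
                        NumericVector locus_start, NumericVector locus_len,
                        double mu_bp) {
  int n_loc = locus_start.size();
  // group edges by locus
  std::vector<std::vector<int>> ped_edges(n_loc), rec_edges(n_loc);
  for (int i = 0; i < e_child.size(); ++i) ped_edges[e_locus[i]].push_back(i);
  for (int i = 0; i < r_child.size(); ++i) rec_edges[r_locus[i]].push_back(i);

  std::vector<int> s_locus;
  std::vector<double> s_pos;
  std::vector<int> carrier_off(1, 0);
  std::vector<int> carriers;

  std::vector<int> child_a(next_node, -1), child_b(next_node, -1);
  std::vector<int> stack, touched;

  for (int l = 0; l < n_loc; ++l) {
    double mu_loc = mu_bp * locus_len[l];
    // collect mutated edges first; skip tree assembly if none
    std::vector<int> mut_nodes;
    for (size_t j = 0; j < ped_edges[l].size(); ++j) {
      int i = ped_edges[l][j];
      int m = e_meioses[i] > 0
                ? (int)R::rbinom((double)e_meioses[i], mu_loc) : 0;
      for (int q = 0; q < m; ++q) mut_nodes.push_back(e_child[i]);
    }
    for (size_t j = 0; j < rec_edges[l].size(); ++j) {
      int i = rec_edges[l][j];
      int m = (int)R::rpois(mu_loc * r_len[i]);
      for (int q = 0; q < m; ++q) mut_nodes.push_back(r_child[i]);
    }
    if (mut_nodes.empty()) continue;

    // assemble children pointers for this locus
    touched.clear();
    auto link = [&](int ch, int pa) {
      if (pa < 0) return;
      if (child_a[pa] < 0) child_a[pa] = ch; else child_b[pa] = ch;
      touched.push_back(pa);
    };
    for (size_t j = 0; j < ped_edges[l].size(); ++j) {
      int i = ped_edges[l][j];
      link(e_child[i], e_parent[i]);
    }
    for (size_t j = 0; j < rec_edges[l].size(); ++j) {
      int i = rec_edges[l][j];
      link(r_child[i], r_parent[i]);
    }

    // unique integer positions within the locus
    int span = (int)locus_len[l];
    std::vector<double> taken;
    for (size_t m = 0; m < mut_nodes.size(); ++m) {
      double pos = -1;
      for (int attempt = 0; attempt < 1000; ++attempt) {
        double cand = std::floor(unif_rand() * span);
        if (cand >= span) cand = span - 1;
        if (std::find(taken.begin(), taken.end(), cand) == taken.end()) {
          pos = cand; break;
        }
      }
      if (pos < 0) stop("locus saturated: cannot place a unique position");
      // leaves below the mutated node
      stack.clear();
      stack.push_back(mut_nodes[m]);
      int before = carriers.size();
      while (!stack.empty()) {
        int nd = stack.back(); stack.pop_back();
        if (nd < n_leaves) { carriers.push_back(nd); continue; }
        if (child_a[nd] >= 0) stack.push_back(child_a[nd]);
        if (child_b[nd] >= 0) stack.push_back(child_b[nd]);
      }
      int cnt = (int)carriers.size() - before;
      if (cnt == 0 || cnt == n_leaves) {
        carriers.resize(before);  // monomorphic among the samples: drop
        continue;
      }
      taken.push_back(pos);
      s_locus.push_back(l);
      s_pos.push_back(locus_start[l] + pos);
      carrier_off.push_back((int)carriers.size());
    }
    for (size_t j = 0; j < touched.size(); ++j) {
      child_a[touched[j]] = -1; child_b[touched[j]] = -1;
    }
  }
  return List::create(
    _["site_locus"] = wrap(s_locus), _["site_pos"] = wrap(s_pos),
    _["carrier_offsets"] = wrap(carrier_off),
    _["carriers"] = wrap(carriers));
}
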