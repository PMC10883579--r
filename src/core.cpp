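#include <Rcpp.h>
using namespace Rcpp;

// Bit-vector sequences are stored as integer masks (B <= 30 bits).

static inline int popcount32(unsigned int v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(v);
#else
  v = v - ((v >> 1) & 0x55555555u);
  v = (v & 0x33333333u) + ((v >> 2) & 0x33333333u);
  return (int)((((v + (v >> 4)) & 0x0F0F0F0Fu) * 0x01010101u) >> 24);
#endif
}

// [[Rcpp::export(name = ".hamming_mask")]]
IntegerVector hamming_mask(IntegerVector a, IntegerVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int x = a[a.size() == 1 ? 0 : i];
    int y = b[b.size() == 1 ? 0 : i];
    if (x == NA_INTEGER || y == NA_INTEGER) { out[i] = NA_INTEGER; continue; }
    out[i] = popcount32((unsigned int)(x ^ y));
  }
  return out;
}

// Draw the occupant of each binding site from the categorical distribution
// with unnormalized mass 1 for "none" and c * s^hamming * copies for each
// product. Returns 1-based product index per site, 0 = unbound.
// [[Rcpp::export(name = ".occupancy_draw")]]
IntegerVector occupancy_draw(IntegerVector site_seq, IntegerVector prod_seq,
                             NumericVector prod_copies, double cc, double ss) {
  int ns = site_seq.size(), np = prod_seq.size();
  IntegerVector bound(ns);
  std::vector<double> aff(np);
  for (int i = 0; i < ns; ++i) {
    double tot = 1.0;
    for (int j = 0; j < np; ++j) {
      int d = popcount32((unsigned int)(site_seq[i] ^ prod_seq[j]));
      aff[j] = cc * std::pow(ss, d) * prod_copies[j];
      tot += aff[j];
    }
    double u = unif_rand() * tot;
    int pick = 0;
    double acc = 1.0;
    if (u >= 1.0) {
      for (int j = 0; j < np; ++j) {
        acc += aff[j];
        if (u < acc) { pick = j + 1; break; }
      }
    }
    bound[i] = pick;
  }
  return bound;
}

// Complete regulatory update for one cell in the population loop: build
// the product pool (expressed native genes with fork-dependent dosage,
// plus foreign deliveries), sample site occupancy, update expression, and
// compute the 5-bit core pattern (expressed native core types plus foreign
// products bit-identical to a native copy of their type). Returns the new
// expression vector and the 1-based index of the matching stage pattern
// (0 = no stage).
// [[Rcpp::export(name = ".cell_regulation")]]
List cell_regulation(IntegerVector site_seq, IntegerVector site_gene,
                     IntegerVector gene_thr, IntegerVector gene_seq,
                     IntegerVector gene_type, IntegerVector gene_w,
                     IntegerVector gene_pos, LogicalVector native,
                     LogicalVector expr, int fork,
                     IntegerVector f_seq, NumericVector f_w,
                     NumericVector f_cp, IntegerVector f_type,
                     IntegerVector stage_codes, double cc, double ss) {
  int ng = gene_thr.size(), ns = site_seq.size(), nf = f_seq.size();
  std::vector<int> p_seq; std::vector<double> p_w, p_cp;
  p_seq.reserve(ng + nf); p_w.reserve(ng + nf); p_cp.reserve(ng + nf);
  for (int g = 0; g < ng; ++g) {
    if (expr[g] && native[g]) {
      p_seq.push_back(gene_seq[g]);
      p_w.push_back((double)gene_w[g]);
      p_cp.push_back(gene_pos[g] <= fork ? 2.0 : 1.0);
    }
  }
  for (int j = 0; j < nf; ++j) {
    p_seq.push_back(f_seq[j]);
    p_w.push_back(f_w[j]);
    p_cp.push_back(f_cp[j]);
  }
  int np = (int)p_seq.size();
  std::vector<double> aff(np), sum(ng, 0.0);
  for (int i = 0; i < ns; ++i) {
    double tot = 1.0;
    for (int j = 0; j < np; ++j) {
      int d = popcount32((unsigned int)(site_seq[i] ^ p_seq[j]));
      aff[j] = cc * std::pow(ss, d) * p_cp[j];
      tot += aff[j];
    }
    double u = unif_rand() * tot;
    if (u >= 1.0) {
      double acc = 1.0;
      for (int j = 0; j < np; ++j) {
        acc += aff[j];
        if (u < acc) {
          if (site_gene[i] > 0) sum[site_gene[i] - 1] += p_w[j];
          break;
        }
      }
    }
  }
  LogicalVector new_expr(ng);
  int bits = 0;
  for (int g = 0; g < ng; ++g) {
    bool on = sum[g] >= gene_thr[g];
    new_expr[g] = on;
    if (on && gene_type[g] != NA_INTEGER && gene_type[g] >= 1 && gene_type[g] <= 5)
      bits |= 1 << (gene_type[g] - 1);
  }
  for (int j = 0; j < nf; ++j) {
    int tk = f_type[j];
    if (tk < 1 || tk > 5 || (bits & (1 << (tk - 1)))) continue;
    for (int g = 0; g < ng; ++g) {
      if (gene_type[g] == tk && gene_seq[g] == f_seq[j]) {
        bits |= 1 << (tk - 1);
        break;
      }
    }
  }
  int si = 0;
  for (int s2 = 0; s2 < stage_codes.size(); ++s2)
    if (stage_codes[s2] == bits) { si = s2 + 1; break; }
  return List::create(_["expr"] = new_expr, _["stage_index"] = si);
}

// One synchronous timestep for a whole holobiont: build the foreign
// product deliveries (signal-peptide targeting, then stochastic leakage)
// from the step-start expression states, then run the regulatory update
// and stage bookkeeping for the host (cell 0) and every symbiont.
// progress = number of stages passed in order (0..3); stage = current
// stage index (1..4). Events: 0 none, 1 divided-ready, 2 died.
// The passed fork/progress/stage vectors are updated in place; the exprs
// list has its elements replaced (never mutated) with fresh vectors.
static void holo_step_core(
                    List caches, List exprs, IntegerVector fork,
                    IntegerVector progress, IntegerVector stage,
                    IntegerVector genome_len, int k,
                    IntegerVector stage_codes, double cc, double ss,
                    const double *pow_tab,
                    double leak, bool tgt_h2s, bool tgt_s2h,
                    bool leak_h2s, bool leak_s2h, bool step_host,
                    int *ev_out) {
  int nc = caches.size();
  std::vector<const int*> site_seq(nc), site_gene(nc), gene_thr(nc),
      gene_seq(nc), gene_type(nc), gene_w(nc), gene_pos(nc), gene_sp(nc),
      native(nc), expr(nc);
  std::vector<int> n_gene(nc), n_site(nc);
  for (int c = 0; c < nc; ++c) {
    // fixed field order of build_regulatory_cache() + new_cell():
    // 1 gene_pos, 2 site_pos, 3 site_gene, 4 site_seq, 5 gene_seq,
    // 6 gene_type, 7 gene_sp, 8 gene_w, 9 gene_thr, 10 B, 11 native
    SEXP ca = caches[c];
    gene_pos[c] = INTEGER(VECTOR_ELT(ca, 0));
    site_gene[c] = INTEGER(VECTOR_ELT(ca, 2));
    site_seq[c] = INTEGER(VECTOR_ELT(ca, 3));
    gene_seq[c] = INTEGER(VECTOR_ELT(ca, 4));
    gene_type[c] = INTEGER(VECTOR_ELT(ca, 5));
    gene_sp[c] = INTEGER(VECTOR_ELT(ca, 6));
    gene_w[c] = INTEGER(VECTOR_ELT(ca, 7));
    gene_thr[c] = INTEGER(VECTOR_ELT(ca, 8));
    native[c] = LOGICAL(VECTOR_ELT(ca, 10));
    n_gene[c] = (int)Rf_xlength(VECTOR_ELT(ca, 0));
    n_site[c] = (int)Rf_xlength(VECTOR_ELT(ca, 3));
    expr[c] = LOGICAL(exprs[c]);
  }

  // foreign deliveries per cell (1 copy each)
  std::vector<std::vector<int>> f_seq(nc), f_type(nc);
  std::vector<std::vector<double>> f_w(nc);
  if (nc > 1) {
    int ngh = n_gene[0];
    // host -> symbionts: targeting (symbiont bit of the signal peptide)
    if (tgt_h2s) {
      for (int g = 0; g < ngh; ++g) {
        if (expr[0][g] && (gene_sp[0][g] & 1)) {
          for (int s2 = 1; s2 < nc; ++s2) {
            f_seq[s2].push_back(gene_seq[0][g]);
            f_type[s2].push_back(gene_type[0][g]);
            f_w[s2].push_back((double)gene_w[0][g]);
          }
        }
      }
    }
    // host -> symbionts: leakage, per expressed gene per symbiont
    if (leak_h2s && leak > 0) {
      for (int s2 = 1; s2 < nc; ++s2) {
        for (int g = 0; g < ngh; ++g) {
          if (expr[0][g] && unif_rand() < leak) {
            f_seq[s2].push_back(gene_seq[0][g]);
            f_type[s2].push_back(gene_type[0][g]);
            f_w[s2].push_back((double)gene_w[0][g]);
          }
        }
      }
    }
    // symbionts -> host: targeting (host bit) and leakage
    for (int s2 = 1; s2 < nc; ++s2) {
      int ngs = n_gene[s2];
      for (int g = 0; g < ngs; ++g) {
        if (!expr[s2][g]) continue;
        bool cross = tgt_s2h && (gene_sp[s2][g] & 2);
        bool leaked = leak_s2h && leak > 0 && unif_rand() < leak;
        if (cross || leaked) {
          f_seq[0].push_back(gene_seq[s2][g]);
          f_type[0].push_back(gene_type[s2][g]);
          f_w[0].push_back((double)gene_w[s2][g]);
        }
        if (cross && leaked) {  // both channels deliver a copy each
          f_seq[0].push_back(gene_seq[s2][g]);
          f_type[0].push_back(gene_type[s2][g]);
          f_w[0].push_back((double)gene_w[s2][g]);
        }
      }
    }
  }

  std::vector<char> ne;
  for (int c = 0; c < nc; ++c) {
    ev_out[c] = 0;
    if (c == 0 && !step_host) continue;
    int ng = n_gene[c], ns = n_site[c];
    int nf = (int)f_seq[c].size();
    std::vector<int> p_seq; std::vector<double> p_w, p_cp;
    for (int g = 0; g < ng; ++g) {
      if (expr[c][g] && native[c][g]) {
        p_seq.push_back(gene_seq[c][g]);
        p_w.push_back((double)gene_w[c][g]);
        p_cp.push_back(gene_pos[c][g] <= fork[c] ? 2.0 : 1.0);
      }
    }
    for (int j = 0; j < nf; ++j) {
      p_seq.push_back(f_seq[c][j]);
      p_w.push_back(f_w[c][j]);
      p_cp.push_back(1.0);
    }
    int np = (int)p_seq.size();
    std::vector<double> aff(np), sum(ng, 0.0);
    for (int i = 0; i < ns; ++i) {
      double tot = 1.0;
      for (int j = 0; j < np; ++j) {
        int d = popcount32((unsigned int)(site_seq[c][i] ^ p_seq[j]));
        aff[j] = pow_tab[d] * p_cp[j];
        tot += aff[j];
      }
      double u = unif_rand() * tot;
      if (u >= 1.0) {
        double acc = 1.0;
        for (int j = 0; j < np; ++j) {
          acc += aff[j];
          if (u < acc) {
            if (site_gene[c][i] > 0) sum[site_gene[c][i] - 1] += p_w[j];
            break;
          }
        }
      }
    }
    ne.assign(ng, 0);
    bool changed = false;
    int bits = 0;
    for (int g = 0; g < ng; ++g) {
      bool on = sum[g] >= gene_thr[c][g];
      ne[g] = on ? 1 : 0;
      if (on != (expr[c][g] != 0)) changed = true;
      if (on && gene_type[c][g] != NA_INTEGER &&
          gene_type[c][g] >= 1 && gene_type[c][g] <= 5)
        bits |= 1 << (gene_type[c][g] - 1);
    }
    for (int j = 0; j < nf; ++j) {
      int tk = f_type[c][j];
      if (tk < 1 || tk > 5 || (bits & (1 << (tk - 1)))) continue;
      for (int g = 0; g < ng; ++g) {
        if (gene_type[c][g] == tk && gene_seq[c][g] == f_seq[c][j]) {
          bits |= 1 << (tk - 1);
          break;
        }
      }
    }
    int si = 0;
    for (int s2 = 0; s2 < stage_codes.size(); ++s2)
      if (stage_codes[s2] == bits) { si = s2 + 1; break; }

    if (changed) {
      // replace, never mutate: cells may alias the old vectors
      LogicalVector nv(ng);
      for (int g = 0; g < ng; ++g) nv[g] = ne[g] != 0;
      exprs[c] = nv;
    }
    bool alive = true, ready = false;
    if (si == 4) {
      if (progress[c] == 3 && fork[c] >= genome_len[c]) {
        stage[c] = 4;
        ready = true;
        ev_out[c] = 1;
      } else {
        alive = false;
        ev_out[c] = 2;
      }
    } else if (si > 0 && si == progress[c] + 1) {
      stage[c] = si;
      progress[c] = si;
    }
    if (alive && !ready && stage[c] == 2) {
      int add = genome_len[c] - fork[c];
      fork[c] += add < k ? add : k;
    }
  }
}

static void fill_pow_tab(double *tab, double cc, double ss, int n) {
  double v = cc;
  for (int d = 0; d < n; ++d) { tab[d] = v; v *= ss; }
}

// One synchronous timestep for a single holobiont (host = cell 1), used
// by the single-holobiont assays and tests. State vectors are cloned.
// [[Rcpp::export(name = ".holobiont_step")]]
List holobiont_step(List caches, List exprs, IntegerVector fork,
                    IntegerVector progress, IntegerVector stage,
                    IntegerVector genome_len, int k,
                    IntegerVector stage_codes, double cc, double ss,
                    double leak, bool tgt_h2s, bool tgt_s2h,
                    bool leak_h2s, bool leak_s2h, bool step_host) {
  double tab[33];
  fill_pow_tab(tab, cc, ss, 33);
  List ex = clone(exprs);
  IntegerVector fk = clone(fork), pg = clone(progress), st = clone(stage);
  IntegerVector ev(ex.size());
  holo_step_core(caches, ex, fk, pg, st, genome_len, k,
                 stage_codes, cc, ss, tab, leak,
                 tgt_h2s, tgt_s2h, leak_h2s, leak_s2h,
                 step_host, INTEGER(ev));
  return List::create(_["exprs"] = ex, _["event"] = ev, _["fork"] = fk,
                      _["progress"] = pg, _["stage"] = st);
}

// One timestep for the whole grid. For every holobiont id in `ord` (in
// order): compute its nutrient share from the step-start cell counts,
// run the holobiont step (updating the holobiont's state arrays in
// place), and draw its basal death. Returns per-cell events as one flat
// vector with per-holobiont offsets, basal flags, and an attention flag
// marking holobionts that need R-level handling (events, pending
// division, basal death).
// [[Rcpp::export(name = ".grid_step")]]
List grid_step(List holos, IntegerVector ord,
               NumericMatrix influx, IntegerMatrix ncells,
               double rho, IntegerVector stage_codes, double cc, double ss,
               double leak, bool tgt_h2s, bool tgt_s2h,
               bool leak_h2s, bool leak_s2h, double delta) {
  int nh = ord.size();
  int H = influx.nrow(), W = influx.ncol();
  double tab[33];
  fill_pow_tab(tab, cc, ss, 33);
  IntegerVector offset(nh);
  int total = 0;
  for (int hi = 0; hi < nh; ++hi) {
    List h = holos[ord[hi] - 1];
    offset[hi] = total;
    total += Rf_length(h[8]);  // exprs list: one entry per cell
  }
  IntegerVector events(total);
  int *evp = INTEGER(events);
  IntegerVector basal(nh), att(nh);
  for (int hi = 0; hi < nh; ++hi) {
    List h = holos[ord[hi] - 1];
    // fixed field order set by new_holobiont() + sync_holo_state():
    // 0 id, 1 host, 2 syms, 3 row, 4 col, 5 birth_sym_count, 6 pending,
    // 7 caches, 8 exprs, 9 forks, 10 progs, 11 stgs, 12 lens
    int row = as<int>(h[3]), col = as<int>(h[4]);
    bool pending = as<bool>(h[6]);
    // 3x3 Moore neighbourhood: toroidal width, bounded height
    int C = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      int r = row - 1 + dr;
      if (r < 0 || r >= H) continue;
      for (int dc = -1; dc <= 1; ++dc) {
        int c2 = (col - 1 + dc + W) % W;
        C += ncells(r, c2);
      }
    }
    double A = influx(row - 1, col - 1) / (C > 0 ? C : 1);
    int k = (int)(A / rho);   // 0 under starvation: replication halts
    int *ev = evp + offset[hi];
    int nc = Rf_length(h[8]);
    holo_step_core(h[7], h[8], h[9], h[10], h[11], h[12], k, stage_codes,
                   cc, ss, tab, leak, tgt_h2s, tgt_s2h, leak_h2s, leak_s2h,
                   !pending, ev);
    bool b = delta > 0 && unif_rand() < delta;
    basal[hi] = b ? 1 : 0;
    bool need = pending || b;
    if (!need) for (int c = 0; c < nc; ++c)
      if (ev[c] != 0) { need = true; break; }
    att[hi] = need ? 1 : 0;
  }
  return List::create(_["att"] = att, _["events"] = events,
                      _["offset"] = offset, _["basal"] = basal);
}

// One regulatory update for a single cell: sample occupancy of every site,
// then set each gene's next expression state by comparing the summed weights
// of products bound in its upstream region against its threshold.
// site_gene: 1-based index (into the gene vectors) of the gene whose region
// each site belongs to, 0 if the site is in no region.
// [[Rcpp::export(name = ".expression_step")]]
List expression_step(IntegerVector site_seq, IntegerVector site_gene,
                     IntegerVector gene_thr,
                     IntegerVector prod_seq, NumericVector prod_weight,
                     NumericVector prod_copies, double cc, double ss) {
  int ns = site_seq.size(), np = prod_seq.size(), ng = gene_thr.size();
  IntegerVector bound(ns);
  NumericVector sum(ng);
  std::vector<double> aff(np);
  for (int i = 0; i < ns; ++i) {
    double tot = 1.0;
    for (int j = 0; j < np; ++j) {
      int d = popcount32((unsigned int)(site_seq[i] ^ prod_seq[j]));
      aff[j] = cc * std::pow(ss, d) * prod_copies[j];
      tot += aff[j];
    }
    double u = unif_rand() * tot;
    int pick = 0;
    double acc = 1.0;
    if (u >= 1.0) {
      for (int j = 0; j < np; ++j) {
        acc += aff[j];
        if (u < acc) { pick = j + 1; break; }
      }
    }
    bound[i] = pick;
    if (pick > 0 && site_gene[i] > 0) sum[site_gene[i] - 1] += prod_weight[pick - 1];
  }
  LogicalVector expr(ng);
  for (int g = 0; g < ng; ++g) expr[g] = sum[g] >= gene_thr[g];
  return List::create(_["expr"] = expr, _["bound"] = bound,
                      _["region_sum"] = sum);
}
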