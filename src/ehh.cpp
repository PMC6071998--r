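#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity walkers.
//
// Haplotype matrices are integer 0/1, rows = haplotypes, columns = markers of
// ONE chromosome sorted by position. Panels must be complete (no NA): callers
// enforce this. EHH at marker m is sum_h C(n_h,2) / C(n,2) where n_h counts
// carrier haplotypes identical over [focal..m].
//
// Stop codes: 0 = EHH fell below floor, 1 = inter-marker gap exceeded,
// 2 = chromosome end reached.

static double group_pairs(const std::vector<int>& cnt) {
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k)
    s += (double)cnt[k] * (cnt[k] - 1) / 2.0;
  return s;
}

// Refine current grouping by the alleles at column j; returns new group count.
static int refine(const IntegerMatrix& H, const std::vector<int>& rows, int j,
                  std::vector<int>& grp, int ngrp, std::vector<int>& cnt) {
  std::vector<int> remap(2 * ngrp, -1);
  int ng = 0;
  cnt.clear();
  for (size_t i = 0; i < rows.size(); ++i) {
    int key = 2 * grp[i] + H(rows[i], j);
    if (remap[key] < 0) {
      remap[key] = ng++;
      cnt.push_back(0);
    }
    grp[i] = remap[key];
    cnt[grp[i]]++;
  }
  return ng;
}

static void walk_side(const IntegerMatrix& H, const std::vector<int>& rows,
                      const NumericVector& pos, int focal, int dir,
                      double ehh_floor, double max_gap,
                      std::vector<int> grp, int ngrp,
                      std::vector<int>& idx, std::vector<double>& ehh,
                      int& stop_reason) {
  const int n = (int)rows.size();
  const int m = H.ncol();
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> cnt;
  int j = focal;
  stop_reason = 2;
  while (true) {
    int jn = j + dir;
    if (jn < 0 || jn >= m) { stop_reason = 2; break; }
    if (std::fabs(pos[jn] - pos[j]) > max_gap) { stop_reason = 1; break; }
    ngrp = refine(H, rows, jn, grp, ngrp, cnt);
    double e = group_pairs(cnt) / denom;
    idx.push_back(jn);
    ehh.push_back(e);
    j = jn;
    if (e < ehh_floor) { stop_reason = 0; break; }
  }
}

// Initial grouping at the focal marker. Allele cores condition on the core
// allele, so all carriers form one group (EHH = 1 at the focal SNP). The
// site core splits on the focal alleles (EHH at focal = site homozygosity).
static int init_groups(const IntegerMatrix& H, const std::vector<int>& rows,
                       int focal, bool site_split, std::vector<int>& grp,
                       double& e0) {
  const int n = (int)rows.size();
  grp.assign(n, 0);
  if (!site_split) {
    e0 = 1.0;
    return 1;
  }
  // compact group labels (0..ngrp-1) so refine() can index remap safely
  int remap[2] = {-1, -1};
  int ng = 0;
  std::vector<int> cnt;
  for (int i = 0; i < n; ++i) {
    int a = H(rows[i], focal);
    if (remap[a] < 0) { remap[a] = ng++; cnt.push_back(0); }
    grp[i] = remap[a];
    cnt[grp[i]]++;
  }
  double denom = (double)n * (n - 1) / 2.0;
  e0 = group_pairs(cnt) / denom;
  return ng;
}

// [[Rcpp::export]]
List cpp_ehh_walk(const IntegerMatrix& H, const IntegerVector& carriers,
                  const NumericVector& pos, int focal, double ehh_floor,
                  double max_gap, bool site_split) {
  std::vector<int> rows(carriers.begin(), carriers.end());
  if (rows.size() < 2) stop("need at least 2 carrier haplotypes");
  std::vector<int> grp;
  double e0;
  int ngrp = init_groups(H, rows, focal, site_split, grp, e0);
  std::vector<int> li, ri;
  std::vector<double> le, re;
  int sl, sr;
  walk_side(H, rows, pos, focal, -1, ehh_floor, max_gap, grp, ngrp, li, le, sl);
  walk_side(H, rows, pos, focal, +1, ehh_floor, max_gap, grp, ngrp, ri, re, sr);
  return List::create(_["ehh0"] = e0,
                      _["left_idx"] = li, _["left_ehh"] = le, _["left_stop"] = sl,
                      _["right_idx"] = ri, _["right_ehh"] = re, _["right_stop"] = sr);
}

// Trapezoidal integral of one side's decay, starting at (pos[focal], e0).
static double side_integral(const NumericVector& pos, int focal,
                            const std::vector<int>& idx,
                            const std::vector<double>& ehh, double e0) {
  double s = 0.0, pe = e0, pp = pos[focal];
  for (size_t k = 0; k < idx.size(); ++k) {
    s += 0.5 * (pe + ehh[k]) * std::fabs(pos[idx[k]] - pp);
    pe = ehh[k];
    pp = pos[idx[k]];
  }
  return s;
}

static void ihh_one(const IntegerMatrix& H, const std::vector<int>& rows,
                    const NumericVector& pos, int focal, double ehh_floor,
                    double max_gap, bool site_split,
                    double& ihh, bool& border) {
  std::vector<int> grp;
  double e0;
  int ngrp = init_groups(H, rows, focal, site_split, grp, e0);
  std::vector<int> li, ri;
  std::vector<double> le, re;
  int sl, sr;
  walk_side(H, rows, pos, focal, -1, ehh_floor, max_gap, grp, ngrp, li, le, sl);
  walk_side(H, rows, pos, focal, +1, ehh_floor, max_gap, grp, ngrp, ri, re, sr);
  ihh = side_integral(pos, focal, li, le, e0) + side_integral(pos, focal, ri, re, e0);
  border = (sl == 2) || (sr == 2);
}

// iHH for ancestral (code 0) and derived (code 1) cores at every marker.
// Columns of the result: ihh_a, ihh_d, n_anc, n_der, border.
// [[Rcpp::export]]
NumericMatrix cpp_scan_ihh(const IntegerMatrix& H, const NumericVector& pos,
                           double ehh_floor, double max_gap) {
  const int m = H.ncol(), n = H.nrow();
  NumericMatrix out(m, 5);
  colnames(out) = CharacterVector::create("ihh_a", "ihh_d", "n_anc", "n_der",
                                          "border");
  std::vector<int> anc, der;
  for (int j = 0; j < m; ++j) {
    anc.clear(); der.clear();
    for (int i = 0; i < n; ++i) {
      if (H(i, j) == 0) anc.push_back(i); else der.push_back(i);
    }
    out(j, 2) = (double)anc.size();
    out(j, 3) = (double)der.size();
    double ia = NA_REAL, id = NA_REAL;
    bool ba = false, bd = false;
    if (anc.size() >= 2) ihh_one(H, anc, pos, j, ehh_floor, max_gap, false, ia, ba);
    if (der.size() >= 2) ihh_one(H, der, pos, j, ehh_floor, max_gap, false, id, bd);
    out(j, 0) = ia;
    out(j, 1) = id;
    out(j, 4) = (ba || bd) ? 1.0 : 0.0;
  }
  return out;
}

// Allele-agnostic integrated site EHH (iES) at every marker.
// Columns: ies, border.
// [[Rcpp::export]]
NumericMatrix cpp_scan_ies(const IntegerMatrix& H, const NumericVector& pos,
                           double ehh_floor, double max_gap) {
  const int m = H.ncol(), n = H.nrow();
  NumericMatrix out(m, 2);
  colnames(out) = CharacterVector::create("ies", "border");
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  for (int j = 0; j < m; ++j) {
    double ie = NA_REAL;
    bool b = false;
    ihh_one(H, all, pos, j, ehh_floor, max_gap, true, ie, b);
    out(j, 0) = ie;
    out(j, 1) = b ? 1.0 : 0.0;
  }
  return out;
}
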