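// Elston-Stewart peeling executor over the combined major-genotype x
// polygene state space. The R side builds, per family, a peeling schedule
// (see plan_family); this file executes schedules for a whole dataset in
// one call. State layout matches the R reference implementation:
// s = g + r * G (0-based; genotype index fastest).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

static inline double dotp(const double *a, const double *b, int n) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += a[i] * b[i];
  return acc;
}

struct Work {
  int G, R, S;
  const double *TM;    // (G*G) x G, row (gm + gf*G), col gc
  const double *TP;    // (R*R) x R
  const double *TMa;   // G x G, [gc, gm] father-averaged
  const double *TPa;   // R x R
  // TMt/TPt: transmission tensors laid out child-index-fastest,
  // TMt[gc + G*(gm + G*gf)]; identical memory to the original 3-d tensor
  std::vector<double> TMt, TPt;
  std::vector<double> M1, A, At, B, vt, Wp;
  Work(int G_, int R_, const double *tm, const double *tp,
       const double *tma, const double *tpa)
      : G(G_), R(R_), S(G_ * R_), TM(tm), TP(tp), TMa(tma), TPa(tpa),
        TMt(G_ * G_ * G_), TPt(R_ * R_ * R_),
        M1(R_ * R_ * G_), A(R_ * G_ * G_), At(R_ * G_ * G_), B(G_ * R_),
        vt(G_ * R_), Wp(S * S) {
    const int GG = G * G, RR = R * R;
    for (int gc = 0; gc < G; ++gc)
      for (int gg = 0; gg < GG; ++gg) TMt[gc + G * gg] = TM[gg + GG * gc];
    for (int rc = 0; rc < R; ++rc)
      for (int rr = 0; rr < RR; ++rr) TPt[rc + R * rr] = TP[rr + RR * rc];
  }

  // K[sm + sf*S] = sum_sc T(sc | sm, sf) v[sc]
  void child_full(const double *v, double *Kout) {
    const int RR = R * R;
    for (int rc = 0; rc < R; ++rc)
      for (int gc = 0; gc < G; ++gc) vt[rc + R * gc] = v[gc + rc * G];
    // M1t[gc + G*(rm + R*rf)] = sum_rc TP(rc | rm, rf) v[gc, rc]
    for (int rr = 0; rr < RR; ++rr)
      for (int gc = 0; gc < G; ++gc)
        M1[gc + G * rr] = dotp(&TPt[R * rr], &vt[R * gc], R);
    for (int gf = 0; gf < G; ++gf)
      for (int rf = 0; rf < R; ++rf)
        for (int gm = 0; gm < G; ++gm)
          for (int rm = 0; rm < R; ++rm)
            Kout[(gm + rm * G) + S * (gf + rf * G)] =
                dotp(&TMt[G * (gm + G * gf)], &M1[G * (rm + R * rf)], G);
  }

  // k[sm] = sum_sc T'(sc | sm) v[sc]  (father integrated out)
  void child_avg(const double *v, double *k) {
    for (int gc = 0; gc < G; ++gc)
      for (int rm = 0; rm < R; ++rm) {
        double acc = 0.0;
        for (int rc = 0; rc < R; ++rc) acc += TPa[rc + R * rm] * v[gc + rc * G];
        B[gc + G * rm] = acc;
      }
    for (int gm = 0; gm < G; ++gm)
      for (int rm = 0; rm < R; ++rm) {
        double acc = 0.0;
        for (int gc = 0; gc < G; ++gc) acc += TMa[gc + G * gm] * B[gc + G * rm];
        k[gm + rm * G] = acc;
      }
  }

  // msg[sc] = sum_{sm,sf} T(sc | sm, sf) W[sm + sf*S]
  void transmit_couple(const double *W, double *msg) {
    const int RR = R * R, GG = G * G;
    // regroup W so the polygene pair is contiguous
    for (int gf = 0; gf < G; ++gf)
      for (int rf = 0; rf < R; ++rf)
        for (int gm = 0; gm < G; ++gm)
          for (int rm = 0; rm < R; ++rm)
            Wp[(rm + R * rf) + RR * (gm + G * gf)] =
                W[(gm + rm * G) + S * (gf + rf * G)];
    for (int gg = 0; gg < GG; ++gg)
      for (int rc = 0; rc < R; ++rc)
        At[gg + GG * rc] = dotp(&TP[RR * rc], &Wp[RR * gg], RR);
    for (int rc = 0; rc < R; ++rc)
      for (int gc = 0; gc < G; ++gc)
        msg[gc + rc * G] = dotp(&TM[GG * gc], &At[GG * rc], GG);
  }

  // msg[sc] = sum_sm T'(sc | sm) U[sm]
  void transmit_single(const double *U, double *msg) {
    for (int gc = 0; gc < G; ++gc)
      for (int rm = 0; rm < R; ++rm) {
        double acc = 0.0;
        for (int gm = 0; gm < G; ++gm) acc += TMa[gc + G * gm] * U[gm + rm * G];
        B[gc + G * rm] = acc;
      }
    for (int gc = 0; gc < G; ++gc)
      for (int rc = 0; rc < R; ++rc) {
        double acc = 0.0;
        for (int rm = 0; rm < R; ++rm) acc += TPa[rc + R * rm] * B[gc + G * rm];
        msg[gc + rc * G] = acc;
      }
  }
};

} // namespace

// Executes all family schedules. `code` is the flat integer stream written
// by dataset_plans(): per family
//   [nmem, root, proband, nsteps,
//    founder flags (nmem),
//    per step: fa, mo, conn, role(0 = parent connector, 1 = child), nch,
//              children...,
//    nleftover, leftover...]
// all indices 0-based and local to the family; `cols` holds the 0-based
// PEN column of each member, families concatenated; `fam_off` indexes the
// start of each family's members in `cols`; `code_off` the start of each
// family's block in `code`. Returns per-family [joint loglik, proband
// marginal loglik]; if posterior_family >= 0, attribute "post" holds that
// family's root-state vector (unnormalised).
// [[Rcpp::export]]
NumericMatrix peel_dataset_cpp(NumericMatrix PEN, NumericMatrix PENden,
                               NumericVector prior,
                               NumericMatrix TMmat, NumericMatrix TPmat,
                               NumericMatrix TMavg, NumericMatrix TPavg,
                               IntegerVector code, IntegerVector code_off,
                               IntegerVector cols, IntegerVector fam_off,
                               int G, int R, int posterior_family = -1) {
  const int S = G * R;
  const int nfam = fam_off.size() - 1;
  Work wk(G, R, TMmat.begin(), TPmat.begin(), TMavg.begin(), TPavg.begin());
  NumericMatrix out(nfam, 2);
  NumericVector post(S);
  bool have_post = false;

  std::vector<double> V, KP(S * S), Kc(S * S), msg(S), k1(S), U(S);
  std::vector<int> founder;

  for (int f = 0; f < nfam; ++f) {
    const int *c = code.begin() + code_off[f];
    const int nmem = *c++;
    const int root = *c++;
    const int proband = *c++;
    const int nsteps = *c++;
    founder.assign(c, c + nmem); c += nmem;
    V.resize((size_t)S * nmem);
    const int *colf = cols.begin() + fam_off[f];
    // init: penetrance, founders times prior; record constant-penetrance
    // single-unit founders (eligible for analytic marginalisation)
    std::vector<char> constpen(nmem, 0);
    std::vector<double> constval(nmem, 1.0);
    for (int i = 0; i < nmem; ++i) {
      const double *p = &PEN(0, colf[i]);
      bool cst = true;
      for (int s = 1; s < S; ++s) if (p[s] != p[0]) { cst = false; break; }
      constpen[i] = (char)(cst && founder[i] >= 2 && i != root); // flag 2 = single unit
      constval[i] = p[0];
      for (int s = 0; s < S; ++s)
        V[(size_t)S * i + s] = (founder[i] ? p[s] * prior[s] : p[s]);
    }
    double logscale = 0.0;
    bool zero = false;

    for (int st = 0; st < nsteps && !zero; ++st) {
      int fa = *c++, mo = *c++, conn = *c++, role = *c++, nch = *c++;
      const int *ch = c; c += nch;
      if (role == 0) { // connector is a parent; put it in the `mo` slot
        if (conn == fa) std::swap(fa, mo);
        if (nch == 1 && constpen[fa]) {
          wk.child_avg(&V[(size_t)S * ch[0]], msg.data());
          for (int s = 0; s < S; ++s) msg[s] *= constval[fa];
        } else {
          wk.child_full(&V[(size_t)S * ch[0]], KP.data());
          for (int j = 1; j < nch; ++j) {
            wk.child_full(&V[(size_t)S * ch[j]], Kc.data());
            for (int s = 0; s < S * S; ++s) KP[s] *= Kc[s];
          }
          const double *vf = &V[(size_t)S * fa];
          for (int sm = 0; sm < S; ++sm) {
            double acc = 0.0;
            for (int sf = 0; sf < S; ++sf) acc += KP[sm + S * sf] * vf[sf];
            msg[sm] = acc;
          }
        }
        for (int s = 0; s < S; ++s) V[(size_t)S * mo + s] *= msg[s];
        conn = mo;
      } else { // connector is a child
        bool fa_t = constpen[fa], mo_t = constpen[mo];
        if (mo_t && !fa_t) { std::swap(fa, mo); fa_t = true; }
        // others = children except conn
        int nothers = 0;
        if (nch - 1 == 0 && fa_t) {
          for (int s = 0; s < S; ++s) U[s] = V[(size_t)S * mo + s] * constval[fa];
          wk.transmit_single(U.data(), msg.data());
        } else {
          const double *vm = &V[(size_t)S * mo], *vf = &V[(size_t)S * fa];
          for (int sf = 0; sf < S; ++sf)
            for (int sm = 0; sm < S; ++sm) KP[sm + S * sf] = vm[sm] * vf[sf];
          for (int j = 0; j < nch; ++j) {
            if (ch[j] == conn) continue;
            ++nothers;
            wk.child_full(&V[(size_t)S * ch[j]], Kc.data());
            for (int s = 0; s < S * S; ++s) KP[s] *= Kc[s];
          }
          wk.transmit_couple(KP.data(), msg.data());
        }
        for (int s = 0; s < S; ++s) V[(size_t)S * conn + s] *= msg[s];
      }
      double m = 0.0;
      for (int s = 0; s < S; ++s) if (V[(size_t)S * conn + s] > m) m = V[(size_t)S * conn + s];
      if (!(m > 0.0) || !std::isfinite(m)) { zero = true; break; }
      for (int s = 0; s < S; ++s) V[(size_t)S * conn + s] /= m;
      logscale += std::log(m);
    }

    const int nleft = *c++;
    double loglik = logscale;
    if (!zero) {
      for (int j = 0; j < nleft; ++j) {
        int i = c[j];
        double tot = 0.0;
        for (int s = 0; s < S; ++s) tot += V[(size_t)S * i + s];
        if (!(tot > 0.0)) { zero = true; break; }
        if (f == posterior_family && i == root) {
          for (int s = 0; s < S; ++s) post[s] = V[(size_t)S * i + s];
          have_post = true;
        }
        loglik += std::log(tot);
      }
    }
    c += nleft;
    out(f, 0) = zero ? R_NegInf : loglik;
    // ascertainment denominator: proband phenotype (tests excluded)
    // under founder priors; PENden has one column per family
    double den = 0.0;
    const double *pp = &PENden(0, f);
    for (int s = 0; s < S; ++s) den += prior[s] * pp[s];
    out(f, 1) = den > 0.0 ? std::log(den) : R_NegInf;
    (void)proband;
  }
  if (have_post) out.attr("post") = post;
  return out;
}
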