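// Human ventricular myocyte membrane kinetics (O'Hara-Rudy dynamic model,
// epicardial and midmyocardial variants) and the MacCannell active-fibroblast
// model, implemented for explicit tissue integration with Rush-Larsen gate
// updates. Voltage-dependent steady states, Rush-Larsen decay factors and
// driving-force prefactors are tabulated on a fine voltage grid once per run
// (the table embeds dt), leaving only calcium-dependent exponentials in the
// per-node inner loop.

#include <Rcpp.h>
#include "ord.h"

using namespace Rcpp;

// physical constants and geometry
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Lcell = 0.01, rad = 0.0011;
static const double pi = 3.14159265358979323846;
static const double vcell = 1000.0 * pi * rad * rad * Lcell;
static const double Ageo = 2.0 * pi * rad * rad + 2.0 * pi * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
                    vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

CellParams ord_params(int celltype) {
  // base values are the endocardial set; epi/mid variants scale them
  CellParams p;
  p.GNa = 75.0;
  p.GNaL = 0.0075;
  p.Gto = 0.02;
  p.PCa = 0.0001;
  p.GKr = 0.046;
  p.GKs = 0.0034;
  p.GK1 = 0.1908;
  p.Gncx = 0.0008;
  p.Pnak = 30.0;
  p.GKb = 0.003;
  p.JupScale = 1.0;
  p.cmdnmax = 0.05;
  p.JrelScale = 1.0;
  p.epi_delta = false;
  if (celltype == CT_EPI) {
    p.GNaL *= 0.6;
    p.Gto *= 4.0;
    p.PCa *= 1.2;
    p.GKr *= 1.3;
    p.GKs *= 1.4;
    p.GK1 *= 1.2;
    p.Gncx *= 1.1;
    p.Pnak *= 0.9;
    p.GKb *= 0.6;
    p.JupScale = 1.3;
    p.cmdnmax *= 1.3;
    p.epi_delta = true;
  } else if (celltype == CT_MID) {
    p.Gto *= 4.0;
    p.PCa *= 2.5;
    p.GKr *= 0.8;
    p.GK1 *= 1.3;
    p.Gncx *= 1.4;
    p.Pnak *= 0.7;
    p.JrelScale = 1.7;
  }
  return p;
}

// table column indices
enum {
  C_em, C_ehf, C_ehs, C_ej, C_ehsp, C_ejp, C_ea, C_eiF, C_eiS, C_eiFp,
  C_eiSp, C_ed, C_eff, C_efs, C_efcaf, C_efcas, C_effp, C_efcafp, C_exrf,
  C_exrs, C_exs1, C_exs2, C_exk1,
  C_mss, C_hss, C_hssp, C_mLss, C_hLss, C_hLssp, C_ass, C_iss, C_assp,
  C_dss, C_fss, C_AiF, C_Afcaf, C_Axrf, C_xrss, C_xs1ss, C_xk1ss,
  C_rkr, C_rk1, C_xkb, C_hca, C_hna, C_Knai, C_Knao, C_ACa, C_BCa, C_ANa,
  C_BNa, C_Tmss, C_Tem, C_Thss, C_Teh, C_Tej, C_spare
};

OrdTab::OrdTab(int celltype, double dt_, bool ina_tp06_) {
  p = ord_params(celltype);
  dt = dt_;
  ina_tp06 = ina_tp06_;
  vmin = -150.0;
  vmax = 100.0;
  dv = 0.025;
  n = (int)std::floor((vmax - vmin) / dv) + 2;
  tab.assign((size_t)n * NCOL, 0.0);
  ehL = std::exp(-dt / 200.0);
  ehLp = std::exp(-dt / 600.0);
  ejca = std::exp(-dt / 75.0);
  const double frt = Frdy / (Rgas * Temp);

  for (int i = 0; i < n; ++i) {
    double v = vmin + i * dv;
    double *r = &tab[(size_t)i * NCOL];

    // INa gates
    r[C_mss] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                       8.552 * std::exp(-(v + 77.42) / 5.955));
    r[C_em] = std::exp(-dt / tm);
    r[C_hss] = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                        6.149 * std::exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                        0.3343 * std::exp((v + 5.730) / 56.66));
    r[C_ehf] = std::exp(-dt / thf);
    r[C_ehs] = std::exp(-dt / ths);
    double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                               0.3052 * std::exp((v + 0.9941) / 38.45));
    r[C_ej] = std::exp(-dt / tj);
    r[C_hssp] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
    r[C_ehsp] = std::exp(-dt / (3.0 * ths));
    r[C_ejp] = std::exp(-dt / (1.46 * tj));

    // INaL gates (tmL = tm)
    r[C_mLss] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
    r[C_hLss] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
    r[C_hLssp] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));

    // Ito
    r[C_ass] = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 /
        (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
         3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
    r[C_ea] = std::exp(-dt / ta);
    r[C_iss] = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
    double delta_epi = p.epi_delta
        ? 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0))
        : 1.0;
    double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                                0.08004 * std::exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * std::exp((v + 114.1) / 8.079));
    tiF *= delta_epi;
    tiS *= delta_epi;
    r[C_eiF] = std::exp(-dt / tiF);
    r[C_eiS] = std::exp(-dt / tiS);
    r[C_AiF] = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
    r[C_assp] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
    double dti_develop = 1.354 +
        1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                  std::exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
    r[C_eiFp] = std::exp(-dt / (dti_develop * dti_recover * tiF));
    r[C_eiSp] = std::exp(-dt / (dti_develop * dti_recover * tiS));

    // ICaL gates
    r[C_dss] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                             std::exp(0.09 * (v + 14.0)));
    r[C_ed] = std::exp(-dt / td);
    r[C_fss] = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                              0.0045 * std::exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                                 0.000035 * std::exp((v + 5.0) / 6.0));
    r[C_eff] = std::exp(-dt / tff);
    r[C_efs] = std::exp(-dt / tfs);
    double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                                0.04 * std::exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                  0.00012 * std::exp(v / 7.0));
    r[C_efcaf] = std::exp(-dt / tfcaf);
    r[C_efcas] = std::exp(-dt / tfcas);
    r[C_Afcaf] = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
    r[C_effp] = std::exp(-dt / (2.5 * tff));
    r[C_efcafp] = std::exp(-dt / (2.5 * tfcaf));

    // IKr
    r[C_xrss] = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                                 4.123e-5 * std::exp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                                 1.128e-5 * std::exp(-(v - 29.74) / 25.94));
    r[C_exrf] = std::exp(-dt / txrf);
    r[C_exrs] = std::exp(-dt / txrs);
    r[C_Axrf] = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
    r[C_rkr] = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
               1.0 / (1.0 + std::exp((v - 10.0) / 30.0));

    // IKs
    r[C_xs1ss] = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 +
        1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
               0.001292 * std::exp(-(v + 210.0) / 230.0));
    double txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                         0.0193 * std::exp(-(v + 66.54) / 31.0));
    r[C_exs1] = std::exp(-dt / txs1);
    r[C_exs2] = std::exp(-dt / txs2);

    // IK1
    r[C_xk1ss] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                       (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                           std::exp((v + 236.8) / 69.33));
    r[C_exk1] = std::exp(-dt / txk1);
    r[C_rk1] = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));

    r[C_xkb] = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));

    // INaCa / INaK voltage factors
    r[C_hca] = std::exp(0.1670 * v * frt);
    r[C_hna] = std::exp(0.5224 * v * frt);
    r[C_Knai] = 9.073 * std::exp(-0.1550 * v * frt / 3.0);
    r[C_Knao] = 27.78 * std::exp((1.0 + 0.1550) * v * frt / 3.0);

    // GHK driving-force prefactors
    double vfrt = v * frt;
    double vffrt = v * Frdy * frt;
    if (std::fabs(vfrt) < 1e-7) {
      r[C_ACa] = 2.0 * Frdy;
      r[C_BCa] = 1.0;
      r[C_ANa] = Frdy;
      r[C_BNa] = 1.0;
    } else {
      double e1 = std::exp(vfrt), e2 = std::exp(2.0 * vfrt);
      r[C_ACa] = 4.0 * vffrt / (e2 - 1.0);
      r[C_BCa] = e2;
      r[C_ANa] = vffrt / (e1 - 1.0);
      r[C_BNa] = e1;
    }

    // ten Tusscher-Panfilov INa gate functions (conduction-calibrated INa)
    {
      double mi = 1.0 / (1.0 + std::exp((-56.86 - v) / 9.03));
      r[C_Tmss] = mi * mi;
      double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
      double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
                  0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
      r[C_Tem] = std::exp(-dt / (am * bm));
      double hi = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
      r[C_Thss] = hi * hi;
      double ah, bh, aj, bj;
      if (v < -40.0) {
        ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
        bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
        aj = (-2.5428e4 * std::exp(0.2444 * v) -
              6.948e-6 * std::exp(-0.04391 * v)) *
             (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
        bj = 0.02424 * std::exp(-0.01052 * v) /
             (1.0 + std::exp(-0.1378 * (v + 40.14)));
      } else {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
      }
      r[C_Teh] = std::exp(-dt * (ah + bh));
      r[C_Tej] = std::exp(-dt * (aj + bj));
    }
    r[C_spare] = 0.0;
  }
}

static inline double rl(double g, double inf, double e) {
  return inf - (inf - g) * e;
}

double ord_step(double *X, const OrdTab &T, double Ist) {
  const double dt = T.dt;
  const CellParams &p = T.p;
  double v = X[0];
  double nai = X[1], nass = X[2], ki = X[3], kss = X[4];
  double cai = X[5], cass = X[6], cansr = X[7], cajsr = X[8];

  const double *a_, *b_;
  double w;
  T.lookup(v, a_, b_, w);
#define TB(c) (a_[c] + w * (b_[c] - a_[c]))

  // CaMK
  const double KmCaMK = 0.15;
  double CaMKb = 0.05 * (1.0 - X[40]) / (1.0 + 0.0015 / cass);
  double CaMKa = CaMKb + X[40];
  double fp = 1.0 / (1.0 + KmCaMK / CaMKa);  // phosphorylated fraction

  const double rtf = Rgas * Temp / Frdy;
  double ENa = rtf * std::log(nao / nai);
  double EK = rtf * std::log(ko / ki);
  double EKs = rtf * std::log((ko + 0.01833 * nao) / (ki + 0.01833 * nai));

  // INa (original formulation or conduction-calibrated TP06 kinetics;
  // the TP06 variant reuses slots 9 (m), 10 (h), 12 (j))
  double INa;
  if (T.ina_tp06) {
    double m3 = X[9] * X[9] * X[9];
    INa = 14.838 * m3 * X[10] * X[12] * (v - ENa);
  } else {
    double h = 0.99 * X[10] + 0.01 * X[11];
    double hp = 0.99 * X[10] + 0.01 * X[13];
    double m3 = X[9] * X[9] * X[9];
    INa = p.GNa * (v - ENa) * m3 *
          ((1.0 - fp) * h * X[12] + fp * hp * X[14]);
  }

  // INaL
  double INaL = p.GNaL * (v - ENa) * X[15] *
                ((1.0 - fp) * X[16] + fp * X[17]);

  // Ito
  double AiF = TB(C_AiF);
  double i_ = AiF * X[19] + (1.0 - AiF) * X[20];
  double ip = AiF * X[22] + (1.0 - AiF) * X[23];
  double Ito = p.Gto * (v - EK) * ((1.0 - fp) * X[18] * i_ + fp * X[21] * ip);

  // ICaL / ICaNa / ICaK
  double f = 0.6 * X[25] + 0.4 * X[26];
  double Afcaf = TB(C_Afcaf);
  double fca = Afcaf * X[27] + (1.0 - Afcaf) * X[28];
  double fpgate = 0.6 * X[31] + 0.4 * X[26];
  double fcap = Afcaf * X[32] + (1.0 - Afcaf) * X[28];
  double jca = X[29], nca = X[30], d = X[24];
  double ACa = TB(C_ACa), BCa = TB(C_BCa), ANa = TB(C_ANa), BNa = TB(C_BNa);
  double PhiCaL = ACa * (cass * BCa - 0.341 * cao);
  double PhiCaNa = ANa * (0.75 * nass * BNa - 0.75 * nao);
  double PhiCaK = ANa * (0.75 * kss * BNa - 0.75 * ko);
  double PCa = p.PCa, PCap = 1.1 * PCa;
  double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  double gl = d * (f * (1.0 - nca) + jca * fca * nca);
  double glp = d * (fpgate * (1.0 - nca) + jca * fcap * nca);
  double ICaL = (1.0 - fp) * PCa * PhiCaL * gl + fp * PCap * PhiCaL * glp;
  double ICaNa = (1.0 - fp) * PCaNa * PhiCaNa * gl + fp * PCaNap * PhiCaNa * glp;
  double ICaK = (1.0 - fp) * PCaK * PhiCaK * gl + fp * PCaKp * PhiCaK * glp;

  // IKr
  double Axrf = TB(C_Axrf);
  double xr = Axrf * X[33] + (1.0 - Axrf) * X[34];
  double IKr = p.GKr * xr * TB(C_rkr) * (v - EK);  // sqrt(ko/5.4) = 1

  // IKs
  double c14 = 3.8e-5 / cai;
  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(c14, 1.4));
  double IKs = p.GKs * KsCa * X[35] * X[36] * (v - EKs);

  // IK1
  double IK1 = p.GK1 * std::sqrt(ko) * TB(C_rk1) * X[37] * (v - EK);

  // INaCa (myoplasmic and subspace components)
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3, KmCaAct = 150.0e-6;
  double hca = TB(C_hca), hna = TB(C_hna);
  double INaCa_i, INaCa_ss;
  {
    double na = nai, ca = cai;
    for (int part = 0; part < 2; ++part) {
      double h1 = 1.0 + na / kna3 * (1.0 + hna);
      double h2 = (na * hna) / (kna3 * h1);
      double h3 = 1.0 / h1;
      double h4 = 1.0 + na / kna1 * (1.0 + na / kna2);
      double h5 = na * na / (h4 * kna1 * kna2);
      double h6 = 1.0 / h4;
      double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
      double h8 = nao / (kna3 * hna * h7);
      double h9 = 1.0 / h7;
      double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
      double h11 = nao * nao / (h10 * kna1 * kna2);
      double h12 = 1.0 / h10;
      double k1 = h12 * cao * kcaon;
      double k2 = kcaoff;
      double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
      double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
      double k5 = kcaoff;
      double k6 = h6 * ca * kcaon;
      double k7 = h5 * h2 * wna;
      double k8 = h8 * h11 * wna;
      double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
      double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
      double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
      double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
      double s = x1 + x2 + x3 + x4;
      double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
      double kact = KmCaAct / ca;
      double allo = 1.0 / (1.0 + kact * kact);
      double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
      double JncxCa = E2 * k2 - E1 * k1;
      double val = p.Gncx * allo * (JncxNa + 2.0 * JncxCa);
      if (part == 0) {
        INaCa_i = 0.8 * val;
        na = nass;
        ca = cass;
      } else {
        INaCa_ss = 0.2 * val;
      }
    }
  }

  // INaK
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    const double Kmgatp = 1.698e-7, Hp = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
    const double Knap = 224.0, Kxkur = 292.0;
    double Knai = TB(C_Knai), Knao = TB(C_Knao);
    double P = eP / (1.0 + Hp / Khp + nai / Knap + ki / Kxkur);
    double yn = nai / Knai, yk = ki / Kki;
    double d1 = (1.0 + yn) * (1.0 + yn) * (1.0 + yn) +
                (1.0 + yk) * (1.0 + yk) - 1.0;
    double a1 = k1p * yn * yn * yn / d1;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double zn = nao / Knao, zk = ko / Kko;
    double d2 = (1.0 + zn) * (1.0 + zn) * (1.0 + zn) +
                (1.0 + zk) * (1.0 + zk) - 1.0;
    double b2 = k2m * zn * zn * zn / d2;
    double a3 = k3p * zk * zk / d2;
    double b3 = k3m * P * Hp / (1.0 + MgATP / Kmgatp);
    double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * yk * yk / d1;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    INaK = p.Pnak * (JnakNa + JnakK);
  }

  double IKb = p.GKb * TB(C_xkb) * (v - EK);
  double INab = 3.75e-10 * ANa * (nai * BNa - nao);
  double ICab = 2.5e-8 * ACa * (cai * BCa - 0.341 * cao);
  double IpCa = 0.0005 * cai / (0.0005 + cai);

  double Iion = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab;

  // fluxes
  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  double Jdiff = (cass - cai) / 0.2;

  const double bt = 4.75;
  double cajsr8;
  {
    double x = 1.5 / cajsr;
    double x2 = x * x, x4 = x2 * x2;
    cajsr8 = x4 * x4;
  }
  double Jrel_inf = p.JrelScale * 0.5 * bt * (-ICaL) / (1.0 + cajsr8);
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt;
  double Jrel_infp = p.JrelScale * 0.5 * btp * (-ICaL) / (1.0 + cajsr8);
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  double Jrel = (1.0 - fp) * X[38] + fp * X[39];

  double Jupnp = p.JupScale * 0.004375 * cai / (cai + 0.00092);
  double Jupp = p.JupScale * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  double Jleak = 0.0039375 * cansr / 15.0;
  double Jup = (1.0 - fp) * Jupnp + fp * Jupp - Jleak;
  double Jtr = (cansr - cajsr) / 100.0;

  // concentration updates (forward Euler)
  double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
                    (Frdy * vmyo) + JdiffNa * vss / vmyo;
  double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  double dki = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) * Acap /
                   (Frdy * vmyo) + JdiffK * vss / vmyo;
  double dkss = -ICaK * Acap / (Frdy * vss) - JdiffK;
  double t1 = 0.00238 + cai, t2 = 0.0005 + cai;
  double Bcai = 1.0 / (1.0 + p.cmdnmax * 0.00238 / (t1 * t1) +
                       0.07 * 0.0005 / (t2 * t2));
  double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                            (2.0 * Frdy * vmyo) -
                        Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  double s1 = 0.00087 + cass, s2 = 0.0087 + cass;
  double Bcass = 1.0 / (1.0 + 0.047 * 0.00087 / (s1 * s1) +
                        1.124 * 0.0087 / (s2 * s2));
  double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                          Jrel * vjsr / vss - Jdiff);
  double dcansr = Jup - Jtr * vjsr / vnsr;
  double j1 = 0.8 + cajsr;
  double Bcajsr = 1.0 / (1.0 + 10.0 * 0.8 / (j1 * j1));
  double dcajsr = Bcajsr * (Jtr - Jrel);

  X[1] = nai + dt * dnai;
  X[2] = nass + dt * dnass;
  X[3] = ki + dt * dki;
  X[4] = kss + dt * dkss;
  X[5] = cai + dt * dcai;
  X[6] = cass + dt * dcass;
  X[7] = cansr + dt * dcansr;
  X[8] = cajsr + dt * dcajsr;

  // Rush-Larsen gate updates
  if (T.ina_tp06) {
    double thss = TB(C_Thss);
    X[9] = rl(X[9], TB(C_Tmss), TB(C_Tem));
    X[10] = rl(X[10], thss, TB(C_Teh));
    X[12] = rl(X[12], thss, TB(C_Tej));
  } else {
    double mss = TB(C_mss), hss = TB(C_hss), hssp = TB(C_hssp);
    X[9] = rl(X[9], mss, TB(C_em));
    X[10] = rl(X[10], hss, TB(C_ehf));
    X[11] = rl(X[11], hss, TB(C_ehs));
    X[12] = rl(X[12], hss, TB(C_ej));
    X[13] = rl(X[13], hssp, TB(C_ehsp));
    X[14] = rl(X[14], hss, TB(C_ejp));
  }
  X[15] = rl(X[15], TB(C_mLss), TB(C_em));
  X[16] = rl(X[16], TB(C_hLss), T.ehL);
  X[17] = rl(X[17], TB(C_hLssp), T.ehLp);
  double ass = TB(C_ass), iss = TB(C_iss), assp = TB(C_assp);
  X[18] = rl(X[18], ass, TB(C_ea));
  X[19] = rl(X[19], iss, TB(C_eiF));
  X[20] = rl(X[20], iss, TB(C_eiS));
  X[21] = rl(X[21], assp, TB(C_ea));
  X[22] = rl(X[22], iss, TB(C_eiFp));
  X[23] = rl(X[23], iss, TB(C_eiSp));
  double dss = TB(C_dss), fss = TB(C_fss);
  X[24] = rl(X[24], dss, TB(C_ed));
  X[25] = rl(X[25], fss, TB(C_eff));
  X[26] = rl(X[26], fss, TB(C_efs));
  X[27] = rl(X[27], fss, TB(C_efcaf));
  X[28] = rl(X[28], fss, TB(C_efcas));
  X[29] = rl(X[29], fss, T.ejca);
  X[31] = rl(X[31], fss, TB(C_effp));
  X[32] = rl(X[32], fss, TB(C_efcafp));
  X[33] = rl(X[33], TB(C_xrss), TB(C_exrf));
  X[34] = rl(X[34], TB(C_xrss), TB(C_exrs));
  X[35] = rl(X[35], TB(C_xs1ss), TB(C_exs1));
  X[36] = rl(X[36], TB(C_xs1ss), TB(C_exs2));
  X[37] = rl(X[37], TB(C_xk1ss), TB(C_exk1));

  // nca (forward Euler) and CaMK trapping
  {
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double q = 1.0 + Kmn / cass;
    double q2 = q * q;
    double anca = 1.0 / (k2n / km2n + q2 * q2);
    X[30] = nca + dt * (anca * k2n - nca * km2n);
  }
  X[38] = rl(X[38], Jrel_inf, std::exp(-dt / tau_rel));
  X[39] = rl(X[39], Jrel_infp, std::exp(-dt / tau_relp));
  X[40] = X[40] + dt * (0.05 * CaMKb * (CaMKb + X[40]) - 0.00068 * X[40]);

#undef TB
  return Iion;
}

// ---------------------------------------------------------------------------
// MacCannell active fibroblast (Kv, inward-rectifier K+, Na+/K+ pump,
// background Na+), fixed intracellular concentrations.
static const double fib_Ki = 129.4349, fib_Nai = 8.5547;

double fib_step(double *X, double dt) {
  const double rtf = Rgas * Temp / Frdy;
  double v = X[0];
  double EK = rtf * std::log(ko / fib_Ki);
  double ENa = rtf * std::log(nao / fib_Nai);

  double IKv = 0.25 * X[1] * X[2] * (v - EK);
  double vk = v - EK;
  double alpha = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
  double beta = (3.0 * std::exp(0.0002 * (vk + 100.0)) +
                 std::exp(0.1 * (vk - 10.0))) /
                (1.0 + std::exp(-0.5 * vk));
  double IK1 = 0.4822 * alpha / (alpha + beta) * vk;
  double na15 = std::pow(fib_Nai, 1.5);
  double INaK = 2.002 * (ko / (ko + 1.0)) * (na15 / (na15 + std::pow(11.0, 1.5))) *
                (v + 150.0) / (v + 200.0);
  double IbNa = 0.0095 * (v - ENa);

  double rinf = 1.0 / (1.0 + std::exp(-(v + 20.0) / 11.0));
  double zr = (v + 20.0) / 25.9;
  double taur = 20.3 + 138.0 * std::exp(-zr * zr);
  double sinf = 1.0 / (1.0 + std::exp((v + 23.0) / 7.0));
  double zs = (v + 23.0) / 22.7;
  double taus = 1574.0 + 5268.0 * std::exp(-zs * zs);
  X[1] = rl(X[1], rinf, std::exp(-dt / taur));
  X[2] = rl(X[2], sinf, std::exp(-dt / taus));

  return IKv + IK1 + INaK + IbNa;
}

void ord_default_state(double *X) {
  static const double init[ORD_NSTATE] = {
      -87.0, 7.0, 7.0, 145.0, 145.0, 1.0e-4, 1.0e-4, 1.2, 1.2,
      0.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.0, 1.0, 1.0,
      0.0, 1.0, 1.0, 0.0, 1.0, 1.0,
      0.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.0, 1.0, 1.0,
      0.0, 0.0, 0.0, 0.0, 1.0,
      0.0, 0.0, 0.0};
  for (int i = 0; i < ORD_NSTATE; ++i) X[i] = init[i];
}

void fib_default_state(double *X) {
  X[0] = -49.6;
  X[1] = 0.0;
  X[2] = 1.0;
}

// ---------------------------------------------------------------------------
// Single-cell harness

static CharacterVector ord_state_names() {
  return CharacterVector::create(
      "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
      "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
      "a", "iF", "iS", "ap", "iFp", "iSp",
      "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
      "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt");
}

// [[Rcpp::export]]
NumericVector ord_initial_state_cpp() {
  NumericVector out(ORD_NSTATE);
  ord_default_state(&out[0]);
  out.attr("names") = ord_state_names();
  return out;
}

// [[Rcpp::export]]
NumericVector fib_initial_state_cpp() {
  NumericVector out(FIB_NSTATE);
  fib_default_state(&out[0]);
  out.attr("names") = CharacterVector::create("v", "r", "s");
  return out;
}

// Pace a single myocyte at a fixed cycle length; record the last
// `record_beats` beats at `out_dt` resolution.
// [[Rcpp::export]]
List ord_pace_cpp(NumericVector state, int celltype, double cl, int nbeats,
                  double dt, double stim_amp, double stim_dur,
                  int record_beats, double out_dt, bool ina_tp06) {
  if (state.size() != ORD_NSTATE) stop("bad state length");
  std::vector<double> X(state.begin(), state.end());
  OrdTab T(celltype, dt, ina_tp06);
  long nstep_beat = (long)std::llround(cl / dt);
  long rec_from = (long)(nbeats - record_beats) * nstep_beat;
  long nstep = (long)nbeats * nstep_beat;
  int thin = std::max(1, (int)std::llround(out_dt / dt));
  std::vector<double> tv, vv, caiv;
  tv.reserve(record_beats > 0 ? (nstep - rec_from) / thin + 2 : 0);

  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    double tb = std::fmod(t, cl);
    double Ist = (tb < stim_dur) ? -stim_amp : 0.0;
    if (record_beats > 0 && s >= rec_from && (s - rec_from) % thin == 0) {
      tv.push_back(t);
      vv.push_back(X[0]);
      caiv.push_back(X[5]);
    }
    double Iion = ord_step(&X[0], T, Ist);
    X[0] += dt * (-Iion - Ist);
    if (!(X[0] > -200.0 && X[0] < 200.0))
      stop("membrane potential out of bounds at step %ld (t = %.3f ms)", s, t);
  }
  NumericVector fin(X.begin(), X.end());
  fin.attr("names") = ord_state_names();
  return List::create(_["time"] = tv, _["v"] = vv, _["cai"] = caiv,
                      _["state"] = fin);
}

// Free-running (or stimulated) fibroblast trace.
// [[Rcpp::export]]
List fib_run_cpp(NumericVector state, double duration, double dt,
                 double stim_amp, double stim_dur, double stim_t0,
                 double out_dt) {
  if (state.size() != FIB_NSTATE) stop("bad state length");
  std::vector<double> X(state.begin(), state.end());
  long nstep = (long)std::llround(duration / dt);
  int thin = std::max(1, (int)std::llround(out_dt / dt));
  std::vector<double> tv, vv;
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    double Ist = (t >= stim_t0 && t < stim_t0 + stim_dur) ? -stim_amp : 0.0;
    if (s % thin == 0) {
      tv.push_back(t);
      vv.push_back(X[0]);
    }
    double Iion = fib_step(&X[0], dt);
    X[0] += dt * (-Iion - Ist);
    if (!(X[0] > -200.0 && X[0] < 200.0))
      stop("fibroblast potential out of bounds at t = %.3f ms", t);
  }
  NumericVector fin(X.begin(), X.end());
  fin.attr("names") = CharacterVector::create("v", "r", "s");
  return List::create(_["time"] = tv, _["v"] = vv, _["state"] = fin);
}
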