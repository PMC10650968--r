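#ifndef CX43EP_ORD_H
#define CX43EP_ORD_H

#include <vector>
#include <cmath>

// State layout for the human ventricular myocyte model (41 variables).
// 0  v      9  m     18 a     24 d      33 xrf   38 Jrelnp
// 1  nai    10 hf    19 iF    25 ff     34 xrs   39 Jrelp
// 2  nass   11 hs    20 iS    26 fs     35 xs1   40 CaMKt
// 3  ki     12 j     21 ap    27 fcaf   36 xs2
// 4  kss    13 hsp   22 iFp   28 fcas   37 xk1
// 5  cai    14 jp    23 iSp   29 jca
// 6  cass   15 mL           30 nca
// 7  cansr  16 hL           31 ffp
// 8  cajsr  17 hLp          32 fcafp
#define ORD_NSTATE 41

// Fibroblast state: 0 v, 1 r (Kv activation), 2 s (Kv inactivation)
#define FIB_NSTATE 3

// Cell variants
#define CT_EPI 0
#define CT_MID 1
#define CT_FIB 2

struct CellParams {
  double GNa, GNaL, Gto, PCa, GKr, GKs, GK1, Gncx, Pnak, GKb;
  double JupScale, cmdnmax, JrelScale;
  bool epi_delta;
};

CellParams ord_params(int celltype);

// Voltage lookup table of steady states, Rush-Larsen decay factors (for a
// fixed dt) and voltage-dependent current factors, per cell variant.
class OrdTab {
public:
  // ina_tp06: use the ten Tusscher-Panfilov INa formulation (conduction-
  // calibrated variant) in place of the original INa
  OrdTab(int celltype, double dt, bool ina_tp06);
  double vmin, vmax, dv;
  int n;
  std::vector<double> tab;   // n rows x NCOL, row-major
  double ehL, ehLp, ejca;    // constant-tau decay factors
  double dt;
  CellParams p;
  bool ina_tp06;

  static const int NCOL = 57;

  inline void lookup(double v, const double *&r0, const double *&r1,
                     double &w) const {
    double x = (v - vmin) / dv;
    if (x < 0) x = 0;
    if (x > n - 1.000001) x = n - 1.000001;
    int i = (int)x;
    w = x - i;
    r0 = &tab[(size_t)i * NCOL];
    r1 = r0 + NCOL;
  }
};

// Advance gates/concentrations of X by dt and return the total ionic current
// Iion (uA/uF) evaluated at the pre-step state. The caller updates X[0] (v):
//   v += dt * (diffusion - Iion - Ist)
// Ist (uA/uF, negative = depolarizing) enters the K+ balance.
double ord_step(double *X, const OrdTab &T, double Ist);

double fib_step(double *X, double dt);

void ord_default_state(double *X);
void fib_default_state(double *X);

#endif
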