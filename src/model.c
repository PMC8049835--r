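/* Compiled right-hand sides for the memristive pre-BotC model, used through
 * deSolve's compiled-model interface.  The parameter layout must match
 * .par_order_full / .par_order_fast in R/params.R exactly. */

#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

enum {
  iC, iSIGMA, iGNA, iGK, iGL, iGNAP, iGTONIC, iGCAN,
  iVNA, iVK, iVL, iVSYN,
  iTHM, iTHMP, iTHN, iTHH, iSM, iSMP, iSN, iSH,
  iTAUN, iTAUH,
  iKCAN, iNCAN, iIP3, iLIP3, iPIP3, iKI, iKA, iKD,
  iCATOT, iKCA, iVSERCA, iKSERCA, iA,
  iIEXTZ, iK1, iK2, iALPHA, iBETA,
  NPAR_FULL,
  iHFROZEN = NPAR_FULL, iGCANTOT, NPAR_FAST
};

static double par[NPAR_FAST];

void prebotc_init_full(void (*odeparms)(int *, double *))
{
  int n = NPAR_FULL;
  odeparms(&n, par);
}

void prebotc_init_fast(void (*odeparms)(int *, double *))
{
  int n = NPAR_FAST;
  odeparms(&n, par);
}

static double xinf(double V, double th, double s)
{
  return 1.0 / (1.0 + exp((V - th) / s));
}

static double taux(double V, double tb, double th, double s)
{
  return tb / cosh((V - th) / (2.0 * s));
}

/* membrane + gate + flux derivatives shared by the full and fast systems;
 * ICAN enters as an effective conductance gcantot = gCAN * f([Ca]) */
static void vnphi_rhs(double V, double n, double phi, double h,
                      double gcantot, double *dV, double *dn, double *dphi)
{
  double INa, IK, IL, INaP, ICAN, Iton, rho;

  INa  = par[iGNA] * pow(xinf(V, par[iTHM], par[iSM]), 3.0) * (1.0 - n) * (V - par[iVNA]);
  IK   = par[iGK] * pow(n, 4.0) * (V - par[iVK]);
  IL   = par[iGL] * (V - par[iVL]);
  INaP = par[iGNAP] * xinf(V, par[iTHMP], par[iSMP]) * h * (V - par[iVNA]);
  ICAN = gcantot * (V - par[iVNA]);
  Iton = par[iGTONIC] * (V - par[iVSYN]);
  rho  = par[iALPHA] + 3.0 * par[iBETA] * phi * phi;

  *dV   = (-INa - IK - IL - INaP - Iton - ICAN + par[iIEXTZ]
           - par[iK1] * V * rho) / par[iC];
  *dn   = (xinf(V, par[iTHN], par[iSN]) - n) / taux(V, par[iTAUN], par[iTHN], par[iSN]);
  *dphi = V - par[iK2] * phi;
}

static void calcium_rhs(double Ca, double l, double *dCa, double *dl)
{
  double G, CaER, JIN, JOUT;

  G    = par[iIP3] * Ca / ((par[iIP3] + par[iKI]) * (Ca + par[iKA]));
  CaER = (par[iCATOT] - Ca) / par[iSIGMA];
  JIN  = (par[iLIP3] + par[iPIP3] * pow(G * l, 3.0)) * (CaER - Ca);
  JOUT = par[iVSERCA] * Ca * Ca / (par[iKSERCA] * par[iKSERCA] + Ca * Ca);

  *dCa = par[iKCA] * (JIN - JOUT);
  *dl  = par[iA] * par[iKD] * (1.0 - l) - par[iA] * Ca * l;
}

/* y = (V, n, h, phi, Ca, l) */
void prebotc_deriv_full(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
  double fCa, dh;

  fCa = 1.0 / (1.0 + pow(par[iKCAN] / y[4], par[iNCAN]));
  vnphi_rhs(y[0], y[1], y[3], y[2], par[iGCAN] * fCa, &ydot[0], &ydot[1], &ydot[3]);
  dh = (xinf(y[0], par[iTHH], par[iSH]) - y[2]) / taux(y[0], par[iTAUH], par[iTHH], par[iSH]);
  ydot[2] = dh;
  calcium_rhs(y[4], y[5], &ydot[4], &ydot[5]);
}

/* y = (V, n, phi) with h and gCANTot frozen */
void prebotc_deriv_fast(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
  vnphi_rhs(y[0], y[1], y[2], par[iHFROZEN], par[iGCANTOT],
            &ydot[0], &ydot[1], &ydot[2]);
}

/* y = (Ca, l); independent of the electrical variables */
void prebotc_deriv_ca(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
  calcium_rhs(y[0], y[1], &ydot[0], &ydot[1]);
}

static const R_CMethodDef CEntries[] = {
  {"prebotc_init_full",  (DL_FUNC) &prebotc_init_full,  0},
  {"prebotc_init_fast",  (DL_FUNC) &prebotc_init_fast,  0},
  {"prebotc_deriv_full", (DL_FUNC) &prebotc_deriv_full, 0},
  {"prebotc_deriv_fast", (DL_FUNC) &prebotc_deriv_fast, 0},
  {"prebotc_deriv_ca",   (DL_FUNC) &prebotc_deriv_ca,   0},
  {NULL, NULL, 0}
};

void R_init_prebotc(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
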