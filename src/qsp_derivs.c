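/* Renal potassium handling with aldosterone feedback and canrenone PK.
 *
 * States (amounts unless noted):
 *   y[0]  K_ecf        extracellular potassium, mEq
 *   y[1]  K_icf        intracellular potassium, mEq
 *   y[2]  K_cell       principal-cell (CNT/CCD) potassium, mEq
 *   y[3]  lumen_PT     PT/LoH luminal potassium, mEq
 *   y[4]  lumen_DCT    DCT luminal potassium, mEq
 *   y[5]  lumen_CNT    CNT/CCD luminal potassium, mEq
 *   y[6]  lumen_MCD    MCD luminal potassium, mEq
 *   y[7]  K_excreted   cumulative urinary potassium, mEq
 *   y[8]  aldo         plasma aldosterone, arbitrary conc. units
 *   y[9]  K_gut        oral-supplement potassium depot, mEq
 *   y[10] cren_gut     canrenone absorption depot, mg
 *   y[11] cren_c       canrenone central compartment, mg
 *   y[12] cren_p       canrenone peripheral compartment, mg
 *
 * Time unit is minutes throughout; concentrations are mEq/L (potassium),
 * mg/L (canrenone).  The parameter vector layout is shared with R
 * (see qsp_parm_names() in R/parameters.R) and must stay in sync.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 45
#define N_STATES 13
#define N_OUT 12

static double p[N_PARMS];

/* primary parameters */
#define P_KIN          p[0]
#define P_NAIN         p[1]
#define P_NORM_K       p[2]
#define P_VECF         p[3]
#define P_MR           p[4]
#define P_HYPERALDO    p[5]
#define P_M_K_ALDO     p[6]
#define P_ALDO_KSEC    p[7]   /* exponent of the aldosterone signal on secretion */
#define P_M_K_MCD      p[8]
#define P_R0_MCD       p[9]   /* mEq/min/nephron */
#define P_GFR          p[10]
#define P_N_NEPH       p[11]
#define P_NORM_NA      p[12]
#define P_K_ECF_ICF    p[13]
#define P_ALDO_NORM    p[14]
/* canrenone PK and effect */
#define P_PK_KA        p[15]
#define P_PK_CL        p[16]
#define P_PK_VC        p[17]
#define P_PK_Q         p[18]
#define P_PK_VP        p[19]
#define P_EMAX         p[20]
#define P_EC50         p[21]
/* structural constants */
#define P_PHI_MR       p[22]  /* aldosterone/MR-dependent fraction of distal uptake */
#define P_F_PT         p[23]
#define P_F_DCT        p[24]
#define P_K_PT         p[25]
#define P_K_DCT        p[26]
#define P_K_CNT        p[27]
#define P_K_MCD        p[28]
#define P_K_ALDO_TURN  p[29]
#define P_S_NAIN_ALDO  p[30]
#define P_S_NA_ALDO    p[31]
#define P_K_ALDO_OFFS  p[32]  /* offset of the aldosterone K setpoint, mEq/L */
#define P_KA_GUT_K     p[33]
#define P_ICF_REF      p[34]
#define P_CELL_REF     p[35]
/* calibration-derived constants (set by build_nominal_parameters) */
#define P_U0_CAL       p[36]  /* nominal distal uptake, mEq/min (whole kidney) */
#define P_KSECR_CAL    p[37]
#define P_KICFECF_CAL  p[38]
#define P_MCD_REF      p[39]
#define P_NNEPH_REF    p[40]
#define P_GFR_REF      p[41]
#define P_NAIN_REF     p[42]
#define P_NA_REF       p[43]
#define P_ALDO_PRODSC  p[44]  /* exp(m_K_ALDO_nominal * offset) */

void spirok_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void spirok_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double K, dK, conc, block, mr_av, aldo_rel, sig, g, sN, snGFR;
    double filt, U, S, outPT, reabPT, toDCT, outDCT, reabDCT, toCNT;
    double toMCD, h, reabMCD, urine, absK, toICF, toECF, prod;

    if (ip[0] < N_OUT) error("nout should be at least %d", N_OUT);

    K  = y[0] / P_VECF * 1000.0;      /* mEq/L */
    dK = K - P_NORM_K;

    conc  = y[11] / P_PK_VC;          /* mg/L */
    block = P_EMAX * conc / (P_EC50 + conc);
    mr_av = P_MR * (1.0 - block);

    aldo_rel = y[8] / P_ALDO_NORM;
    if (aldo_rel < 1e-9) aldo_rel = 1e-9;
    sig = mr_av * pow(aldo_rel, P_ALDO_KSEC);
    g   = (1.0 - P_PHI_MR) + P_PHI_MR * sig;

    sN    = P_N_NEPH / P_NNEPH_REF;
    snGFR = P_GFR / P_N_NEPH;                 /* single-nephron GFR */
    filt  = snGFR * P_N_NEPH * K / 1000.0;    /* mEq/min */

    /* distal (CNT/CCD) basolateral uptake and apical secretion */
    U = sN * P_U0_CAL * (K / P_NORM_K) * g;
    S = P_KSECR_CAL * y[2];

    outPT  = P_K_PT * y[3];
    reabPT = P_F_PT * outPT;
    toDCT  = (1.0 - P_F_PT) * outPT;

    outDCT  = P_K_DCT * y[4];
    reabDCT = P_F_DCT * outDCT;
    toCNT   = (1.0 - P_F_DCT) * outDCT;

    toMCD = P_K_CNT * y[5];

    h = 1.0 + P_M_K_MCD * dK;
    if (h < 0.05) h = 0.05;
    reabMCD = sN * P_NNEPH_REF * P_R0_MCD * (y[6] / P_MCD_REF) * h;
    urine   = P_K_MCD * y[6];

    absK  = P_KA_GUT_K * y[9];
    toICF = P_K_ECF_ICF * y[0];
    toECF = P_KICFECF_CAL * y[1];

    prod = P_K_ALDO_TURN * P_ALDO_NORM * (1.0 + P_HYPERALDO)
         * exp(P_M_K_ALDO * (dK + P_K_ALDO_OFFS)) / P_ALDO_PRODSC
         * pow(P_NAIN / P_NAIN_REF, -P_S_NAIN_ALDO)
         * pow(P_NORM_NA / P_NA_REF, -P_S_NA_ALDO);

    ydot[0]  = P_KIN + absK + reabPT + reabDCT + reabMCD + toECF
             - toICF - filt - U;
    ydot[1]  = toICF - toECF;
    ydot[2]  = U - S;
    ydot[3]  = filt - outPT;
    ydot[4]  = toDCT - outDCT;
    ydot[5]  = toCNT + S - P_K_CNT * y[5];
    ydot[6]  = toMCD - reabMCD - urine;
    ydot[7]  = urine;
    ydot[8]  = prod - P_K_ALDO_TURN * y[8];
    ydot[9]  = -absK;
    ydot[10] = -P_PK_KA * y[10];
    ydot[11] = P_PK_KA * y[10]
             - (P_PK_CL / P_PK_VC) * y[11]
             - (P_PK_Q / P_PK_VC) * y[11] + (P_PK_Q / P_PK_VP) * y[12];
    ydot[12] = (P_PK_Q / P_PK_VC) * y[11] - (P_PK_Q / P_PK_VP) * y[12];

    yout[0]  = K;         /* plasma K, mEq/L */
    yout[1]  = urine;     /* urinary flux, mEq/min */
    yout[2]  = S;         /* distal secretion, mEq/min */
    yout[3]  = U;         /* distal uptake, mEq/min */
    yout[4]  = filt;      /* filtration, mEq/min */
    yout[5]  = reabPT;
    yout[6]  = reabDCT;
    yout[7]  = reabMCD;
    yout[8]  = conc;      /* canrenone central conc, mg/L */
    yout[9]  = block;     /* fractional MR blockade */
    yout[10] = g;         /* distal transport gain */
    yout[11] = y[8];      /* aldosterone */
}
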