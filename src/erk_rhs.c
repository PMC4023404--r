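#include <math.h>

/* Compartmental ERK shuttling/substrate-buffering model, deSolve compiled-rhs
 * interface.  Parameter vector layout must match .erk_parm_order in R/params.R.
 *
 * States (amounts; ERK/substrate pools as fractions of total cellular ERK):
 *  0 M0  1 M1  2 M2  3 D
 *  4 E0c 5 E1c 6 E2c 7 EBc
 *  8 E0n 9 E1n 10 E2n 11 EBn 12 EIn
 * 13 Pc 14 Pn
 */

#define N_PARMS 34

static double parms[N_PARMS];

void erk_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void erk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double a_M   = parms[0],  d_M    = parms[1];
    const double k_fb  = parms[2],  k_rec  = parms[3];
    const double a_E1  = parms[4],  a_E2   = parms[5];
    const double d_c1  = parms[6],  d_c2   = parms[7];
    const double d_n1  = parms[8],  d_n2   = parms[9];
    const double k_in  = parms[10], k_pass = parms[11], k_out = parms[12];
    const double k_on_c = parms[13], k_off_c = parms[14];
    const double k_cat_c = parms[15], k_sdp_c = parms[16];
    const double k_on_n = parms[17], k_off_n = parms[18];
    const double k_cat_n = parms[19], k_sdp_n = parms[20];
    const double Sc_tot = parms[21], Sn_tot = parms[22];
    const double phi_n  = parms[23], k_rel  = parms[24];
    const double fb_mode = parms[25];  /* 0: dynamic desensitization;
                                          1: instantaneous Hill inhibition */
    const double fb_K = parms[26], fb_h = parms[27];
    const double u   = parms[28];   /* input strength of current segment */
    const double inh = parms[29];   /* (0,1]; reduced after MEK inhibitor */
    const double pho = parms[30];   /* (0,1]; reduced after okadaic acid  */
    const int importin  = parms[31] > 0.5;
    const int const_mek = parms[32] > 0.5;
    const double m2_clamp = parms[33];

    const double phi_c = 1.0 - phi_n;

    const double M0 = y[0], M1 = y[1], M2 = y[2], D = y[3];
    const double E0c = y[4], E1c = y[5], E2c = y[6], EBc = y[7];
    const double E0n = y[8], E1n = y[9], E2n = y[10], EBn = y[11];
    const double EIn = y[12], Pc = y[13], Pn = y[14];

    const double M2_eff = const_mek ? m2_clamp : M2;
    const double fb = fb_mode > 0.5
        ? 1.0 / (1.0 + pow(E2c / fb_K, fb_h))
        : 1.0 - D;
    const double v  = a_M * u * fb;
    const double p1 = inh * a_E1 * M2_eff;
    const double p2 = inh * a_E2 * M2_eff;

    /* bimolecular terms: amounts / compartment volume fraction -> conc. */
    const double b_c = k_on_c * E2c * (Sc_tot - Pc - EBc) / phi_c;
    const double b_n = k_on_n * E2n * (Sn_tot - Pn - EBn) / phi_n;

    const double flux_nuc = (k_in + k_pass) * E2c;
    const double J_nuc_in = importin ? k_rel * EIn : flux_nuc;

    if (const_mek) {
        ydot[0] = 0.0; ydot[1] = 0.0; ydot[2] = 0.0; ydot[3] = 0.0;
    } else {
        ydot[0] = -v * M0 + d_M * M1;
        ydot[1] =  v * M0 - v * M1 - d_M * M1 + d_M * M2;
        ydot[2] =  v * M1 - d_M * M2;
        ydot[3] = fb_mode > 0.5 ? 0.0 : k_fb * E2c * (1.0 - D) - k_rec * D;
    }

    ydot[4] = -p1 * E0c + pho * d_c1 * E1c - k_pass * E0c + k_out * E0n;
    ydot[5] =  p1 * E0c - p2 * E1c - pho * d_c1 * E1c + pho * d_c2 * E2c
              - k_pass * E1c + k_out * E1n;
    ydot[6] =  p2 * E1c - pho * d_c2 * E2c - flux_nuc + k_out * E2n
              - b_c + k_off_c * EBc + k_cat_c * EBc;
    ydot[7] =  b_c - k_off_c * EBc - k_cat_c * EBc;

    ydot[8]  = k_pass * E0c + pho * d_n1 * E1n - k_out * E0n;
    ydot[9]  = k_pass * E1c - pho * d_n1 * E1n + pho * d_n2 * E2n - k_out * E1n;
    ydot[10] = J_nuc_in - pho * d_n2 * E2n - k_out * E2n
              - b_n + k_off_n * EBn + k_cat_n * EBn;
    ydot[11] = b_n - k_off_n * EBn - k_cat_n * EBn;
    ydot[12] = importin ? flux_nuc - k_rel * EIn : 0.0;

    ydot[13] = k_cat_c * EBc - pho * k_sdp_c * Pc;
    ydot[14] = k_cat_n * EBn - pho * k_sdp_n * Pn;
}
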