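#ifndef PRIOMATCH_WFPT_H
#define PRIOMATCH_WFPT_H

// Log density of the Wiener first-passage time at the LOWER boundary.
// t: decision time (rt - t0) in seconds, v: drift, a: boundary separation,
// w: relative start point in (0,1). Diffusion coefficient fixed at 1.
double wfpt_log_lower(double t, double v, double a, double w, double eps);

// Log density for an observed response (boundary = 1 upper / 0 lower) at rt,
// with non-decision time t0. Returns -Inf for rt <= t0 or invalid parameters.
double wfpt_log_response(double rt, int upper, double v, double a, double w,
                         double t0, double eps);

// Log of the outlier-mixture trial likelihood:
// (1 - q) * wfpt + q * contam, with contam the (already halved, for the
// random-choice contaminant) uniform density over the observed RT range.
double wfpt_mix_log(double rt, int upper, double v, double a, double w,
                    double t0, double q, double log_contam, double eps);

#endif
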