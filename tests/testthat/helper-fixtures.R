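# Independent closed-form oracle for the upper-boundary absorption
# probability of a drift diffusion with unit diffusion coefficient,
# relative start z, boundary separation a: standard gambler's-ruin limit.
oracle_upper_prob <- function(v, a, z) {
  if (abs(v) < 1e-12) return(z)
  (1 - exp(-2 * v * z * a)) / (1 - exp(-2 * v * a))
}

# quadrature mass of one boundary's first-passage density
wfpt_mass <- function(boundary, v, a, z, t0 = 0, upper_lim = 60) {
  stats::integrate(function(t) exp(wfpt_logpdf(t, boundary, v, a, z, t0)),
                   lower = t0, upper = upper_lim, rel.tol = 1e-9,
                   abs.tol = 1e-10)$value
}

# standard test truth: friend-prioritizing subject with a drift advantage
make_fp_truth <- function(id = "s001", effect = 0.8, jitter = 0,
                          group = "FP") {
  pri <- if (group == "FP") "friend" else "self"
  oth <- if (group == "FP") "self" else "friend"
  v <- c(stranger_match = 1.2, self_nonmatch = -1.8,
         friend_nonmatch = -1.8, stranger_nonmatch = -1.8)
  v[paste0(pri, "_match")] <- 1.5 + effect
  v[paste0(oth, "_match")] <- 1.5
  if (jitter > 0) v <- v + rnorm(length(v), 0, jitter)
  subject_truth(id, group, v_map = v,
                a_map = c(self = 1.5, friend = 1.6, stranger = 1.6),
                z_map = c(self = 0.5, friend = 0.5, stranger = 0.5),
                t0_map = c(match = 0.25, nonmatch = 0.29))
}

# small multi-subject trial table simulated without deadline censoring,
# for sampler-correctness checks
sim_cohort_trials <- function(truths, trials_per_condition = 20,
                              deadline_ms = 6000, outlier_prob = 0.05,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- task_design(trials_per_condition = trials_per_condition,
                        response_deadline_ms = deadline_ms)
  purrr::map_dfr(truths, simulate_ddm_trials, design = design,
                 outlier_prob = outlier_prob)
}

# brute-force connected components over a channel x time mask under
# channel-adjacency x consecutive-time connectivity (test-side oracle)
brute_components <- function(mask, adj_idx) {
  C <- nrow(mask); Tn <- ncol(mask)
  lab <- matrix(0L, C, Tn)
  nxt <- 0L
  for (c0 in seq_len(C)) for (t0 in seq_len(Tn)) {
    if (!mask[c0, t0] || lab[c0, t0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(c0, t0))
    lab[c0, t0] <- nxt
    while (length(queue) > 0) {
      pt <- queue[[1]]; queue <- queue[-1]
      nbrs <- c(lapply(adj_idx[[pt[1]]], function(cc) c(cc, pt[2])),
                list(c(pt[1], pt[2] - 1), c(pt[1], pt[2] + 1)))
      for (nb in nbrs) {
        if (nb[2] < 1 || nb[2] > Tn) next
        if (mask[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
          lab[nb[1], nb[2]] <- nxt
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}
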