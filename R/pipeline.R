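#' Pipeline configuration
#'
#' Bundles every constant the end-to-end pipeline needs, with one explicit
#' seed per stochastic stage (derived from `seed`). The `"paper"` preset
#' uses the full-scale analysis settings (10000 MCMC samples with 1000
#' burn-in, 1000 permutations, 1000 bootstraps); the `"desk"` preset scales
#' the simulation down (600/150 MCMC, 200 permutations/bootstraps, a small
#' cohort, 250 Hz synthetic EEG) so the whole chain runs in minutes.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Master integer seed.
#' @param ... Named overrides of any config field.
#' @return A list of class `prio_config`.
#' @export
pipeline_config <- function(preset = c("desk", "paper"), seed = 1, ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    design = task_design(),
    n_fp = 8, n_sp = 8,
    effect_size_v = 0.8, noise_sd = 0.1, outlier_prob = 0.05,
    coupling_gain = 0.6, canonical_rho = 0.33,
    n_boot = if (preset == "paper") 1000 else 200,
    n_perm = if (preset == "paper") 1000 else 200,
    mcmc_samples = if (preset == "paper") 10000 else 600,
    mcmc_burn = if (preset == "paper") 1000 else 150,
    eeg_fs = if (preset == "paper") 1000 else 250,
    eeg_subjects = 2, eeg_noise_sd = 1,
    out_dir = NULL,
    seeds = list(cohort = seed, behavior = seed + 1, ddm = seed + 2,
                 eeg = seed + 3, cluster = seed + 4, traits = seed + 5,
                 cca = seed + 6)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  base[names(overrides)] <- overrides
  structure(base, class = "prio_config")
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Chains the stages end to end: cohort simulation, response-efficiency
#' classification, signal detection indices, bootstrap condition means,
#' hierarchical DDM fit of the full model with posterior drift contrasts,
#' synthetic EEG for a subject subset with ERP component amplitudes,
#' induced alpha/low-beta power with ERS/ERD, trial-level power-drift
#' coupling, and the trait/game canonical correlation. When `out_dir` is
#' set, stage outputs are written as TSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results plus the config.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config("desk", seed = 1,
#'                                     mcmc_samples = 200, mcmc_burn = 50))
#' res$classification
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "prio_config"))
  res <- list(config = config)

  cohort <- generate_cohort(config$n_fp, config$n_sp,
                            effect_size_v = config$effect_size_v,
                            noise_sd = config$noise_sd,
                            design = config$design,
                            outlier_prob = config$outlier_prob,
                            coupling_gain = config$coupling_gain,
                            seed = config$seeds$cohort)
  res$cohort <- cohort

  eff <- response_efficiency(cohort$trials)
  assignment <- classify_groups(eff)
  trials <- dplyr::left_join(cohort$trials,
                             dplyr::select(assignment, "subject", "group"),
                             by = "subject")
  res$efficiency <- eff
  res$classification <- assignment
  res$sdt <- sdt_indices(cohort$trials)
  res$bootstrap <- bootstrap_condition_means(trials, n_boot = config$n_boot,
                                             seed = config$seeds$behavior)

  fit <- fit_hddm(cohort$trials, ddm_spec(),
                  n_samples = config$mcmc_samples,
                  burn_in = config$mcmc_burn, seed = config$seeds$ddm)
  res$hddm <- fit
  grp <- fit$groups
  res$drift_contrasts <- purrr::map_dfr(grp, function(g) {
    tibble(group = g,
           p_friend_gt_self = p_bayes(fit, "v",
                                      c("friend_match", "self_match"),
                                      "greater", group = g),
           p_self_gt_friend = p_bayes(fit, "v",
                                      c("self_match", "friend_match"),
                                      "greater", group = g))
  })

  # EEG for a subject subset: match-condition self/friend epochs
  eeg_ids <- vapply(cohort$truths, `[[`, "", "subject_id")
  eeg_ids <- head(eeg_ids, config$eeg_subjects)
  epochs_list <- purrr::map(eeg_ids, function(id) {
    truth <- cohort$truths[[match(id, vapply(cohort$truths, `[[`, "",
                                             "subject_id"))]]
    tr <- dplyr::filter(cohort$trials, .data$subject == id,
                        .data$match == "match",
                        .data$label %in% c("self", "friend"))
    synthesize_epochs(tr, osc = osc_spec(mod_factor = sqrt(0.7),
                                         coupling_gain = truth$coupling_gain),
                      fs = config$eeg_fs, noise_sd = config$eeg_noise_sd,
                      drift = condition_drift(truth, tr),
                      seed = config$seeds$eeg + match(id, eeg_ids))
  })
  names(epochs_list) <- eeg_ids

  erp_tbl <- purrr::map_dfr(epochs_list, function(ep) {
    ep <- epoch_and_baseline(ep)
    ep <- reject_artifacts(ep, 70, by = "label")
    purrr::map_dfr(c("N1", "P2", "P3", "LPP"), function(comp) {
      component_amplitude(ep, comp, by = "label")
    })
  })
  res$erp <- erp_tbl

  # induced alpha/low-beta power and trial-level coupling with drift
  coupling <- purrr::map_dfr(eeg_ids, function(id) {
    ep <- epochs_list[[id]]
    ind <- remove_phase_locked(ep, by = "label")
    ind <- subset_epochs(ind, channels = intersect(osc_spec()$channels,
                                                   ind$channels))
    fam <- build_wavelets(freqs = 8:18, fs = ep$fs)
    tfr <- ers_erd(tf_power(ind, fam, keep_trials = TRUE))
    tfr_band_mean(tfr, c(8, 18), c(200, 700))
  })
  coupling$drift <- unlist(purrr::map(eeg_ids, function(id) {
    condition_drift(cohort$truths[[match(id, vapply(cohort$truths, `[[`, "",
                                                    "subject_id"))]],
                    dplyr::filter(coupling, .data$subject == id))
  }))
  res$coupling <- window_correlation(coupling$power, coupling$drift)

  traits <- generate_traits_and_games(cohort, config$canonical_rho,
                                      seed = config$seeds$traits)
  res$traits <- traits
  x_block <- dplyr::select(traits, "empathic_concern":"friend_familiarity")
  # behavioral block: friend-match accuracy, RT, d' and beta per subject
  beh <- dplyr::filter(eff, .data$label == "friend") |>
    dplyr::select("subject", accuracy_friend = "accuracy",
                  rt_friend = "mean_rt_ms") |>
    dplyr::left_join(
      dplyr::filter(res$sdt, .data$label == "friend") |>
        dplyr::select("subject", d_prime_friend = "d_prime",
                      beta_friend = "beta"),
      by = "subject")
  y_block <- beh[match(traits$subject, beh$subject),
                 c("accuracy_friend", "rt_friend", "d_prime_friend",
                   "beta_friend")]
  res$cca <- permutation_pvalue(x_block, y_block, n_perm = config$n_perm,
                                seed = config$seeds$cca,
                                anchor = "accuracy_friend")
  res$game_correlations <- game_correlations(
    beh$accuracy_friend[match(traits$subject, beh$subject)] -
      (dplyr::filter(eff, .data$label == "self") |>
         dplyr::pull("accuracy", name = "subject"))[traits$subject],
    traits[c("trust_send", "pgg_contribution")],
    n_boot = config$n_boot, seed = config$seeds$cca + 1)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(cohort$trials, file.path(config$out_dir, "trials.tsv"))
    write_table_tsv(eff, file.path(config$out_dir, "efficiency.tsv"))
    write_table_tsv(assignment, file.path(config$out_dir, "groups.tsv"))
    write_table_tsv(res$sdt, file.path(config$out_dir, "sdt.tsv"))
    write_table_tsv(erp_tbl, file.path(config$out_dir, "erp.tsv"))
    write_table_tsv(traits, file.path(config$out_dir, "traits.tsv"))
    summary <- list(
      seeds = config$seeds, preset = config$preset,
      n_subjects = length(cohort$truths),
      groups = as.list(table(assignment$group)),
      dic = res$hddm$dic$dic,
      drift_contrasts = res$drift_contrasts,
      coupling = res$coupling,
      cca_rho = if (inherits(res$cca, "prio_cca")) res$cca$rho else NA,
      cca_p = if (inherits(res$cca, "prio_cca")) res$cca$p_perm else NA
    )
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
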