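#' Build a pipeline run configuration
#'
#' All module parameters with their reference-design defaults, plus a
#' master seed that fans out to per-stage seeds through [derive_seed()],
#' so any stage can be reproduced in isolation. The configuration (and
#' its fingerprint, attached to every output table) fully determines a
#' synthetic run.
#'
#' @param mode `"synthetic"` (default) or `"real"` (epochs supplied by the
#'   caller).
#' @param seed master seed.
#' @param n_group_a,n_group_b,trials_per_participant cohort sizes.
#' @param montage_channels 8, 16 or 64 synthetic channels.
#' @param correctness_gain,confidence_gain,rt_gain injected ERP gains
#'   (microvolts); zero everywhere gives a null run.
#' @param coupling_a,coupling_b confidence/onset coupling per group.
#' @param alpha FDR level for both scan steps.
#' @param run_bayes fit the step-3 Bayesian cluster models (slowest part).
#' @param bayes_iter,bayes_chains sampler settings for step 3 and the
#'   behavioural model.
#' @param simulate_trajectories generate and analyze mouse trajectories
#'   (otherwise generative onsets/flags are used directly).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), seed = 1L,
                       n_group_a = 19, n_group_b = 14,
                       trials_per_participant = 300,
                       montage_channels = 8,
                       correctness_gain = -0.34, confidence_gain = 0.2,
                       rt_gain = 0.3,
                       coupling_a = -0.04, coupling_b = -0.01,
                       alpha = 0.05, run_bayes = FALSE,
                       bayes_iter = 2000, bayes_chains = 4,
                       simulate_trajectories = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, seed = as.integer(seed),
              n_group_a = n_group_a, n_group_b = n_group_b,
              trials_per_participant = trials_per_participant,
              montage_channels = montage_channels,
              correctness_gain = correctness_gain,
              confidence_gain = confidence_gain, rt_gain = rt_gain,
              coupling_a = coupling_a, coupling_b = coupling_b,
              alpha = alpha, run_bayes = run_bayes,
              bayes_iter = bayes_iter, bayes_chains = bayes_chains,
              simulate_trajectories = simulate_trajectories)
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: simulates the cohort, applies the kinematic exclusion
#' rules, generates and preprocesses epochs, runs the three statistical
#' steps for each term (correctness on all retained trials; confidence on
#' correct trials only; movement onset on all retained trials), and the
#' behavioural analyses. Returns a result bundle whose tables all carry
#' the configuration fingerprint.
#'
#' @param config a [run_config()].
#' @param epochs optional preprocessed [epoch_array()] for
#'   `mode = "real"`.
#' @return list with elements `behavior` (trial table), `retention`,
#'   `scans`, `clusters`, `effects`, `bayes` (when enabled), `metacog`,
#'   `behavior_model`, `group_table`, `config`, `hash`.
#' @export
run_pipeline <- function(config = run_config(), epochs = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- attr(config, "hash")
  cohort <- cohort_spec(config$n_group_a, config$n_group_b,
                        config$trials_per_participant,
                        seed = derive_seed(config$seed, "behavior"))
  obs_a <- observer_spec(confidence_rt_coupling = config$coupling_a)
  obs_b <- observer_spec(confidence_rt_coupling = config$coupling_b)
  trials <- simulate_behavior(cohort, obs_a, obs_b)

  if (config$simulate_trajectories && nrow(trials)) {
    set.seed(derive_seed(config$seed, "trajectories"))
    lab <- character(nrow(trials))
    onset_det <- numeric(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- simulate_trajectory(trials$onset[i],
        target_side = if (trials$response_side[i] > 0) "right" else "left",
        com = trials$com_true[i])
      o <- detect_movement_onset(tr)
      com <- detect_change_of_mind(tr,
        if (trials$response_side[i] > 0) "right" else "left")
      lab[i] <- apply_trial_exclusions(o, trials$confidence[i], com)
      onset_det[i] <- as.numeric(o)
    }
    trials$exclusion <- lab
    trials$onset_detected <- onset_det
  } else {
    trials$exclusion <- trials$exclusion_true
  }
  retained <- trials[trials$exclusion == "none", , drop = FALSE]

  if (config$mode == "synthetic") {
    montage <- default_montage(config$montage_channels)
    templates <- default_erp_templates(config$correctness_gain,
                                       config$confidence_gain,
                                       config$rt_gain)
    epochs <- simulate_epochs(retained, templates, noise_spec(), montage,
                              seed = derive_seed(config$seed, "epochs"))
  }
  if (is.null(epochs)) stop("real mode requires preprocessed epochs")
  pp <- preprocess_epochs(epochs)
  ep <- pp$epochs

  terms <- c("correctness", "confidence", "movementRT")
  scans <- clusters <- effects <- list()
  bayes <- list()
  for (term in terms) {
    e_t <- if (term == "confidence")
      subset_epochs(ep, trials = ep$metadata$correct) else ep
    sc <- scan_responsive_electrodes(e_t, term, alpha = config$alpha)
    scans[[term]] <- sc
    if (length(sc$electrodes)) {
      cl <- cluster_regression(e_t, sc$electrodes, term,
                               alpha = config$alpha)
      clusters[[term]] <- cl$clusters
      effects[[term]] <- lapply(cl$clusters, function(cst)
        effect_amplitude(e_t, cst, contrast = term))
      if (config$run_bayes && length(cl$clusters)) {
        amp <- cluster_amplitudes(e_t, cl$clusters[[1]])
        model <- if (term == "correctness") 4 else 5
        if (term != "movementRT")
          bayes[[term]] <- fit_cluster_model(
            amp, model, iter = config$bayes_iter,
            warmup = config$bayes_iter %/% 2,
            chains = config$bayes_chains,
            seed = derive_seed(config$seed, paste0("bayes/", term)))
      }
    } else {
      clusters[[term]] <- list()
      effects[[term]] <- list()
    }
  }

  counts <- sdt_counts(retained)
  mrat <- tryCatch(
    fit_hierarchical_mratio(
      counts,
      groups = vapply(names(counts), function(p)
        retained$group[match(p, retained$participant)], ""),
      iter = 800, warmup = 400,
      seed = derive_seed(config$seed, "mratio")),
    error = function(e) NULL)
  behmod <- confidence_rt_model(retained, iter = config$bayes_iter,
                                warmup = config$bayes_iter %/% 2,
                                chains = config$bayes_chains,
                                seed = derive_seed(config$seed, "behmod"))
  group_table <- behavioral_group_table(retained)
  group_table$config <- hash

  list(behavior = trials, retention = pp$log, scans = scans,
       clusters = clusters, effects = effects, bayes = bayes,
       metacog = mrat, behavior_model = behmod,
       group_table = group_table, config = config, hash = hash)
}

#' Behavioural summary table by group
#'
#' Per-group means of accuracy, confidence (mean and within-participant
#' variability) and movement onsets for correct and incorrect trials,
#' with Welch t, p and JZS Bayes factor per row.
#'
#' @param trials retained trial table.
#' @return data.frame, one row per measure.
#' @export
behavioral_group_table <- function(trials) {
  glev <- unique(trials$group)
  per_part <- function(fun) {
    vapply(split(trials, trials$participant), fun, 0)
  }
  pgroup <- vapply(split(trials$group, trials$participant),
                   function(g) g[1], "")
  measures <- list(
    accuracy = per_part(function(d) mean(d$correct)),
    confidence_mean = per_part(function(d) mean(d$confidence) / 100),
    confidence_sd = per_part(function(d) sd(d$confidence) / 100),
    onset_correct = per_part(function(d) mean(d$onset[d$correct])),
    onset_incorrect = per_part(function(d)
      mean(d$onset[!d$correct])))
  out <- do.call(rbind, lapply(names(measures), function(nm) {
    v <- measures[[nm]]
    a <- v[pgroup == glev[1]]; b <- v[pgroup == glev[2]]
    gc <- group_compare(a, b)
    data.frame(measure = nm, group_a = mean(a, na.rm = TRUE),
               sd_a = sd(a), group_b = mean(b, na.rm = TRUE), sd_b = sd(b),
               t = gc$t, p = gc$p, bf10 = gc$bf10)
  }))
  rownames(out) <- NULL
  out
}
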