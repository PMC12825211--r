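# End-to-end orchestration: synthetic generation (optional) -> preprocessing
# -> clustering arm (+ null controls) -> syllable segmentation ->
# selectivity scoring and group statistics, with a machine-readable summary.

#' Build a pipeline run configuration
#'
#' @param subjects List of per-subject trial descriptions; each element is a
#'   list with `subject_id`, `group` (e.g. `"TIS"` / `"Biphasic"`),
#'   `regime` (`"selective"` / `"nonselective"`), `n_configs`, `mode`, and
#'   optionally `csv` / `log` paths to load recorded data instead of
#'   simulating.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Character subset of `c("cluster", "controls", "syllables",
#'   "selectivity")`.
#' @param params Stage parameter overrides (see Details in
#'   [run_pipeline()]).
#' @param outdir Optional output directory for CSV/JSON artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(subjects, seed = 1,
                       stages = c("cluster", "controls", "syllables",
                                  "selectivity"),
                       params = list(), outdir = NULL) {
  defaults <- list(likelihood_threshold = 0.5, origin = "image_origin",
                   k_sd = 3, profile = "custom", latent_dim = 3,
                   n_states = 20, ar_order = 3, iters_ar = 50,
                   iters_full = 500, kappa_ar = 1e9, kappa_full = 1e8,
                   m = 100, B = 1000, dropout_rate = 0.05, noise_px = 1.5,
                   on_s = 5, off_s = 5, fps = 60)
  params <- utils::modifyList(defaults, params)
  structure(list(subjects = subjects, seed = as.integer(seed),
                 stages = stages, params = params, outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per subject: trial generation (or loading), preprocessing into
#' the standardized position matrix with movement gating, the clustering arm
#' (spectral embedding, density clustering, agreement with configuration
#' labels, optional shuffle/noise null controls), sticky AR-HMM syllable
#' segmentation, and per-configuration selectivity scoring. When at least
#' two groups are present, the group comparison (bootstrap, beta regression,
#' Mann-Whitney U, Cohen's d, Cliff's delta) is added. Identical
#' configuration and seed reproduce the summary exactly.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with `ami` (per-subject
#'   agreement, incl. controls), `scores` (per-configuration selectivity),
#'   `group_comparison` (or NULL), `subjects` (per-subject artifacts), and
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  ami_rows <- list(); score_rows <- list(); per_subject <- list()

  for (si in seq_along(config$subjects)) {
    sub <- config$subjects[[si]]
    sid <- sub$subject_id %||% paste0("S", si)
    sub_seed <- derive_seed(config$seed, paste0("subject_", sid))

    if (!is.null(sub$csv)) {
      if (!file.exists(sub$csv))
        stop("preflight: keypoint CSV not found: ", sub$csv)
      if (is.null(sub$log) || !file.exists(sub$log %||% ""))
        stop("preflight: epoch table / sweep log not found: ",
             sub$log %||% "<missing>")
      series <- read_dlc_csv(sub$csv, fps = p$fps)
      epochs <- read_sweep_log(sub$log)
      states_true <- NULL
    } else {
      spec <- trial_spec(n_configs = sub$n_configs %||% 8,
                         mode = sub$mode %||% "TIS4",
                         on_s = p$on_s, off_s = p$off_s, fps = p$fps,
                         dropout_rate = p$dropout_rate,
                         noise_px = p$noise_px,
                         seed = sub_seed, subject_id = sid)
      sweep <- enumerate_sweep(cuff_grid(), spec$mode)
      labels <- sweep$label[seq_len(spec$n_configs)]
      lib <- motif_library(labels, regime = sub$regime %||% "selective",
                           seed = derive_seed(sub_seed, "library"),
                           fps = p$fps)
      trial <- generate_trial(spec, lib)
      series <- trial$series; epochs <- trial$epochs
      states_true <- trial$states
    }

    prep <- preprocess_trial(series, epochs,
                             likelihood_threshold = p$likelihood_threshold,
                             origin = p$origin, k_sd = p$k_sd)
    artifacts <- list(subject_id = sid, epochs = prep$epochs,
                      states_true = states_true)

    if ("cluster" %in% config$stages) {
      emb <- embed(prep$values, profile = p$profile,
                   seed = derive_seed(sub_seed, "embed"))
      cl <- cluster_density(emb$coords, profile = p$profile)
      rep0 <- agreement_report(cl, prep$labels, coords = emb$coords)
      row <- data.frame(subject_id = sid, group = sub$group %||% NA,
                        control = "none", ami = rep0$ami,
                        silhouette = rep0$silhouette)
      if ("controls" %in% config$stages) {
        for (ctrl in c("row_shuffle", "gaussian_noise")) {
          vals_c <- null_controls(prep$values, ctrl,
                                  seed = derive_seed(sub_seed, ctrl))
          emb_c <- embed(vals_c, profile = p$profile,
                         seed = derive_seed(sub_seed, "embed"))
          cl_c <- cluster_density(emb_c$coords, profile = p$profile)
          rep_c <- agreement_report(cl_c, prep$labels, coords = emb_c$coords)
          row <- rbind(row, data.frame(subject_id = sid,
                                       group = sub$group %||% NA,
                                       control = ctrl, ami = rep_c$ami,
                                       silhouette = rep_c$silhouette))
        }
      }
      ami_rows[[sid]] <- row
      artifacts$embedding <- emb
      artifacts$clusters <- cl
    }

    if (any(c("syllables", "selectivity") %in% config$stages)) {
      latents <- pca_latents(prep$values, d = p$latent_dim)
      m0 <- fit_ar_only(latents, n_states = p$n_states,
                        ar_order = p$ar_order, iters = p$iters_ar,
                        kappa = p$kappa_ar,
                        seed = derive_seed(sub_seed, "arhmm"))
      fit <- fit_full(m0, latents, iters = p$iters_full,
                      kappa = p$kappa_full)
      artifacts$sequence <- fit$sequence
      if ("selectivity" %in% config$stages) {
        tab <- syllable_config_table(fit$sequence, prep$epochs)
        sc <- selectivity_score(tab)
        sc$subject_id <- sid
        sc$group <- sub$group %||% NA
        score_rows[[sid]] <- sc
        artifacts$selectivity <- tab
      }
    }
    per_subject[[sid]] <- artifacts
  }

  scores <- if (length(score_rows)) do.call(rbind, score_rows) else NULL
  group_comparison <- NULL
  if (!is.null(scores) && length(unique(scores$group[!is.na(scores$group)])) >= 2) {
    groups <- unique(scores$group)
    boot <- bootstrap_means(scores$score, scores$group, m = p$m, B = p$B,
                            seed = derive_seed(config$seed, "bootstrap"))
    a <- scores$score[scores$group == groups[1]]
    b <- scores$score[scores$group == groups[2]]
    npe <- nonparametric_effects(a, b)
    breg <- tryCatch({
      df <- data.frame(score = scores$score,
                       group = factor(scores$group),
                       subject = factor(scores$subject_id))
      form <- if (nlevels(df$subject) > 1) score ~ group + subject else
        score ~ group
      beta_regression(form, df)
    }, error = function(e) e$message)
    group_comparison <- list(bootstrap = boot, nonparametric = npe,
                             beta_regression = breg)
  }

  result <- structure(list(
    ami = if (length(ami_rows)) do.call(rbind, ami_rows) else NULL,
    scores = scores, group_comparison = group_comparison,
    subjects = per_subject, seed = config$seed),
    class = "pipeline_result")
  rownames(result$ami) <- NULL
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$ami))
    write.csv(result$ami, file.path(outdir, "ami.csv"), row.names = FALSE)
  if (!is.null(result$scores))
    write.csv(result$scores, file.path(outdir, "selectivity_scores.csv"),
              row.names = FALSE)
  summary <- list(seed = result$seed,
                  ami = result$ami,
                  n_scores = if (is.null(result$scores)) 0 else
                    nrow(result$scores))
  if (!is.null(result$group_comparison)) {
    gc <- result$group_comparison
    summary$bootstrap <- gc$bootstrap$summary
    summary$ci_overlap <- gc$bootstrap$ci_overlap
    summary$nonparametric <- gc$nonparametric
    if (inherits(gc$beta_regression, "beta_regression"))
      summary$beta_coefficients <- gc$beta_regression$coefficients
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(outdir)
}

#' Validate pipeline input files
#'
#' Checks that keypoint CSVs parse in the three-header-row dialect, carry
#' the expected hindlimb keypoint schema, and that the epoch table is
#' consistent (ordered, non-overlapping, spans within the recording).
#' Failures are collected, not raised.
#'
#' @param csv Path to a keypoint CSV.
#' @param log Path to a sweep log / epoch table.
#' @return Data frame of failures (`file`, `check`, `message`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(csv, log = NULL) {
  failures <- data.frame(file = character(), check = character(),
                         message = character())
  fail <- function(file, check, message)
    rbind(failures, data.frame(file = file, check = check,
                               message = message))
  series <- NULL
  if (!file.exists(csv)) {
    failures <- fail(csv, "exists", "file not found")
  } else {
    series <- tryCatch(read_dlc_csv(csv), error = function(e) {
      failures <<- fail(csv, "dialect", conditionMessage(e))
      NULL
    })
    if (!is.null(series)) {
      expected <- hindlimb_keypoints()
      unknown <- setdiff(series$bodyparts, expected)
      if (length(unknown))
        failures <- fail(csv, "schema",
                         paste0("unknown bodypart(s): ",
                                paste(unknown, collapse = ", "),
                                "; expected schema: ",
                                paste(expected, collapse = ", ")))
    }
  }
  if (!is.null(log)) {
    if (!file.exists(log)) {
      failures <- fail(log, "exists", "file not found")
    } else {
      epochs <- tryCatch(read_sweep_log(log), error = function(e) {
        failures <<- fail(log, "epochs", conditionMessage(e))
        NULL
      })
      if (!is.null(epochs) && !is.null(series) &&
          max(epochs$off_end) > nrow(series$x))
        failures <- fail(log, "span",
                         "epoch spans extend beyond the recording")
    }
  }
  failures
}
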