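# End-to-end simulated study: pre baselines -> pre MI -> closed-loop NFT
# (6 runs) -> post baselines -> post MI, then the full evaluation
# (IAF, band RP topography, per-run dARP, ERD maps, CV accuracies,
# functional connectivity contrasts, cohort statistics).

#' Study configuration
#'
#' Desk-scale defaults keep a full 18-subject study tractable on one CPU:
#' 1 min baselines, motor-imagery runs of 4 trials per task (36 trials per
#' session) and 60 s NFT runs. `paper_scale = TRUE` restores the published
#' protocol timing: 12 trials per task (108 per session), 3 min NFT runs,
#' all four decoding schemes and all five bands for connectivity.
#'
#' @param n_subjects cohort size. @param seed master RNG seed.
#' @param paper_scale use full protocol timing.
#' @param baseline_s baseline run length (s).
#' @param mi_runs,mi_trials_per_task motor-imagery session structure.
#' @param nft_runs,nft_run_s neurofeedback session structure.
#' @param schemes decoding schemes to evaluate.
#' @param fc_bands band names for functional connectivity.
#' @param fc_measures `"PLI"`, `"imCoh"` or both.
#' @param eta_override fixed trainability for every subject (`NULL` to draw
#'   from the cohort distribution; 0 gives a negative-control cohort).
#' @param out_dir if non-`NULL`, EDF+ recordings and result CSVs are
#'   written there.
#' @param nft_config an [nft_config()].
#' @return a `study_config` list.
#' @export
study_config <- function(n_subjects = 18L, seed = 1L, paper_scale = FALSE,
                         baseline_s = 60,
                         mi_runs = 3L,
                         mi_trials_per_task = if (paper_scale) 12L else 4L,
                         nft_runs = 6L,
                         nft_run_s = if (paper_scale) 180 else 60,
                         schemes = if (paper_scale)
                           c("three_class", "L_vs_R", "L_vs_I", "R_vs_I")
                         else "three_class",
                         fc_bands = if (paper_scale)
                           c("delta", "theta", "alpha", "beta", "gamma")
                         else "alpha",
                         fc_measures = c("PLI", "imCoh"),
                         eta_override = NULL, out_dir = NULL,
                         nft_config = alphanft::nft_config()) {
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 paper_scale = paper_scale, baseline_s = baseline_s,
                 mi_runs = as.integer(mi_runs),
                 mi_trials_per_task = as.integer(mi_trials_per_task),
                 nft_runs = as.integer(nft_runs), nft_run_s = nft_run_s,
                 schemes = schemes, fc_bands = fc_bands,
                 fc_measures = fc_measures, eta_override = eta_override,
                 out_dir = out_dir, nft_config = nft_config),
            class = "study_config")
}

#' Run the full simulated neurofeedback study
#'
#' Executes, per subject: pre eyes-closed/eyes-open baselines (IAF and
#' baseline ARP), pre motor-imagery session with CV decoding and ERD maps,
#' the closed-loop NFT session (the subject's alpha amplitude evolves with
#' the feedback), post baselines and post motor-imagery session, and
#' functional connectivity on both eyes-open baselines. Cohort-level
#' results: paired-t band-RP topographies with FDR correction, per-edge
#' connectivity contrasts, and the Pearson correlation between frontal
#' dARP and the change in three-class decoding accuracy. Deterministic
#' given the config seed.
#'
#' @param config a [study_config()].
#' @param progress print per-subject progress lines.
#' @return a `study_results` list (see [report_study()] for the exported
#'   tables).
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  mont <- montage()
  cohort <- generate_cohort(config$n_subjects, config$seed,
                            eta_override = config$eta_override)
  subj_rows <- list(); acc_rows <- list(); arp_rows <- list()
  erd_rows <- list(); rp_store <- list(); fc_store <- list()
  edf_dir <- config$out_dir
  if (!is.null(edf_dir)) dir.create(edf_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  for (i in seq_along(cohort)) {
    prof <- cohort[[i]]
    sid <- sprintf("sub-%02d", i)
    if (progress) message(sid, " (eta = ", signif(prof$eta, 3), ")")

    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stopf("study aborted at stage '%s' for %s: %s", what, sid,
              conditionMessage(e)))
    }

    pre_ec <- stage("pre EC baseline", generate_baseline(
      prof, eyes = "closed", duration_s = config$baseline_s, mont = mont,
      seed = derive_seed(prof$seed, "pre_ec")))
    pre_eo <- stage("pre EO baseline", generate_baseline(
      prof, eyes = "open", duration_s = config$baseline_s, mont = mont,
      seed = derive_seed(prof$seed, "pre_eo")))
    iaf_pre <- stage("IAF", suppressWarnings(estimate_iaf(pre_ec)))
    bands <- band_set(clip(iaf_pre, 8, 12))

    pre_mi <- stage("pre MI", generate_mi_session(
      prof, alpha_amp = prof$a0, n_runs = config$mi_runs,
      trials_per_task = config$mi_trials_per_task, mont = mont,
      seed = derive_seed(prof$seed, "pre_mi")))
    pre_eval <- stage("pre decoding", evaluate_mi(pre_mi, mont, bands,
                                                  config$schemes,
                                                  seed = derive_seed(prof$seed, "cv_pre")))

    state <- stage("engine init", init_engine(pre_eo, iaf_pre,
                                              config$nft_config, mont))
    nft <- stage("NFT session", run_nft_session(
      prof, state, n_runs = config$nft_runs, run_s = config$nft_run_s,
      seed = derive_seed(prof$seed, "nft")))

    post_ec <- stage("post EC baseline", generate_baseline(
      prof, alpha_amp = nft$final_amp, eyes = "closed",
      duration_s = config$baseline_s, mont = mont,
      seed = derive_seed(prof$seed, "post_ec")))
    post_eo <- stage("post EO baseline", generate_baseline(
      prof, alpha_amp = nft$final_amp, eyes = "open",
      duration_s = config$baseline_s, mont = mont,
      seed = derive_seed(prof$seed, "post_eo")))
    iaf_post <- stage("post IAF", suppressWarnings(estimate_iaf(post_ec)))
    post_mi <- stage("post MI", generate_mi_session(
      prof, alpha_amp = nft$final_amp, n_runs = config$mi_runs,
      trials_per_task = config$mi_trials_per_task, mont = mont,
      seed = derive_seed(prof$seed, "post_mi")))
    post_eval <- stage("post decoding", evaluate_mi(post_mi, mont, bands,
                                                    config$schemes,
                                                    seed = derive_seed(prof$seed, "cv_post")))

    # band relative power per channel on both EO baselines
    rp <- stage("RP topography", {
      scalp_pre <- select_channels(pre_eo, mont$scalp)
      scalp_post <- select_channels(post_eo, mont$scalp)
      est_pre <- windowed_psd(scalp_pre)
      est_post <- windowed_psd(scalp_post)
      lapply(names(bands), function(bn)
        list(pre = relative_power(est_pre, bands[[bn]]),
             post = relative_power(est_post, bands[[bn]])))
    })
    names(rp) <- names(bands)
    rp_store[[i]] <- rp

    # frontal-mean dARP between EO baselines (the training outcome measure)
    f16 <- match(mont$frontal16, mont$scalp)
    arp_pre <- mean(rp$alpha$pre[f16])
    arp_post <- mean(rp$alpha$post[f16])
    darp <- delta_relative(arp_post, arp_pre)

    fc <- stage("connectivity", {
      seg_pre <- segment_baseline(select_channels(pre_eo, mont$lateral48))
      seg_post <- segment_baseline(select_channels(post_eo, mont$lateral48))
      out <- list()
      for (bn in config$fc_bands) {
        band <- bands[[bn]]
        if ("PLI" %in% config$fc_measures) {
          out[[paste0(bn, "_PLI")]] <- list(
            pre = pli_matrix(seg_pre, band, pre_eo$sfreq, bn, mont$lateral48),
            post = pli_matrix(seg_post, band, post_eo$sfreq, bn,
                              mont$lateral48))
        }
        if ("imCoh" %in% config$fc_measures) {
          out[[paste0(bn, "_imCoh")]] <- list(
            pre = imcoh_matrix(seg_pre, band, pre_eo$sfreq, bn,
                               mont$lateral48),
            post = imcoh_matrix(seg_post, band, post_eo$sfreq, bn,
                                mont$lateral48))
        }
      }
      out
    })
    fc_store[[i]] <- fc

    if (!is.null(edf_dir)) {
      write_edf(pre_eo, file.path(edf_dir,
                                  paste0(sid, "_ses-pre_task-rest_eo.edf")))
      write_edf(pre_ec, file.path(edf_dir,
                                  paste0(sid, "_ses-pre_task-rest_ec.edf")))
      write_edf(pre_mi, file.path(edf_dir, paste0(sid, "_ses-pre_task-mi.edf")))
      write_edf(post_eo, file.path(edf_dir,
                                   paste0(sid, "_ses-post_task-rest_eo.edf")))
      write_edf(post_ec, file.path(edf_dir,
                                   paste0(sid, "_ses-post_task-rest_ec.edf")))
      write_edf(post_mi, file.path(edf_dir,
                                   paste0(sid, "_ses-post_task-mi.edf")))
    }

    subj_rows[[i]] <- data.frame(
      subject = sid, eta = prof$eta, a0 = prof$a0, true_iaf = prof$iaf,
      iaf_pre = as.numeric(iaf_pre), iaf_post = as.numeric(iaf_post),
      final_amp = nft$final_amp, arp_baseline = state$arp_baseline,
      darp = darp, stringsAsFactors = FALSE)
    acc_rows[[i]] <- do.call(rbind, lapply(config$schemes, function(sc)
      data.frame(subject = sid,
                 session = c("pre", "post"), scheme = sc,
                 accuracy = c(pre_eval$acc[[sc]], post_eval$acc[[sc]]),
                 stringsAsFactors = FALSE)))
    arp_rows[[i]] <- data.frame(subject = sid,
                                run = seq_along(nft$run_mean_delta_arp),
                                mean_delta_arp = nft$run_mean_delta_arp,
                                stringsAsFactors = FALSE)
    erd_rows[[i]] <- rbind(cbind(subject = sid, session = "pre",
                                 pre_eval$erd),
                           cbind(subject = sid, session = "post",
                                 post_eval$erd))
  }

  subjects <- do.call(rbind, subj_rows)
  accuracy <- do.call(rbind, acc_rows)

  # cohort topography: paired t per channel per band + FDR per band family
  topo <- list()
  for (bn in names(rp_store[[1L]])) {
    pre <- t(vapply(rp_store, function(r) r[[bn]]$pre, numeric(56L)))
    post <- t(vapply(rp_store, function(r) r[[bn]]$post, numeric(56L)))
    tt <- lapply(seq_len(56L), function(ch) {
      if (nrow(pre) < 2L) return(test_result(NA_real_, NA_real_, 0L,
                                             nrow(pre), NA_real_,
                                             degenerate = TRUE))
      paired_t(pre[, ch], post[, ch])
    })
    p <- vapply(tt, function(z) z$p_value, 0)
    ok <- !vapply(tt, function(z) z$degenerate, TRUE) & is.finite(p)
    p_fdr <- rep(NA_real_, 56L)
    if (any(ok)) p_fdr[ok] <- fdr_bh(p[ok])$p_adjusted
    topo[[bn]] <- data.frame(
      band = bn, channel = mont$scalp,
      mean_delta_rp = colMeans((post - pre) / pre),
      t = vapply(tt, function(z) z$statistic, 0), p = p, p_fdr = p_fdr,
      sig_fdr = !is.na(p_fdr) & p_fdr <= 0.05, stringsAsFactors = FALSE)
  }
  delta_rp_topo <- do.call(rbind, topo)

  fc_contrasts <- list()
  for (key in names(fc_store[[1L]])) {
    if (config$n_subjects < 2L) break
    pre <- lapply(fc_store, function(f) f[[key]]$pre)
    post <- lapply(fc_store, function(f) f[[key]]$post)
    ec <- edge_contrast(pre, post)
    ec$band <- sub("_.*", "", key)
    ec$measure <- sub(".*_", "", key)
    fc_contrasts[[key]] <- ec
  }
  fc_contrasts <- if (length(fc_contrasts)) do.call(rbind, fc_contrasts)
                  else NULL

  corr <- NULL
  if ("three_class" %in% config$schemes && config$n_subjects >= 3L) {
    d_acc <- with(accuracy[accuracy$scheme == "three_class", ],
                  accuracy[session == "post"] - accuracy[session == "pre"])
    corr <- pearson_r(subjects$darp, d_acc)
  }

  res <- structure(list(subjects = subjects, accuracy = accuracy,
                        arp_runs = do.call(rbind, arp_rows),
                        delta_rp_topo = delta_rp_topo,
                        erd_topo = do.call(rbind, erd_rows),
                        fc_contrasts = fc_contrasts, correlation = corr,
                        config = config),
                   class = "study_results")
  if (!is.null(config$out_dir)) report_study(res, config$out_dir)
  res
}

# decode one MI session: FIR 8-30 Hz, 0-4 s epochs, CV per scheme; ERD from
# unfiltered [-3, 4) s epochs in the individual alpha band.
evaluate_mi <- function(rec, mont, bands, schemes, seed) {
  scalp <- select_channels(rec, mont$scalp)
  filtered <- fir_bandpass(scalp)
  trials <- epoch_trials(filtered, 0, 4)
  acc <- lapply(schemes, function(sc)
    evaluate_cv(trials, sc, seed = derive_seed(seed, sc)))
  names(acc) <- schemes
  erd_trials <- epoch_trials(scalp, -3, 4)
  erd <- compute_erd(erd_trials, bands$alpha)
  erd_df <- data.frame(task = rep(rownames(erd), each = ncol(erd)),
                       channel = rep(colnames(erd), nrow(erd)),
                       erd = as.numeric(t(erd)), stringsAsFactors = FALSE)
  list(acc = acc, erd = erd_df)
}

#' Write the study result tables to CSV
#'
#' Emits `accuracy.csv`, `arp_runs.csv`, `delta_rp_topo.csv`,
#' `erd_topo.csv`, `fc_contrasts.csv`, `correlation.csv`, `subjects.csv`
#' and `run_log.json` (config echo plus a content hash) into `outdir`.
#'
#' @param results a `study_results` object from [run_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
report_study <- function(results, outdir) {
  # correlation is NULL for cohorts too small for a Pearson test (n < 3);
  # it is then reported as an NA row rather than treated as missing
  required <- c("subjects", "accuracy", "arp_runs", "delta_rp_topo",
                "erd_topo", "config")
  missing <- required[vapply(required, function(k) is.null(results[[k]]), TRUE)]
  if (length(missing))
    stopf("incomplete results; missing: %s", paste(missing, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(results$subjects, "subjects.csv")
  wr(results$accuracy, "accuracy.csv")
  wr(results$arp_runs, "arp_runs.csv")
  wr(results$delta_rp_topo, "delta_rp_topo.csv")
  wr(results$erd_topo, "erd_topo.csv")
  if (!is.null(results$fc_contrasts)) wr(results$fc_contrasts,
                                         "fc_contrasts.csv")
  co <- results$correlation
  wr(data.frame(r = if (is.null(co)) NA else co$estimate,
                p = if (is.null(co)) NA else co$p_value,
                n = if (is.null(co)) NA else co$n), "correlation.csv")
  cfg <- results$config
  cfg$nft_config <- unclass(cfg$nft_config)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  log <- list(config = jsonlite::fromJSON(cfg_json),
              config_hash = sum(utf8ToInt(as.character(cfg_json)) *
                                  seq_along(utf8ToInt(as.character(cfg_json)))) %%
                2147483647,
              package_version = as.character(utils::packageVersion("alphanft")),
              timestamp = "deterministic-output")
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
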