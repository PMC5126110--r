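#' Analysis configuration with the canonical defaults
#'
#' The single source of the analysis constants: the five band definitions
#' with their FIR lengths, the 250 Hz working rate, the 180-s analysis
#' segment, the 20-scale cubic-detrend DFA rules, 1000-iteration bootstrap
#' at alpha 0.05, and TFCE with e = 0.66, h = 2, 1000 permutations.
#' Unknown keys are rejected, so a typo cannot silently fall back to a
#' default.
#'
#' @param ... overrides for any of the default keys.
#' @return an object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(...) {
  defaults <- list(
    bands = default_bands(),
    fs = 250,
    segment_start = 0,
    segment_duration = 180,
    dfa_n_scales = 20L,
    dfa_poly_order = 3L,
    stats_n_boot = 1000L,
    stats_alpha = 0.05,
    tfce_e = 0.66,
    tfce_h = 2,
    tfce_n_steps = 100L,
    tfce_n_perm = 1000L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(over)] <- over                     # whole-value replacement
  if (cfg$fs <= 0 || cfg$segment_duration <= 0) stop("fs and segment_duration must be positive")
  if (cfg$stats_alpha <= 0 || cfg$stats_alpha >= 1) stop("stats_alpha must lie in (0, 1)")
  structure(cfg, class = "analysis_config")
}

#' Cohort-level statistics on one condition's H matrix
#'
#' The participant-level inference chain: grand-median H per participant;
#' type-II GLM on group, ISI and their interaction; rank-sum group
#' follow-up; within-group Spearman follow-ups with ISI; per-band
#' across-electrode-median correlation profiles with bootstrap CIs per
#' group; and spatio-spectral TFCE correlation inference per group.
#'
#' @param hm an [h_matrix()] for all participants of one condition.
#' @param cohort cohort data frame aligned with `hm`'s participants.
#' @param config an [analysis_config()].
#' @param adj optional [bin_adjacency()]; defaults to the montage carried
#'   by `hm`.
#' @param run_tfce set `FALSE` to skip the permutation stage.
#' @return list with `glm`, `ranksum`, `spearman_within`, `band_profiles`,
#'   `tfce` (per group), `grand_median`, `condition`.
#' @export
analyze_h <- function(hm, cohort, config = analysis_config(), adj = NULL,
                      run_tfce = TRUE) {
  stopifnot(inherits(hm, "h_matrix"))
  if (nrow(cohort) != dim(hm)[1]) stop("cohort and h_matrix participant counts differ")
  if (!identical(as.character(cohort$id), dimnames(hm)[[1]])) {
    stop("cohort ids and h_matrix participants do not match")
  }
  gm <- grand_median_h(hm)
  bm <- band_median_h(hm)
  groups <- levels(factor(cohort$group))
  seed <- config$seed

  glm_res <- glm_type2(gm, cohort)
  rs <- ranksum_test(gm[cohort$group == "ID"], gm[cohort$group == "CTRL"])
  spearman_within <- lapply(stats::setNames(groups, groups), function(g) {
    i <- cohort$group == g
    spearman_test(cohort$isi[i], gm[i])
  })

  band_profiles <- lapply(stats::setNames(groups, groups), function(g) {
    i <- which(cohort$group == g)
    rows <- lapply(colnames(bm), function(b) {
      ci <- bootstrap_rho_ci(cohort$isi[i], bm[i, b],
                             n_boot = config$stats_n_boot,
                             seed = derive_seed(seed, paste0("boot_", g, "_", b)))
      data.frame(band = b, rho = ci$rho, t = ci$statistic, df = ci$df,
                 p = ci$p, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
                 robust = ci$robust, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  tfce <- NULL
  if (run_tfce) {
    if (is.null(adj)) {
      montage <- attr(hm, "montage")
      if (is.null(montage)) stop("TFCE requested but no montage/adjacency available")
      adj <- bin_adjacency(montage, dim(hm)[3])
    }
    tfce <- lapply(stats::setNames(groups, groups), function(g) {
      i <- which(cohort$group == g)
      sub <- h_matrix(unclass(hm)[i, , , drop = FALSE],
                      condition = attr(hm, "condition"))
      pars <- tfce_params(e_exponent = config$tfce_e,
                          h_exponent = config$tfce_h,
                          n_steps = config$tfce_n_steps,
                          n_perm = config$tfce_n_perm,
                          alpha = config$stats_alpha,
                          seed = derive_seed(seed, paste0("tfce_", g)))
      res <- tfce_correlation(sub, cohort$isi[i], adj = adj, params = pars)
      list(result = res,
           summary = summarize_spatiospectral(res, config$stats_alpha))
    })
  }

  list(condition = attr(hm, "condition"), grand_median = gm,
       band_median = bm, glm = glm_res, ranksum = rs,
       spearman_within = spearman_within, band_profiles = band_profiles,
       tfce = tfce)
}

#' Run the full pipeline on per-condition recordings
#'
#' Per condition: band filtering, Hilbert envelopes, DFA Hurst matrix,
#' then [analyze_h()]. If both EO and EC are supplied, the EO-EC
#' [condition_contrast()] is added. Results, tables and a run manifest are
#' written under `out_dir` when given.
#'
#' @param recordings_by_condition named list (`EO`, `EC`, or one of them)
#'   of lists of [recording()]s, one per participant, names = ids.
#' @param cohort cohort data frame.
#' @param montage a [generate_montage()] result.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory.
#' @return list with per-condition `analysis`, `h` matrices, optional
#'   `contrast`, and `manifest`.
#' @export
run_pipeline <- function(recordings_by_condition, cohort, montage,
                         config = analysis_config(), out_dir = NULL) {
  t0 <- Sys.time()
  conds <- names(recordings_by_condition)
  if (is.null(conds) || !all(conds %in% c("EO", "EC"))) {
    stop("recordings_by_condition must be named with conditions EO/EC")
  }
  hms <- lapply(stats::setNames(conds, conds), function(cd) {
    recs <- recordings_by_condition[[cd]]
    recs <- lapply(recs, function(r) {
      crop_segment(r, config$segment_start, config$segment_duration)
    })
    compute_h_matrix(recs, config$bands, montage = montage, condition = cd)
  })
  adj <- bin_adjacency(montage, length(config$bands))
  analyses <- lapply(hms, analyze_h, cohort = cohort, config = config, adj = adj)
  contrast <- NULL
  if (all(c("EO", "EC") %in% conds)) {
    contrast <- condition_contrast(hms$EO, hms$EC)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("envlrtc")),
    seed = config$seed,
    n_participants = nrow(cohort),
    n_electrodes = length(montage$labels),
    bands = vapply(config$bands, `[[`, "", "name"),
    conditions = conds,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- list(h = hms, analysis = analyses, contrast = contrast,
              manifest = manifest)
  if (!is.null(out_dir)) write_report(out, cohort, out_dir)
  out
}

# Strip non-serialisable bulk from an analysis list for the JSON report.
.report_analysis <- function(an) {
  list(
    condition = an$condition,
    glm = as.data.frame(an$glm),
    ranksum = an$ranksum[c("z", "p")],
    spearman_within = lapply(an$spearman_within, function(s) {
      s[c("rho", "n", "df", "statistic", "p")]
    }),
    band_profiles = an$band_profiles,
    tfce_summary = if (!is.null(an$tfce)) lapply(an$tfce, `[[`, "summary")
  )
}

#' Write the results bundle
#'
#' Emits `report.json` (GLM table, follow-up tests, per-band bootstrap
#' profiles, TFCE summaries per group), per-condition H matrices and TFCE
#' maps as long-format TSV, the cohort table, and `manifest.json`.
#'
#' @param results a [run_pipeline()] result list.
#' @param cohort the cohort table.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(analyses = lapply(results$analysis, .report_analysis),
                 contrast = results$contrast)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  for (cd in names(results$h)) {
    write_h_matrix(results$h[[cd]], file.path(out_dir, paste0("h_", cd, ".tsv")))
    an <- results$analysis[[cd]]
    if (!is.null(an$tfce)) {
      for (g in names(an$tfce)) {
        r <- an$tfce[[g]]$result
        long <- expand.grid(electrode = rownames(r$p), band = colnames(r$p),
                            stringsAsFactors = FALSE)
        long$rho <- as.numeric(r$rho)
        long$t <- as.numeric(r$t)
        long$t_tfce <- as.numeric(r$t_tfce)
        long$p <- as.numeric(r$p)
        utils::write.table(long,
                           file.path(out_dir, sprintf("tfce_%s_%s.tsv", cd, g)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(out_dir)
}
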