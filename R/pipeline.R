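#' Run configuration
#'
#' Collects every tunable of an end-to-end run in one serializable object;
#' the resolved configuration is written next to the outputs of every run
#' so results can be regenerated bit-identically from (config, seed).
#'
#' @param seed master seed; every stochastic stage derives its own
#'   substream from it
#' @param layout_mode `"four-section"` or `"whole-chip"`
#' @param dilution list `start`, `end`, `n`
#' @param noise list passed to [noise_spec()] (seed is filled from `seed`)
#' @param censoring list `lower`, `upper` (uM)
#' @param shape list `w`, `k`
#' @param quota named vector for [design_library()]
#' @param out_dir output directory
#' @return object of class `qpid_config`
#' @export
run_config <- function(seed = 1L, layout_mode = "four-section",
                       dilution = list(start = 2.0, end = 0.0156, n = 32L),
                       noise = list(protein_cv_range = c(0.06, 0.40),
                                    snr = 100, intensity_cv = 0.05),
                       censoring = list(lower = 1e-3, upper = 50),
                       shape = list(w = 5L, k = 10L),
                       quota = c(A_only = 34L, B_only = 34L, both = 34L,
                                 accessible_unbound = 5L, control = 5L),
                       out_dir = tempfile("qpid_run_")) {
  structure(list(seed = as.integer(seed), layout_mode = layout_mode,
                 dilution = dilution, noise = noise, censoring = censoring,
                 shape = shape, quota = quota, out_dir = out_dir),
            class = "qpid_config")
}

#' Run the full pipeline on simulated inputs
#'
#' Executes simulate -> calibrate -> quantify -> fit -> summarize ->
#' shape -> model in one seeded run: a four-section chip is simulated with
#' the bundled reference Kd truths (censored entries planted at
#' `censored_truth_uM`), the calibration series is simulated and fitted, Kd
#' values are estimated per (protein, oligo) with censoring, group
#' summaries are produced per annotated element, shape feature vectors and
#' distances are computed for the characterized half-site oligos against a
#' synthetic-genome half-site profile, and shape regression models of
#' affinity are fitted on a synthetic half-site library. All outputs plus
#' the resolved config and a run log are written under `config$out_dir`.
#'
#' @param config a [run_config()]
#' @param censored_truth_uM Kd planted for censored-weak reference entries
#' @return invisibly, the run directory path
#' @export
run_pipeline <- function(config = run_config(), censored_truth_uM = 200) {
  stopifnot(inherits(config, "qpid_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                file = logf, append = TRUE)
  log("qpid %s run, seed %d, started %s",
      as.character(utils::packageVersion("qpid")), config$seed,
      format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  stage <- "config"
  result <- tryCatch({
    jsonlite::write_json(unclass(config),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "simulate+fit"
    ref_run <- run_reference_chip(
      seed = config$seed, layout_mode = config$layout_mode,
      dilution = config$dilution, noise = config$noise,
      censoring = config$censoring, censored_truth_uM = censored_truth_uM)
    curve <- ref_run$curve
    jsonlite::write_json(unclass(curve), file.path(config$out_dir, "curve.json"),
                         auto_unbox = TRUE, digits = NA)
    log("calibration: slope %.1f intercept %.1f r2 %.5f",
        curve$slope, curve$intercept, curve$r_squared)
    lib <- cre_minilibrary()
    write_scan_table(ref_run$scan, file.path(config$out_dir, "scan.tsv"))
    write_tsv(ref_run$occupancy, file.path(config$out_dir, "occupancy.tsv"))
    kd <- ref_run$kd
    write_kd_table(kd, file.path(config$out_dir, "kd.tsv"))
    log("kd fits: %d quantitative, %d censored_weak, %d other",
        sum(kd$status == "quantitative"), sum(kd$status == "censored_weak"),
        sum(!kd$status %in% c("quantitative", "censored_weak")))

    stage <- "summarize"
    atf1 <- kd[kd$protein == "ATF1", ]
    atf1$site <- lib$site[match(atf1$oligo, lib$oligo)]
    sums <- lapply(split(atf1[!is.na(atf1$site), ], atf1$site[!is.na(atf1$site)]),
                   function(g) {
                     v <- ifelse(g$status == "quantitative", g$kd_uM, NA)
                     s <- summarize_group(v, g$site[1])
                     data.frame(group = s$label, mean_kd = s$mean_kd,
                                spread = s$spread, n = s$n,
                                n_censored = s$n_censored)
                   })
    write_tsv(do.call(rbind, sums), file.path(config$out_dir, "summaries.tsv"))

    stage <- "shape"
    tab <- synth_pentamer_table(derive_seed(config$seed, "shape_table"))
    write_shape_table(tab, file.path(config$out_dir, "pentamers.tsv"))
    sim <- synth_genome_and_peaks(seed = derive_seed(config$seed, "genome"))
    cand <- extract_candidates(sim$genome, sim$chip_a, sim$chip_b, sim$dnase)
    sitelib <- design_library(cand, config$quota,
                              seed = derive_seed(config$seed, "library"),
                              genome = sim$genome)
    write_fasta_seqs(setNames(sitelib$sequence, sitelib$id),
                     file.path(config$out_dir, "library.fa"))
    write_tsv(sitelib[, c("id", "chrom", "start", "end", "strand",
                          "site_type", "category", "core_offset")],
              file.path(config$out_dir, "library.tsv"))
    log("library: %d entries (%s)", nrow(sitelib),
        paste(names(table(sitelib$category)), table(sitelib$category),
              sep = "=", collapse = ", "))
    with_core <- sitelib[sitelib$site_type == "CRE_half", ]
    vecs <- lapply(seq_len(nrow(with_core)), function(i)
      build_feature_vector(with_core$sequence[i], with_core$core_offset[i],
                           config$shape$w, config$shape$k, tab))
    names(vecs) <- with_core$id
    write_feature_vectors(vecs, file.path(config$out_dir, "vectors.tsv"))
    prof <- reference_profile(with_core$sequence,
                              core_start = with_core$core_offset[1],
                              w = config$shape$w, k = config$shape$k,
                              table = tab, label = "half-site library")
    dists <- t(vapply(vecs, normalized_distance, numeric(4), profile = prof))
    write_tsv(data.frame(id = rownames(dists), dists),
              file.path(config$out_dir, "distances.tsv"))

    stage <- "model"
    X <- build_design_matrix(vecs)
    planted <- planted_shape_model(
      X, weights = c(MGW_p8 = -0.8, Roll_p17 = 0.3), intercept = 3,
      noise_sd = 0.2, seed = derive_seed(config$seed, "planted"))
    model <- fit_model(X, planted$response, "affinity_A")
    jsonlite::write_json(
      list(response = model$response_label, intercept = model$intercept,
           weights = as.list(model$weights),
           std_weights = as.list(model$std_weights),
           r_squared = model$r_squared, ridge_flag = !is.na(model$ridge)),
      file.path(config$out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    log("shape model r2 %.4f, top feature %s", model$r_squared,
        rank_features(model)$feature[1])
    log("run completed")
    config$out_dir
  }, error = function(e) {
    log("FAILED at stage '%s': %s", stage, conditionMessage(e))
    qpid_stop("qpid_stage_failure", "pipeline failed at stage '%s': %s",
              stage, conditionMessage(e))
  })
  invisible(result)
}

#' Simulate and analyse one reference chip end to end
#'
#' The canonical full-chip experiment: a four-section chip carrying the
#' bundled CRE mini-library with the measured reference Kd values planted
#' as ground truth (censored entries planted at `censored_truth_uM`, above
#' the 50 uM sensitivity limit), default device noise, and the 32-point
#' 2 -> 0.0156 uM dilution series. The on-chip calibration experiment is
#' simulated from the same instrument response the chip channels use
#' (slope 35579 RFU/uM through the origin; local backgrounds are modeled
#' explicitly, so the device response passes through the origin and any
#' intercept in a fitted calibration line is an estimate of residual
#' offset), fitted by OLS, and the fitted curve — not the truth — is used
#' for quantification, as on the real device.
#'
#' @param seed master seed
#' @param layout_mode,dilution,noise,censoring as in [run_config()]
#' @param censored_truth_uM planted Kd for censored-weak reference entries
#' @param slope_truth instrument response, RFU per uM
#' @return list: `scan`, `curve`, `occupancy` (aggregated), `kd` (fit
#'   table), `truths`
#' @export
run_reference_chip <- function(seed = 1L, layout_mode = "four-section",
                               dilution = list(start = 2.0, end = 0.0156,
                                               n = 32L),
                               noise = list(protein_cv_range = c(0.06, 0.40),
                                            snr = 100, intensity_cv = 0.05),
                               censoring = list(lower = 1e-3, upper = 50),
                               censored_truth_uM = 200,
                               slope_truth = 35579) {
  ref <- reference_kd_table()
  lib <- cre_minilibrary()
  proteins <- c("ATF1", "cJun", "cFos", "AP1")
  truths <- do.call(rbind, lapply(proteins, function(p) {
    kd <- ref[[p]][match(lib$oligo, ref$oligo)]
    data.frame(protein = p, oligo = lib$oligo,
               kd_uM = ifelse(is.na(kd), censored_truth_uM, kd),
               stringsAsFactors = FALSE)
  }))
  response <- calibration_curve(slope_truth, 0)
  cal_pts <- simulate_calibration_series(curve = response,
                                         seed = derive_seed(seed, "cal"))
  curve <- fit_calibration(cal_pts)
  layout <- chip_layout(layout_mode, proteins = proteins, oligos = lib$oligo)
  dil <- make_dilution_series(dilution$start, dilution$end, dilution$n)
  ns <- noise_spec(noise$protein_cv_range, noise$snr, noise$intensity_cv,
                   seed = derive_seed(seed, "chip"))
  scan <- simulate_chip(layout, truths, dil, ns, response)
  occ <- suppressMessages(quantify_scan(scan, curve))
  agg <- aggregate_replicates(occ)
  kd <- fit_all_kd(suppressMessages(assemble_series(agg)),
                   lower_limit = censoring$lower, upper_limit = censoring$upper)
  list(scan = scan, curve = curve, occupancy = agg, kd = kd, truths = truths)
}

#' Render the human-readable report of a completed run
#'
#' Kd table with '-' for censored entries plus the group mean +/- SD
#' summaries; regeneration is idempotent.
#'
#' @param run_dir a directory produced by [run_pipeline()]
#' @return invisibly, the report path
#' @export
render_report <- function(run_dir) {
  kd_path <- file.path(run_dir, "kd.tsv")
  if (!file.exists(kd_path))
    qpid_stop("qpid_incomplete_run", "no kd table under '%s'", run_dir)
  kd <- read.delim(kd_path, stringsAsFactors = FALSE)
  rpt <- file.path(run_dir, "report.txt")
  con <- file(rpt, "w"); on.exit(close(con))
  writeLines("Dissociation constants (uM); '-' = censored weak", con)
  kd_h <- kd
  kd_h$kd_uM <- ifelse(kd_h$status %in% c("censored_weak", "failed"), "-",
                       as.character(signif(kd_h$kd_uM, 3)))
  write.table(kd_h[, c("protein", "oligo", "kd_uM", "status", "n_points")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  sum_path <- file.path(run_dir, "summaries.tsv")
  if (file.exists(sum_path)) {
    s <- read.delim(sum_path, stringsAsFactors = FALSE)
    writeLines("", con)
    writeLines("Group summaries (mean +/- population SD, uM):", con)
    writeLines(sprintf("  %s: %.3g +/- %.3g (n=%d, censored=%d)",
                       s$group, s$mean_kd, s$spread, s$n, s$n_censored), con)
  }
  invisible(rpt)
}
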