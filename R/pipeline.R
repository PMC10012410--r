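#' Declarative run configuration
#'
#' Exactly one input source must be given: either a phantom specification
#' (synthetic run) or a list of real input paths (`dsc`, `anatomical`,
#' `labels`, optionally `ratings`). Every output records the seed and a hash
#' of the configuration, so a rerun with the same configuration is
#' reproducible.
#'
#' @param phantom A [phantom_spec()], or `NULL`.
#' @param inputs Named list of input paths, or `NULL`.
#' @param scenario A [scenario_spec()] for phantom runs.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param aif [aif_model()] used for simulation; set `select_aif = TRUE` to
#'   run automated AIF selection on the series instead.
#' @param select_aif Run automated AIF selection (default TRUE).
#' @param threshold_fraction SVD truncation threshold.
#' @param noise_sigma Simulation noise level (phantom runs).
#' @param register If `TRUE` (default), run the rigid registration stage;
#'   otherwise assume label and perfusion grids are aligned.
#' @param n_ictal,n_postictal Cohort sizes for [run_cohort()].
#' @param ictal,postictal Cohort [scenario_spec()]s for [run_cohort()].
#' @param subject_cv Between-subject variability for [run_cohort()].
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), inputs = NULL,
                       scenario = scenario_spec("ictal"),
                       out_dir = tempfile("tpma_run_"), seed = 1L,
                       aif = aif_model(), select_aif = TRUE,
                       threshold_fraction = 0.1, noise_sigma = 0,
                       register = TRUE,
                       n_ictal = 10L, n_postictal = 17L,
                       ictal = scenario_spec("ictal"),
                       postictal = scenario_spec("postictal"),
                       subject_cv = 0.2,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.null(phantom) && !is.null(inputs))
    stop("config invalid: give either a phantom spec or real inputs, not both")
  if (is.null(phantom) && is.null(inputs))
    stop("config invalid: one of phantom spec or real inputs is required")
  structure(list(phantom = phantom, inputs = inputs, scenario = scenario,
                 out_dir = out_dir, seed = as.integer(seed), aif = aif,
                 select_aif = select_aif,
                 threshold_fraction = threshold_fraction,
                 noise_sigma = noise_sigma, register = register,
                 n_ictal = n_ictal, n_postictal = n_postictal,
                 ictal = ictal, postictal = postictal,
                 subject_cv = subject_cv, log_level = log_level),
            class = "run_config")
}

.log <- function(config, ...) {
  if (config$log_level != "quiet")
    message(format(Sys.time(), "%H:%M:%S"), " [tpmaquant] ", ...)
}

.config_hash <- function(config) {
  plain <- utils::capture.output(utils::str(config, give.attr = FALSE))
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(paste(plain, collapse = "\n")))
    h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full single-subject analysis
#'
#' For a phantom configuration: build the phantom, inject the scenario's
#' ground truth, simulate the bolus passage, compute the six perfusion maps,
#' rigidly register the tMIP map to the anatomy, pull the labels into
#' perfusion space via the inverse transform, and derive ROI statistics,
#' intra-individual z-scores and asymmetry indices. For real inputs the same
#' chain starts from the files on disk. All stage outputs are written under
#' `config$out_dir` together with a provenance record (seed, configuration
#' hash, package version).
#'
#' @param config A [run_config()].
#' @param subject_id Subject identifier used in file names.
#' @return A list of class `subject_bundle`: `maps` (`perfusion_maps`),
#'   `labels_perf` (labels in perfusion space), `stats` (ROI table with z),
#'   `gm`, `ai`, `lobar`, `transform`, `files`.
#' @export
run_subject <- function(config, subject_id = "sub-01") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  if (!is.null(config$phantom)) {
    .log(config, "stage phantom: building synthetic subject ", subject_id)
    ph <- make_label_phantom(config$phantom)
    truth <- make_perfusion_truth(ph, config$scenario)
    series <- simulate_dsc(truth, aif = config$aif,
                           noise_sigma = config$noise_sigma,
                           seed = config$seed, arterial_mask = ph$artery)
    anat <- ph$anatomy; anat_affine <- ph$affine
    labels <- ph$labels
    dsc_affine <- ph$affine
    brain <- truth$cbf > 0
  } else {
    .log(config, "stage io: reading inputs for ", subject_id)
    dscv <- read_volume(config$inputs$dsc)
    side <- file.path(dirname(config$inputs$dsc),
                      sub("\\.nii(\\.gz)?$", ".json", basename(config$inputs$dsc)))
    acq <- if (file.exists(side)) .parse_sidecar(side) else list(tr = 1, te = 0.03)
    series <- structure(list(signal = dscv$data, tr = acq$tr, te = acq$te,
                             time = (seq_len(dim(dscv$data)[4]) - 1) * acq$tr,
                             baseline_window = 1:8),
                        class = "dsc_series")
    dsc_affine <- dscv$affine
    anatv <- read_volume(config$inputs$anatomical)
    anat <- anatv$data; anat_affine <- anatv$affine
    labv <- read_volume(config$inputs$labels)
    lut <- utils::read.csv(config$inputs$lut, stringsAsFactors = FALSE)
    labels <- structure(list(labels = labv$data, lut = lut,
                             affine = labv$affine), class = "label_map")
    brain <- apply(series$signal, 1:3, function(s) mean(s[1:8]) > 0)
  }

  .log(config, "stage dsc_quant: AIF selection + SVD deconvolution")
  aif <- if (config$select_aif) select_aif(series, brain) else config$aif
  maps <- compute_maps(series, brain, aif = aif,
                       threshold_fraction = config$threshold_fraction)

  if (config$register) {
    .log(config, "stage registration: tMIP -> anatomy (6 DOF, MI)")
    tmip0 <- maps$tmip
    tmip0[is.na(tmip0)] <- 0
    transform <- rigid_register(tmip0, anat, dsc_affine, anat_affine)
    labels_perf <- resample_labels(labels, transform, dsc_affine,
                                   dim(maps$rcbf))
  } else {
    transform <- rigid_transform()
    labels_perf <- labels
  }

  .log(config, "stage roi_metrics: ROI statistics, z-scores, asymmetry")
  rs <- roi_statistics(maps$rcbf, labels_perf)
  stats <- intra_subject_zscores(rs)
  ai <- asymmetry_indices(rs)
  lobar <- lobar_aggregate(rs)

  .log(config, "stage io: writing outputs")
  files <- character(0)
  for (mp in c("rcbf", "rcbv", "mtt", "ttp", "tmip", "tmax")) {
    f <- file.path(config$out_dir, paste0(subject_id, "_", mp, ".nii.gz"))
    m <- maps[[mp]]; m[is.na(m)] <- 0
    files <- c(files, write_volume(m, f, dsc_affine))
  }
  files <- c(files, write_roi_tables(stats, ai, config$out_dir, subject_id))
  f_lob <- file.path(config$out_dir, paste0(subject_id, "_lobar.csv"))
  utils::write.csv(cbind(subject_id = subject_id, lobar), f_lob, row.names = FALSE)
  f_tf <- file.path(config$out_dir, paste0(subject_id, "_transform.mat"))
  write_transform(transform, f_tf)
  prov <- file.path(config$out_dir, paste0(subject_id, "_provenance.json"))
  writeLines(sprintf(
    '{"subject_id": "%s", "seed": %d, "config_hash": "%s", "package_version": "%s"}',
    subject_id, config$seed, .config_hash(config),
    as.character(utils::packageVersion("tpmaquant"))), prov)
  files <- c(files, f_lob, f_tf, prov)
  .log(config, "subject ", subject_id, " done in ",
       round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 1), " s")
  structure(list(maps = maps, labels_perf = labels_perf, stats = stats,
                 gm = rs$gm, ai = ai, lobar = lobar, transform = transform,
                 files = files),
            class = "subject_bundle")
}

.parse_sidecar <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  grab <- function(key) {
    m <- regmatches(txt, regexec(paste0('"', key, '"\\s*:\\s*([0-9.eE+-]+)'), txt))[[1]]
    if (length(m) < 2) stop("sidecar missing '", key, "'")
    as.numeric(m[2])
  }
  list(tr = grab("tr"), te = grab("te"))
}

#' Run the full cohort analysis
#'
#' Simulates (or assembles) the ictal/postictal cohort, then produces the
#' cohort-level results: lobar rank-sum comparisons of mean rCBF between the
#' cohorts, thalamic z-score sign counts, categorical perfusion proportions
#' with the chi-square independence test, inter-rater Cohen's kappa at
#' subject and region level with per-category agreement, and the comparison
#' of quantitative asymmetry indices to the consensus visual lateralization.
#' A human-readable markdown report plus machine-readable CSV tables are
#' written to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list of class `cohort_report` with elements `comparisons`,
#'   `sign_counts`, `proportions`, `chisq`, `kappa_subject`, `kappa_region`,
#'   `agreement`, `ai_concordance`, `cohort` (the simulated bundle) and
#'   `files`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .log(config, "stage phantom: simulating cohort (",
       config$n_ictal, " ictal / ", config$n_postictal, " postictal)")
  cohort <- simulate_cohort(config$n_ictal, config$n_postictal,
                            phantom = config$phantom, ictal = config$ictal,
                            postictal = config$postictal,
                            subject_cv = config$subject_cv, seed = config$seed)
  subj <- cohort$subjects
  comparative <- config$n_ictal > 0 && config$n_postictal > 0

  .log(config, "stage roi_metrics: per-subject lobar tables, z, AI")
  lob_rows <- NULL; z_rows <- NULL; ai_rows <- NULL
  for (sid in unique(subj$subject_id)) {
    ss <- subj[subj$subject_id == sid, ]
    gm <- .pool_rows(ss$n_voxels[.is_cortical(ss$lobe)],
                     ss$mean[.is_cortical(ss$lobe)],
                     ss$sd[.is_cortical(ss$lobe)])
    gm <- list(mean = gm$mean, sd = gm$sd, n_voxels = gm$n)
    lb <- lobar_aggregate(ss)
    lob_rows <- rbind(lob_rows, cbind(subject_id = sid, cohort = ss$cohort[1],
                                      lb, stringsAsFactors = FALSE))
    zz <- intra_subject_zscores(ss, gm)
    z_rows <- rbind(z_rows, zz)
    lbh <- lobar_aggregate(ss, by_hemisphere = TRUE)
    aa <- asymmetry_indices(data.frame(name = lbh$region,
                                       hemisphere = lbh$hemisphere,
                                       lobe = lbh$region, mean = lbh$mean,
                                       stringsAsFactors = FALSE))
    ai_rows <- rbind(ai_rows, data.frame(subject_id = sid, region = aa$name,
                                         ai = aa$ai, stringsAsFactors = FALSE))
  }

  comparisons <- NULL; sign_counts <- NULL; chisq <- NULL; proportions <- NULL
  if (comparative) {
    .log(config, "stage group_analysis: rank-sum comparisons")
    ct <- data.frame(subject_id = lob_rows$subject_id, cohort = lob_rows$cohort,
                     region = lob_rows$region, value = lob_rows$mean,
                     stringsAsFactors = FALSE)
    comparisons <- compare_groups(ct)
    sign_counts <- thalamic_sign_counts(z_rows)
  }
  cons <- if (is.null(cohort$ratings)) NULL else
    cohort$ratings[cohort$ratings$rater == "consensus" &
                     cohort$ratings$level == "subject", ]
  if (!is.null(cons) && nrow(cons)) {
    rep_df <- data.frame(subject_id = cons$subject_id,
                         cohort = subj$cohort[match(cons$subject_id, subj$subject_id)],
                         category = cons$category, stringsAsFactors = FALSE)
    proportions <- categorical_proportions(rep_df)
    if (comparative) {
      tab <- table(rep_df$cohort, rep_df$category)
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (all(dim(tab) >= 2))
        chisq <- chi_square_independence(tab)
    }
  }

  .log(config, "stage concordance: inter-rater agreement, AI vs ratings")
  rr <- cohort$ratings
  kappa_subject <- NULL; kappa_region <- NULL; agreement <- NULL
  ai_conc <- NULL
  if (!is.null(rr) && nrow(rr)) {
    pick <- function(rater, level) {
      x <- rr[rr$rater == rater & rr$level == level, ]
      x[order(x$subject_id, x$region), "category"]
    }
    kappa_subject <- cohens_kappa(pick("r1", "subject"), pick("r2", "subject"))
    kappa_region <- cohens_kappa(pick("r1", "region"), pick("r2", "region"))
    agreement <- vapply(.subject_categories, function(cc)
      category_agreement(pick("r1", "subject"), pick("r2", "subject"), cc),
      numeric(1))
    cons_reg <- rr[rr$rater == "consensus" & rr$level == "region",
                   c("subject_id", "region", "category")]
    ai_conc <- tryCatch(ai_rating_concordance(ai_rows, cons_reg),
                        error = function(e) NULL)
  } else {
    .log(config, "no ratings available; concordance section skipped")
  }

  files <- .write_cohort_report(config, comparisons, sign_counts, proportions,
                                chisq, kappa_subject, kappa_region, agreement,
                                ai_conc, comparative)
  structure(list(comparisons = comparisons, sign_counts = sign_counts,
                 proportions = proportions, chisq = chisq,
                 kappa_subject = kappa_subject, kappa_region = kappa_region,
                 agreement = agreement, ai_concordance = ai_conc,
                 cohort = cohort, z_table = z_rows, lobar = lob_rows,
                 ai_table = ai_rows, files = files),
            class = "cohort_report")
}

.write_cohort_report <- function(config, comparisons, sign_counts, proportions,
                                 chisq, kappa_subject, kappa_region, agreement,
                                 ai_conc, comparative) {
  out <- config$out_dir
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    f <- file.path(out, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(comparisons, "group_comparisons.csv")
  wr(sign_counts, "thalamic_sign_counts.csv")
  if (!is.null(proportions)) wr(proportions$proportions, "categorical_proportions.csv")

  lines <- c("# Cohort perfusion report", "",
             paste0("- seed: ", config$seed),
             paste0("- config hash: ", .config_hash(config)), "",
             "## Group-wise rCBF comparisons (rank-sum)", "")
  if (comparative && !is.null(comparisons)) {
    lines <- c(lines, "| region | U | p | direction |", "|---|---|---|---|",
               sprintf("| %s | %.1f | %.3g | %s |", comparisons$region,
                       comparisons$U, comparisons$p, comparisons$direction))
  } else {
    lines <- c(lines, "_not computed (single-cohort input)_")
  }
  lines <- c(lines, "", "## Thalamic z-score sign counts", "")
  if (!is.null(sign_counts)) {
    lines <- c(lines, "| cohort | side | z>0 | z<0 | z=0 |", "|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %d | %d |", sign_counts$cohort,
                       sign_counts$side, sign_counts$n_pos, sign_counts$n_neg,
                       sign_counts$n_zero))
  } else lines <- c(lines, "_not computed (single-cohort input)_")
  lines <- c(lines, "", "## Categorical perfusion proportions", "")
  if (!is.null(proportions)) {
    pp <- proportions$proportions
    lines <- c(lines, "| cohort | category | n | percent |", "|---|---|---|---|",
               sprintf("| %s | %s | %d | %d%% |", pp$cohort, pp$category, pp$n,
                       pp$percent),
               "",
               sprintf("Hyperperfusion sensitivity for the ictal state: %d%%.",
                       proportions$sensitivity$percent))
    if (!is.null(chisq))
      lines <- c(lines, sprintf("Chi-square independence: X2 = %.2f, df = %d, p = %.3g.",
                                chisq$chisq, chisq$df, chisq$p))
  } else lines <- c(lines, "_no ratings available; section skipped_")
  lines <- c(lines, "", "## Inter-rater agreement", "")
  if (!is.null(kappa_subject)) {
    lines <- c(lines,
               sprintf("- subject-level Cohen's kappa: %.3f (p_o = %.3f)",
                       kappa_subject$kappa, kappa_subject$p_o),
               sprintf("- region-level Cohen's kappa: %.3f (p_o = %.3f)",
                       kappa_region$kappa, kappa_region$p_o),
               sprintf("- per-category agreement: %s",
                       paste(sprintf("%s %.1f%%", names(agreement), agreement),
                             collapse = ", ")))
  } else lines <- c(lines, "_no ratings available; section skipped_")
  lines <- c(lines, "", "## Asymmetry vs consensus rating", "")
  if (!is.null(ai_conc)) {
    md <- ai_conc$medians
    lines <- c(lines,
               sprintf("- median AI: left-asymmetric %.3f, normal %.3f, right-asymmetric %.3f",
                       md[["left"]], md[["normal"]], md[["right"]]))
    for (side in c("left", "right"))
      if (!is.null(ai_conc$tests[[side]]))
        lines <- c(lines, sprintf("- %s-asymmetric vs normal: p = %.3g", side,
                                  ai_conc$tests[[side]]$p))
  } else lines <- c(lines, "_not computed_")
  f_rep <- file.path(out, "report.md")
  writeLines(lines, f_rep)
  c(files, f_rep)
}
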