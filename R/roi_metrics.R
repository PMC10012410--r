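.is_cortical <- function(lobe) lobe %in% names(.cortical_lobes)

#' ROI-wise descriptive statistics and grey-matter summary
#'
#' Computes per-ROI voxel count, mean and standard deviation of a perfusion
#' map over in-mask voxels, plus a pooled summary over all cortical
#' grey-matter voxels (the intra-individual normalization reference).
#' Subcortical structures — including the thalamus — and vessels are
#' excluded from the grey-matter pool.
#'
#' @param map 3D numeric array (a perfusion map; NA = masked out).
#' @param labels A `label_map` on the same grid.
#' @param mask Optional logical array; voxels outside are excluded.
#' @return A list of class `roi_stats`: `stats` (data.frame with id, name,
#'   hemisphere, lobe, n_voxels, mean, sd; ROIs with no in-mask voxels are
#'   reported with `n_voxels = 0` and flagged) and `gm`
#'   (list mean/sd/n_voxels over pooled cortical voxels).
#' @export
roi_statistics <- function(map, labels, mask = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (!all(dim(map) == dim(labels$labels)))
    stop("map and labels must be on the same grid")
  lut <- labels$lut
  lab <- as.vector(labels$labels)
  v <- as.vector(map)
  keep <- !is.na(v) & lab > 0
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  lab <- lab[keep]; v <- v[keep]
  f <- factor(lab, levels = lut$id)
  n <- as.integer(table(f))
  mu <- as.numeric(tapply(v, f, mean))
  sdev <- as.numeric(tapply(v, f, stats::sd))
  sdev[n == 1] <- 0
  stats <- data.frame(lut, n_voxels = n, mean = mu, sd = sdev,
                      stringsAsFactors = FALSE)
  stats$flagged <- stats$n_voxels == 0
  gm_sel <- .is_cortical(lut$lobe)[match(lab, lut$id)]
  gv <- v[gm_sel]
  gm <- list(mean = if (length(gv)) mean(gv) else NA_real_,
             sd = if (length(gv) > 1) stats::sd(gv) else NA_real_,
             n_voxels = length(gv))
  structure(list(stats = stats, gm = gm), class = "roi_stats")
}

#' Intra-individual z-scores against cortical grey matter
#'
#' `z_roi = (mu_roi - mu_GM) / sigma_GM`, where the reference mean and
#' standard deviation are taken over the subject's pooled cortical
#' grey-matter voxels. z-scores are invariant under any positive rescaling
#' of the map.
#'
#' @param stats A `roi_stats` object, or its `stats` data.frame.
#' @param gm Grey-matter summary (`list(mean, sd, n_voxels)`); taken from
#'   `stats` when it is a `roi_stats`.
#' @return The stats data.frame with a `z` column (NA for flagged ROIs).
#' @export
intra_subject_zscores <- function(stats, gm = NULL) {
  if (inherits(stats, "roi_stats")) {
    if (is.null(gm)) gm <- stats$gm
    stats <- stats$stats
  }
  if (is.null(gm)) stop("grey-matter summary required")
  if (!is.finite(gm$sd) || gm$sd <= 0)
    stop("degenerate map: sigma_GM must be positive")
  stats$z <- (stats$mean - gm$mean) / gm$sd
  if ("flagged" %in% names(stats)) stats$z[stats$flagged] <- NA_real_
  stats
}

#' Left/right asymmetry indices
#'
#' `AI = (lh - rh) / (lh + rh)` per name-matched left/right ROI pair,
#' computed on ROI means. The index ranges from +1 (fully left-lateralized)
#' to -1 (fully right-lateralized) and is 0 for symmetric regions; positive
#' values indicate higher perfusion on the left. Pairs with `lh + rh = 0`
#' are flagged with `AI = NA` and should be excluded downstream.
#'
#' @param stats A `roi_stats` object or a stats data.frame with columns
#'   name, hemisphere, lobe, mean (and optionally n_voxels).
#' @return Data.frame with columns name, lobe, lh, rh, ai, flagged.
#' @export
asymmetry_indices <- function(stats) {
  if (inherits(stats, "roi_stats")) stats <- stats$stats
  lh <- stats[stats$hemisphere == "left", ]
  rh <- stats[stats$hemisphere == "right", ]
  m <- match(lh$name, rh$name)
  if (anyNA(m)) stop("unpaired left ROIs: ", paste(lh$name[is.na(m)], collapse = ", "))
  rh <- rh[m, ]
  denom <- lh$mean + rh$mean
  ai <- ifelse(denom == 0, NA_real_, (lh$mean - rh$mean) / denom)
  data.frame(name = lh$name, lobe = lh$lobe, lh = lh$mean, rh = rh$mean,
             ai = ai, flagged = denom == 0, stringsAsFactors = FALSE)
}

# volume-weighted pooling of mean/sd rows (sample-sd convention)
.pool_rows <- function(n, mu, sdev) {
  N <- sum(n)
  if (N == 0) return(list(n = 0L, mean = NA_real_, sd = NA_real_))
  M <- sum(n * mu) / N
  ss <- sum((n - 1) * sdev^2 + n * mu^2) - N * M^2
  list(n = N, mean = M, sd = if (N > 1) sqrt(max(ss, 0) / (N - 1)) else 0)
}

#' Lobar aggregation of ROI statistics
#'
#' Volume-weighted pooling of cortical parcels into lobes (frontal,
#' parietal, temporal, occipital, insula), the thalamus reported alongside,
#' and a whole-cortex row that equals the grey-matter summary. Pooled
#' standard deviations use the exact total-sum-of-squares identity, so a
#' lobe's mean/sd equal the direct voxelwise values over the union of its
#' member parcels.
#'
#' @param stats A `roi_stats` object or stats data.frame.
#' @param by_hemisphere If `TRUE`, aggregate per (lobe, hemisphere) pair
#'   instead of pooling both sides.
#' @return Data.frame with region, hemisphere, n_voxels, mean, sd.
#' @export
lobar_aggregate <- function(stats, by_hemisphere = FALSE) {
  if (inherits(stats, "roi_stats")) stats <- stats$stats
  cortical <- stats[.is_cortical(stats$lobe) & stats$n_voxels > 0, ]
  bad <- stats$lobe == "" | is.na(stats$lobe)
  if (any(bad))
    stop("parcels without a lobe assignment: ",
         paste(unique(stats$name[bad]), collapse = ", "))
  thal <- stats[stats$name == "thalamus" & stats$n_voxels > 0, ]
  groups <- if (by_hemisphere)
    split(cortical, list(cortical$lobe, cortical$hemisphere), drop = TRUE)
  else split(cortical, cortical$lobe)
  rows <- lapply(names(groups), function(g) {
    gg <- groups[[g]]
    p <- .pool_rows(gg$n_voxels, gg$mean, gg$sd)
    data.frame(region = gg$lobe[1],
               hemisphere = if (by_hemisphere) gg$hemisphere[1] else "both",
               n_voxels = p$n, mean = p$mean, sd = p$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (nrow(thal)) {
    tg <- if (by_hemisphere) split(thal, thal$hemisphere) else list(both = thal)
    for (h in names(tg)) {
      p <- .pool_rows(tg[[h]]$n_voxels, tg[[h]]$mean, tg[[h]]$sd)
      out <- rbind(out, data.frame(region = "thalamus",
                                   hemisphere = if (by_hemisphere) h else "both",
                                   n_voxels = p$n, mean = p$mean, sd = p$sd,
                                   stringsAsFactors = FALSE))
    }
  }
  p <- .pool_rows(cortical$n_voxels, cortical$mean, cortical$sd)
  out <- rbind(out, data.frame(region = "whole_cortex", hemisphere = "both",
                               n_voxels = p$n, mean = p$mean, sd = p$sd,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write tidy ROI tables
#'
#' Emits the per-ROI statistics (with z-scores when present) and the
#' pairwise asymmetry table as CSV files.
#'
#' @param stats Stats data.frame (e.g. from [intra_subject_zscores()]).
#' @param ai Asymmetry data.frame from [asymmetry_indices()].
#' @param dir Output directory.
#' @param subject_id Subject identifier written into both tables.
#' @return Invisibly, the two file paths.
#' @export
write_roi_tables <- function(stats, ai, dir, subject_id = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(subject_id, "_roi_stats.csv"))
  f2 <- file.path(dir, paste0(subject_id, "_asymmetry.csv"))
  utils::write.csv(cbind(subject_id = subject_id, stats), f1, row.names = FALSE)
  utils::write.csv(cbind(subject_id = subject_id, ai), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
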