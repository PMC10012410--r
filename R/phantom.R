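#' Phantom specification
#'
#' Describes the geometry of a synthetic parcellated head phantom: an
#' ellipsoidal head with a white-matter core, a cortical grey-matter shell
#' partitioned into equal-angle parcels per hemisphere, subcortical nuclei
#' (always including left/right thalamus) and a small midline arterial
#' segment used for arterial-input-function selection tests.
#'
#' @param grid_shape Integer triple, phantom grid in voxels (each >= 16).
#' @param voxel_size Numeric triple, voxel edge lengths in mm.
#' @param n_cortical_parcels Cortical parcels per hemisphere (default 32,
#'   the DKT-style parcellation count used throughout the package).
#' @param subcortical Character vector of subcortical structure names; must
#'   include `"thalamus"`. Each structure is instantiated once per hemisphere.
#' @param seed Integer seed controlling the deterministic anatomical texture.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size = c(3, 3, 3),
                         n_cortical_parcels = 32L,
                         subcortical = "thalamus",
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three integers, each >= 16")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  n_cortical_parcels <- as.integer(n_cortical_parcels)
  if (n_cortical_parcels < 1L)
    stop("n_cortical_parcels must be >= 1")
  if (!"thalamus" %in% subcortical)
    stop("subcortical set must include 'thalamus'")
  if (anyDuplicated(subcortical))
    stop("subcortical structure names must be unique")
  # each equal-angle sector must span at least ~2 voxels of shell arc
  if (n_cortical_parcels > 4L * min(grid_shape))
    stop("grid too small to host ", n_cortical_parcels, " parcels per hemisphere")
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 n_cortical_parcels = n_cortical_parcels,
                 subcortical = subcortical,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Perfusion scenario specification
#'
#' Defines the ground-truth perfusion state injected into a phantom:
#' grey-matter baselines, a bilateral thalamic CBF multiplier (ictal
#' hyperperfusion > 1, postictal hypoperfusion < 1), an optional lateralized
#' cortical focus, measurement noise, and the rater error rate for the
#' simulated visual readings.
#'
#' @param scenario One of `"null"`, `"ictal"`, `"postictal"`.
#' @param thalamic_cbf_multiplier Bilateral multiplier on thalamic CBF.
#'   Defaults: 1 (null), 1.3 (ictal), 0.85 (postictal).
#' @param focus_region Cortical parcel name carrying a lateralized focus, or
#'   `NULL`. Defaults to a temporal parcel for ictal/postictal scenarios.
#' @param focus_side `"left"` or `"right"`.
#' @param focus_cbf_multiplier CBF multiplier applied to the focus parcel on
#'   `focus_side` only. Defaults: 1.5 (ictal), 0.7 (postictal), 1 (null).
#' @param baseline_cbf_gm Grey-matter baseline CBF, mL/100g/min.
#' @param baseline_cbv_gm Grey-matter baseline CBV, mL/100g.
#' @param baseline_mtt Grey-matter baseline MTT, s. Must satisfy
#'   `mtt = cbv/cbf * 60`; if inconsistent it is recomputed from CBF and CBV.
#' @param noise_sigma Noise level as a fraction of the baseline signal.
#' @param rater_error_rate Probability that a simulated rater corrupts one
#'   rated item (flips it to a uniformly random other category).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("null", "ictal", "postictal"),
                          thalamic_cbf_multiplier = NULL,
                          focus_region = NULL,
                          focus_side = c("left", "right"),
                          focus_cbf_multiplier = NULL,
                          baseline_cbf_gm = 60,
                          baseline_cbv_gm = 4,
                          baseline_mtt = 4,
                          noise_sigma = 0.05,
                          rater_error_rate = 0.1) {
  scenario <- match.arg(scenario)
  focus_side <- match.arg(focus_side)
  if (is.null(thalamic_cbf_multiplier))
    thalamic_cbf_multiplier <- switch(scenario, null = 1, ictal = 1.3, postictal = 0.85)
  if (is.null(focus_cbf_multiplier))
    focus_cbf_multiplier <- switch(scenario, null = 1, ictal = 1.5, postictal = 0.7)
  if (is.null(focus_region) && scenario != "null")
    focus_region <- "temporal_1"
  if (thalamic_cbf_multiplier <= 0 || focus_cbf_multiplier <= 0)
    stop("multipliers must be > 0")
  if (scenario == "ictal" && thalamic_cbf_multiplier <= 1)
    warning("ictal scenario usually implies thalamic_cbf_multiplier > 1")
  if (scenario == "postictal" && thalamic_cbf_multiplier >= 1)
    warning("postictal scenario usually implies thalamic_cbf_multiplier < 1")
  if (rater_error_rate < 0 || rater_error_rate >= 1)
    stop("rater_error_rate must be in [0, 1)")
  if (baseline_cbf_gm <= 0 || baseline_cbv_gm <= 0)
    stop("baselines must be positive")
  mtt_cv <- baseline_cbv_gm / baseline_cbf_gm * 60
  if (abs(baseline_mtt - mtt_cv) > 1e-8 * mtt_cv) {
    message("baseline_mtt recomputed as cbv/cbf * 60 = ", signif(mtt_cv, 4),
            " s to preserve central-volume consistency")
    baseline_mtt <- mtt_cv
  }
  structure(list(scenario = scenario,
                 thalamic_cbf_multiplier = thalamic_cbf_multiplier,
                 focus_region = focus_region,
                 focus_side = focus_side,
                 focus_cbf_multiplier = focus_cbf_multiplier,
                 baseline_cbf_gm = baseline_cbf_gm,
                 baseline_cbv_gm = baseline_cbv_gm,
                 baseline_mtt = baseline_mtt,
                 noise_sigma = noise_sigma,
                 rater_error_rate = rater_error_rate),
            class = "scenario_spec")
}

# lobes receiving cortical parcels and their share of the 2*pi azimuth;
# proportions loosely follow relative lobe sizes
.cortical_lobes <- c(frontal = 10, parietal = 6, temporal = 8,
                     occipital = 6, insula = 2)

.rated_regions <- c("frontal", "parietal", "temporal", "occipital",
                    "insula", "thalamus")

# Smooth random field over world coordinates: a seeded sum of cosine modes
# (wavelengths >= ~25 mm), even in x so the field is mirror-symmetric about
# the sagittal midplane. Being an analytic function of anatomical
# coordinates it moves rigidly with the head when a pose is applied, and it
# gives anatomy and perfusion the shared spatial detail real brains have.
.smooth_field <- function(X, Y, Z, seed, n_modes = 40L, amp_sd = 1) {
  set.seed(seed)
  kmax <- 2 * pi / 25
  kx <- stats::runif(n_modes, 0, kmax)
  ky <- stats::runif(n_modes, 0, kmax)
  kz <- stats::runif(n_modes, 0, kmax)
  phy <- stats::runif(n_modes, 0, 2 * pi)
  phz <- stats::runif(n_modes, 0, 2 * pi)
  cf <- stats::rnorm(n_modes)
  Xa <- abs(X)                      # even in x: exact mirror symmetry
  S <- array(0, dim = dim(X))
  for (j in seq_len(n_modes))
    S <- S + cf[j] * cos(kx[j] * Xa) * cos(ky[j] * Y + phy[j]) *
      cos(kz[j] * Z + phz[j])
  S <- (S - mean(S)) / stats::sd(S)
  pmin(pmax(S, -2.5), 2.5) * amp_sd
}

# allocate n parcels to lobes proportionally to .cortical_lobes
.parcel_lobes <- function(n) {
  w <- .cortical_lobes / sum(.cortical_lobes)
  counts <- floor(w * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(w * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(.cortical_lobes), counts)
}

#' Build a parcellated head phantom
#'
#' Constructs concentric ellipsoids (white-matter core inside a cortical
#' grey-matter shell), splits the shell into equal-angle azimuthal sectors
#' per hemisphere, places subcortical nuclei near the midline (thalami
#' always), and adds a small midline arterial segment. The geometry is
#' mirror-symmetric about the sagittal midplane, so left/right parcels are
#' exact name-matched pairs.
#'
#' @param spec A [phantom_spec()].
#' @param pose Optional `rigid_transform` giving the head's pose in world
#'   space: the geometry is evaluated analytically on the displaced grid
#'   (no resampling), emulating a subject whose head sits rotated/shifted
#'   in the scanner while the image header is unchanged.
#' @return A list of class `label_phantom` with elements `anatomy` (3D array,
#'   T1-like intensities), `labels` (a `label_map`: 3D integer array `labels`,
#'   lookup table `lut` with columns id/name/hemisphere/lobe, and `affine`),
#'   and `artery` (logical mask of arterial voxels).
#' @export
make_label_phantom <- function(spec, pose = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  ctr <- (dm - 1) / 2
  # RAS-style affine, world origin at grid centre
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- -ctr * vs
  ix <- (seq_len(dm[1]) - 1 - ctr[1]) * vs[1]
  iy <- (seq_len(dm[2]) - 1 - ctr[2]) * vs[2]
  iz <- (seq_len(dm[3]) - 1 - ctr[3]) * vs[3]
  X <- array(rep(ix, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(iy, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(iz, each = dm[1] * dm[2]), dim = dm)
  if (!is.null(pose)) {
    stopifnot(inherits(pose, "rigid_transform"))
    w <- transform_points(invert_transform(pose),
                          cbind(as.vector(X), as.vector(Y), as.vector(Z)))
    X <- array(w[, 1], dim = dm)
    Y <- array(w[, 2], dim = dm)
    Z <- array(w[, 3], dim = dm)
  }
  fov <- dm * vs
  outer_ax <- 0.42 * fov
  inner_ax <- 0.28 * fov
  r_out <- (X / outer_ax[1])^2 + (Y / outer_ax[2])^2 + (Z / outer_ax[3])^2
  r_in <- (X / inner_ax[1])^2 + (Y / inner_ax[2])^2 + (Z / inner_ax[3])^2
  head <- r_out <= 1
  core <- r_in <= 1
  shell <- head & !core

  n <- spec$n_cortical_parcels
  phi <- atan2(Z, Y)                      # azimuth about the L-R axis
  # Angular sector boundaries at empirical azimuth quantiles of the shell:
  # contiguous wedges of near-equal width whose voxel counts match the
  # prescribed 1/n fractions closely despite grid voxelization (uniformly
  # spaced boundaries leave systematic 15-20% count imbalances). Grid
  # diagonals put hundreds of voxels at exactly the same azimuth, so ties
  # are broken by a tiny deterministic, mirror-symmetric offset (a function
  # of |x| and radius only, keeping left/right pairs in the same sector).
  phi_key <- phi + 1e-9 * (abs(X) + sqrt(2) * 1e-3 * (Y^2 + Z^2))
  qs <- stats::quantile(phi_key[shell], probs = seq_len(n - 1) / n,
                        names = FALSE, type = 1)
  sector <- findInterval(phi_key, qs, left.open = TRUE) + 1L
  left <- X < 0

  labels <- array(0L, dim = dm)
  lobes <- .parcel_lobes(n)
  # per-lobe running index for names like frontal_1, frontal_2, ...
  within <- stats::ave(seq_along(lobes), lobes, FUN = seq_along)
  pnames <- paste0(lobes, "_", within)
  labels[shell & left] <- 1000L + sector[shell & left]
  labels[shell & !left] <- 2000L + sector[shell & !left]

  lut <- data.frame(
    id = c(1000L + seq_len(n), 2000L + seq_len(n)),
    name = c(pnames, pnames),
    hemisphere = rep(c("left", "right"), each = n),
    lobe = c(lobes, lobes),
    stringsAsFactors = FALSE)

  # subcortical blobs: mirrored ellipsoids near the midline, inside the core
  sub <- spec$subcortical
  for (m in seq_along(sub)) {
    cx <- 12 + 14 * (m - 1)                       # |x| offset, mm
    cy <- -6 * (m - 1)
    ax <- c(9, 12, 9)
    for (side in c("left", "right")) {
      sx <- if (side == "left") -cx else cx
      blob <- ((X - sx) / ax[1])^2 + ((Y - cy) / ax[2])^2 + (Z / ax[3])^2 <= 1
      blob <- blob & core
      if (!any(blob))
        stop("grid too small to host subcortical structure '", sub[m], "'")
      id <- (if (side == "left") 100L else 200L) + m
      labels[blob] <- id
      lut <- rbind(lut, data.frame(id = id, name = sub[m], hemisphere = side,
                                   lobe = "subcortical", stringsAsFactors = FALSE))
    }
  }

  # remaining core voxels are white matter, labelled per hemisphere
  wm <- core & labels == 0L
  labels[wm & left] <- 191L
  labels[wm & !left] <- 192L
  lut <- rbind(lut,
               data.frame(id = c(191L, 192L), name = "cerebral_white_matter",
                          hemisphere = c("left", "right"), lobe = "subcortical",
                          stringsAsFactors = FALSE))

  # midline arterial segment (inferior, within the head): feeds select_aif
  artery <- (X / 6)^2 + (Y / 6)^2 <= 1 & Z >= -0.30 * fov[3] & Z <= -0.12 * fov[3] & head
  labels[artery] <- 900L
  lut <- rbind(lut, data.frame(id = 900L, name = "basilar_artery",
                               hemisphere = "none", lobe = "subcortical",
                               stringsAsFactors = FALSE))

  field <- .smooth_field(X, Y, Z, seed = spec$seed + 1L)
  anat <- array(0, dim = dm)
  anat[labels >= 1000L] <- 80          # cortical GM
  anat[labels %in% c(191L, 192L)] <- 110
  anat[labels >= 100L & labels < 300L & !(labels %in% c(191L, 192L))] <- 90
  anat[artery] <- 60
  anat[head] <- anat[head] + 8 * field[head]
  set.seed(spec$seed)
  anat[head] <- anat[head] + stats::rnorm(sum(head), 0, 0.5)

  labmap <- structure(list(labels = labels, lut = lut, affine = affine,
                           field = field),
                      class = "label_map")
  structure(list(anatomy = anat, labels = labmap, artery = artery,
                 affine = affine, spec = spec),
            class = "label_phantom")
}

#' Ground-truth perfusion maps for a scenario
#'
#' Assigns tissue-class baseline CBF/CBV, applies the scenario's bilateral
#' thalamic multiplier and the lateralized focus multiplier to CBF (CBV is
#' left unchanged), and recomputes MTT as `cbv/cbf * 60` so the
#' central-volume identity holds everywhere.
#'
#' @param labels A `label_map` (or a `label_phantom`, whose labels are used).
#' @param scenario A [scenario_spec()].
#' @return A list of class `truth_maps` with 3D arrays `cbf`
#'   (mL/100g/min), `cbv` (mL/100g) and `mtt` (s).
#' @export
make_perfusion_truth <- function(labels, scenario) {
  if (inherits(labels, "label_phantom")) labels <- labels$labels
  stopifnot(inherits(labels, "label_map"), inherits(scenario, "scenario_spec"))
  lut <- labels$lut
  lab <- labels$labels
  cbf_gm <- scenario$baseline_cbf_gm
  cbv_gm <- scenario$baseline_cbv_gm

  cbf_by_id <- stats::setNames(numeric(nrow(lut)), lut$id)
  cbv_by_id <- cbf_by_id
  cortical <- lut$lobe %in% names(.cortical_lobes)
  # regional heterogeneity: smooth sinusoidal modulation over the azimuthal
  # parcel index, identical for name-matched left/right parcels (so all
  # asymmetry indices stay exactly zero) and centred to zero voxel-weighted
  # mean so the grey-matter reference mean stays at baseline_cbf_gm
  sector <- ifelse(cortical, (lut$id - 1L) %% 1000L, NA_integer_)
  n_par <- max(sector, na.rm = TRUE) + 1L
  mod <- ifelse(cortical, 0.12 * sin(2 * pi * (sector + 0.5) / n_par), 0)
  cnt <- tabulate(match(lab[lab > 0], lut$id), nbins = nrow(lut))
  if (any(cortical) && sum(cnt[cortical]) > 0)
    mod[cortical] <- mod[cortical] -
      sum(cnt[cortical] * mod[cortical]) / sum(cnt[cortical])
  cbf_by_id[cortical] <- cbf_gm * (1 + mod[cortical])
  cbv_by_id[cortical] <- cbv_gm * (1 + mod[cortical])
  is_wm <- lut$name == "cerebral_white_matter"
  cbf_by_id[is_wm] <- cbf_gm * 25 / 60
  cbv_by_id[is_wm] <- cbv_gm / 2
  is_thal <- lut$name == "thalamus"
  other_sub <- lut$lobe == "subcortical" & !is_wm & !is_thal & lut$hemisphere != "none"
  cbf_by_id[other_sub] <- cbf_gm
  cbv_by_id[other_sub] <- cbv_gm
  is_art <- lut$hemisphere == "none"
  cbf_by_id[is_art] <- cbf_gm * 2
  cbv_by_id[is_art] <- cbv_gm * 2

  if (!is.null(scenario$focus_region)) {
    hit <- lut$name == scenario$focus_region & lut$hemisphere == scenario$focus_side
    if (!any(hit))
      stop("focus_region '", scenario$focus_region, "' (", scenario$focus_side,
           ") not found in the lookup table")
    cbf_by_id[hit] <- cbf_by_id[hit] * scenario$focus_cbf_multiplier
  }

  idx <- match(lab, lut$id)
  cbf <- array(0, dim = dim(lab))
  cbv <- array(0, dim = dim(lab))
  nz <- !is.na(idx)
  cbf[nz] <- cbf_by_id[idx[nz]]
  cbv[nz] <- cbv_by_id[idx[nz]]
  # voxel-scale perfusion heterogeneity shared with the anatomical image
  # (same smooth field): multiplicative on CBF and CBV jointly so MTT is
  # untouched; quantized so the bolus simulation convolves few classes
  if (!is.null(labels$field)) {
    m <- 1 + round(0.15 * labels$field, 2)
    tissue <- nz & !(lab %in% lut$id[lut$hemisphere == "none"])
    cbf[tissue] <- cbf[tissue] * m[tissue]
    cbv[tissue] <- cbv[tissue] * m[tissue]
  }
  # thalamic baseline pinned to the voxel-weighted cortical grey-matter
  # mean (its nuclei are perfused like cortex on average), so that in a
  # null scenario the thalamic z-score is zero by construction
  cort_vox <- nz & (lut$lobe[idx] %in% names(.cortical_lobes))
  thal_vox <- nz & (lut$name[idx] == "thalamus")
  if (any(cort_vox) && any(thal_vox)) {
    cbf[thal_vox] <- mean(cbf[cort_vox]) * scenario$thalamic_cbf_multiplier
    cbv[thal_vox] <- mean(cbv[cort_vox])
  }
  mtt <- array(0, dim = dim(lab))
  pos <- cbf > 0
  mtt[pos] <- cbv[pos] / cbf[pos] * 60
  structure(list(cbf = cbf, cbv = cbv, mtt = mtt), class = "truth_maps")
}

# flow in 1/s from CBF in mL/100g/min
.k_unit <- 6000

#' Simulate a DSC-MRI bolus passage
#'
#' Discrete-time tracer-kinetic forward model at the repetition time: per
#' voxel, `C_t[i] = F * TR * sum_j Ca[j] * R[i-j]` with residue
#' `R(t) = exp(-t/MTT)` and `F = cbf/6000` (1/s). Signal is
#' `S(t) = S0 * exp(-TE * kappa * C_t(t))` plus optional Gaussian noise.
#' Voxels in `arterial_mask` carry the arterial curve itself.
#'
#' @param truth A `truth_maps` object.
#' @param aif An [aif_model()] providing the arterial concentration curve.
#' @param tr Repetition time, s.
#' @param te Echo time, s.
#' @param n_timepoints Number of dynamics (default 80).
#' @param noise_sigma Gaussian noise SD as a fraction of baseline signal.
#' @param seed Integer seed for the noise.
#' @param arterial_mask Optional logical array of arterial voxels.
#' @param s0 Baseline signal level (arbitrary units).
#' @param kappa Susceptibility calibration constant (a.u.).
#' @param baseline_n Number of pre-bolus baseline timepoints (default 8).
#' @return A list of class `dsc_series`: `signal` (4D array), `tr`, `te`,
#'   `time`, `baseline_window`.
#' @export
simulate_dsc <- function(truth, aif = aif_model(), tr = 1, te = 0.03,
                         n_timepoints = 80L, noise_sigma = 0, seed = 1L,
                         arterial_mask = NULL, s0 = 100, kappa = 1,
                         baseline_n = 8L) {
  stopifnot(inherits(truth, "truth_maps"))
  if (tr <= 0 || te <= 0) stop("TR and TE must be positive")
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (any(truth$cbf < 0) || any(truth$cbv < 0)) stop("truth maps must be nonnegative")
  dm <- dim(truth$cbf)
  tt <- (seq_len(n_timepoints) - 1) * tr
  ca <- gamma_variate(tt, aif)

  # voxels fall into few (cbf, mtt) classes; convolve once per class
  key <- paste(truth$cbf, truth$mtt)
  brain <- truth$cbf > 0
  classes <- unique(key[brain])
  ct <- array(0, dim = c(dm, n_timepoints))
  nvox <- prod(dm)
  for (k in classes) {
    sel <- which(key == k & brain)
    v <- sel[1]
    f <- truth$cbf[v] / .k_unit
    mtt <- truth$mtt[v]
    if (mtt <= 0) next                    # cbv = 0: no tracer retention, C_t = 0
    r <- exp(-tt / mtt)
    ctk <- f * tr * as.vector(stats::convolve(ca, rev(r), type = "open"))[seq_len(n_timepoints)]
    for (i in seq_len(n_timepoints)) ct[sel + (i - 1) * nvox] <- ctk[i]
  }
  if (!is.null(arterial_mask)) {
    sel <- which(arterial_mask)
    for (i in seq_len(n_timepoints)) ct[sel + (i - 1) * nvox] <- ca[i]
    brain <- brain | arterial_mask
  }
  signal <- s0 * exp(-te * kappa * ct)
  signal[array(!brain, dim = c(dm, n_timepoints))] <- 0
  if (noise_sigma > 0) {
    set.seed(seed)
    nse <- stats::rnorm(sum(brain) * n_timepoints, 0, noise_sigma * s0)
    bsel <- which(array(brain, dim = c(dm, n_timepoints)))
    signal[bsel] <- signal[bsel] + nse
  }
  structure(list(signal = signal, tr = tr, te = te, time = tt,
                 baseline_window = seq_len(baseline_n)),
            class = "dsc_series")
}

#' Simulate an ictal/postictal cohort
#'
#' Generates a reproducible cohort bundle: one shared label phantom,
#' per-scenario ground truth, per-subject ROI-level perfusion tables
#' (ground-truth ROI means under a global lognormal subject scale and
#' multiplicative measurement noise), simulated visual ratings from two
#' independent raters plus a consensus (the ground-truth category), and —
#' optionally — full per-subject DSC series.
#'
#' The ROI-level sampling path makes repeated-cohort power and type-I-error
#' studies tractable; the voxelwise DSC path (`include_dsc = TRUE`) feeds the
#' full image pipeline.
#'
#' @param n_ictal,n_postictal Cohort sizes (defaults 10 and 17).
#' @param phantom A [phantom_spec()].
#' @param ictal,postictal [scenario_spec()] objects for the two cohorts.
#' @param subject_cv Between-subject coefficient of variation of the global
#'   perfusion scale (lognormal; default 0.2).
#' @param seed Integer seed; the bundle is a pure function of it.
#' @param include_dsc If `TRUE`, also simulate a DSC series per subject.
#' @param aif [aif_model()] used when `include_dsc = TRUE`.
#' @param template A [cohort_template()] reusing the deterministic phantom /
#'   ground-truth part across many seeds (for power or type-I-error
#'   studies); when given, `phantom`, `ictal` and `postictal` are ignored.
#' @return A list of class `tpma_cohort`: `phantom`, `truth` (per scenario),
#'   `subjects` (long ROI table: subject_id, cohort, id, name, hemisphere,
#'   lobe, n_voxels, mean, sd), `ratings` (subject- and region-level rows for
#'   raters r1, r2 and consensus), `dsc` (list or NULL), `seed`.
#' @export
simulate_cohort <- function(n_ictal = 10L, n_postictal = 17L,
                            phantom = phantom_spec(),
                            ictal = scenario_spec("ictal"),
                            postictal = scenario_spec("postictal"),
                            subject_cv = 0.2, seed = 1L,
                            include_dsc = FALSE, aif = aif_model(),
                            template = NULL) {
  n_ictal <- as.integer(n_ictal); n_postictal <- as.integer(n_postictal)
  if (n_ictal < 0L || n_postictal < 0L) stop("cohort sizes must be >= 0")
  if (is.null(template)) template <- cohort_template(phantom, ictal, postictal)
  ph <- template$phantom
  truth <- template$truth
  base <- template$base
  scen <- template$scenarios

  set.seed(seed)
  subjects <- NULL
  ratings <- NULL
  dsc <- if (include_dsc) list() else NULL
  cohorts <- c(rep("ictal", n_ictal), rep("postictal", n_postictal))
  if (length(cohorts)) {
    sdlog <- sqrt(log(1 + subject_cv^2))
    for (s in seq_along(cohorts)) {
      ch <- cohorts[s]
      sid <- sprintf("sub-%02d", s)
      tab <- base[[ch]]
      g <- exp(stats::rnorm(1, 0, sdlog))
      eps <- stats::rnorm(nrow(tab), 0, scen[[ch]]$noise_sigma)
      m <- tab$mean * g * (1 + eps)
      sub <- data.frame(subject_id = sid, cohort = ch, tab[, c("id", "name", "hemisphere", "lobe")],
                        n_voxels = tab$n_voxels, mean = m,
                        sd = scen[[ch]]$noise_sigma * abs(m),
                        stringsAsFactors = FALSE)
      subjects <- rbind(subjects, sub)
      ratings <- rbind(ratings, .simulate_ratings(sid, scen[[ch]]))
      if (include_dsc) {
        tr_s <- truth[[ch]]
        tr_s$cbf <- tr_s$cbf * g
        tr_s$cbv <- tr_s$cbv * g
        dsc[[sid]] <- simulate_dsc(tr_s, aif = aif,
                                   noise_sigma = scen[[ch]]$noise_sigma,
                                   seed = sample.int(.Machine$integer.max, 1),
                                   arterial_mask = ph$artery)
      }
    }
  }
  structure(list(phantom = ph, truth = truth, subjects = subjects,
                 ratings = ratings, dsc = dsc, scenarios = scen, seed = seed),
            class = "tpma_cohort")
}

#' Precompute the deterministic part of a cohort simulation
#'
#' Builds the label phantom, the per-scenario ground-truth maps and their
#' ROI statistics once, so that [simulate_cohort()] can be called with many
#' seeds without re-deriving them (repeated-cohort power studies).
#'
#' @param phantom A [phantom_spec()].
#' @param ictal,postictal [scenario_spec()] objects.
#' @return A list of class `cohort_template`.
#' @export
cohort_template <- function(phantom = phantom_spec(),
                            ictal = scenario_spec("ictal"),
                            postictal = scenario_spec("postictal")) {
  ph <- make_label_phantom(phantom)
  truth <- list(ictal = make_perfusion_truth(ph, ictal),
                postictal = make_perfusion_truth(ph, postictal))
  base <- list(ictal = roi_statistics(truth$ictal$cbf, ph$labels)$stats,
               postictal = roi_statistics(truth$postictal$cbf, ph$labels)$stats)
  structure(list(phantom = ph, truth = truth, base = base,
                 scenarios = list(ictal = ictal, postictal = postictal)),
            class = "cohort_template")
}

.subject_categories <- c("normal", "hypoperfusion", "hyperperfusion")
.region_categories <- c("normal", "left-hyper", "right-hyper", "left-hypo", "right-hypo")

# ground-truth visual categories implied by a scenario
.truth_ratings <- function(scenario) {
  subj <- switch(scenario$scenario, null = "normal",
                 ictal = "hyperperfusion", postictal = "hypoperfusion")
  reg <- stats::setNames(rep("normal", length(.rated_regions)), .rated_regions)
  if (!is.null(scenario$focus_region) && scenario$focus_cbf_multiplier != 1) {
    lobe <- sub("_[0-9]+$", "", scenario$focus_region)
    if (lobe %in% .rated_regions) {
      dir <- if (scenario$focus_cbf_multiplier > 1) "hyper" else "hypo"
      reg[lobe] <- paste0(scenario$focus_side, "-", dir)
    }
  }
  list(subject = subj, region = reg)
}

.corrupt <- function(category, vocab, error_rate) {
  flip <- stats::runif(length(category)) < error_rate
  if (any(flip))
    category[flip] <- vapply(category[flip], function(cc)
      sample(setdiff(vocab, cc), 1), character(1))
  category
}

.simulate_ratings <- function(subject_id, scenario) {
  tr <- .truth_ratings(scenario)
  out <- NULL
  for (rater in c("r1", "r2", "consensus")) {
    er <- if (rater == "consensus") 0 else scenario$rater_error_rate
    subj_cat <- .corrupt(tr$subject, .subject_categories, er)
    reg_cat <- .corrupt(tr$region, .region_categories, er)
    out <- rbind(out,
                 data.frame(subject_id = subject_id, rater = rater,
                            level = "subject", region = "global",
                            category = subj_cat, stringsAsFactors = FALSE),
                 data.frame(subject_id = subject_id, rater = rater,
                            level = "region", region = .rated_regions,
                            category = unname(reg_cat), stringsAsFactors = FALSE))
  }
  out
}
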