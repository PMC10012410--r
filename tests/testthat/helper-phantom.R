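# Shared fixtures, built lazily and memoized for the whole run.

.fixture_env <- new.env(parent = emptyenv())

# small phantom spec for geometry-light tests
small_spec <- function(n = 24L, parcels = 8L, seed = 1L)
  phantom_spec(grid_shape = rep(n, 3L), voxel_size = c(4, 4, 4),
               n_cortical_parcels = parcels, seed = seed)

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default-size phantom shared across files
default_phantom <- function()
  memo("default_phantom", make_label_phantom(phantom_spec()))

# noiseless null-scenario truth + DSC series + maps on the default phantom
null_bundle <- function() {
  memo("null_bundle", {
    ph <- default_phantom()
    scen <- scenario_spec("null", noise_sigma = 0, rater_error_rate = 0)
    truth <- make_perfusion_truth(ph, scen)
    series <- simulate_dsc(truth, noise_sigma = 0, arterial_mask = ph$artery)
    brain <- truth$cbf > 0 | ph$artery
    maps <- compute_maps(series, brain, aif = aif_model(),
                         threshold_fraction = 0.002)
    list(phantom = ph, scen = scen, truth = truth, series = series,
         brain = brain, maps = maps)
  })
}

# deterministic cohort template at default study conditions
default_template <- function()
  memo("default_template", cohort_template())

# null-vs-null template (no injected effect anywhere)
null_template <- function()
  memo("null_template", {
    nul <- scenario_spec("null", noise_sigma = 0.05)
    cohort_template(phantom_spec(), ictal = nul, postictal = nul)
  })

# pooled (volume-weighted) thalamic mean per subject from a cohort bundle
thalamic_means <- function(cohort) {
  tt <- cohort$subjects[cohort$subjects$name == "thalamus", ]
  agg <- stats::aggregate(cbind(w = n_voxels * mean, n = n_voxels) ~ subject_id + cohort,
                          data = tt, FUN = sum)
  agg$value <- agg$w / agg$n
  agg
}

# per-subject z-table (thalamus rows) from a cohort bundle's light-path stats
cohort_z_table <- function(cohort) {
  out <- NULL
  for (sid in unique(cohort$subjects$subject_id)) {
    ss <- cohort$subjects[cohort$subjects$subject_id == sid, ]
    cort <- ss$lobe %in% c("frontal", "parietal", "temporal", "occipital", "insula")
    n <- sum(ss$n_voxels[cort])
    mu <- sum(ss$n_voxels[cort] * ss$mean[cort]) / n
    ss2 <- sum(ss$n_voxels[cort] * ((ss$n_voxels[cort] - 1) / ss$n_voxels[cort] *
                 ss$sd[cort]^2 + ss$mean[cort]^2))
    sd <- sqrt(max(ss2 / n - mu^2, 0) * n / (n - 1))
    gm <- list(mean = mu, sd = max(sd, 1e-12), n_voxels = n)
    zz <- intra_subject_zscores(ss, gm)
    out <- rbind(out, zz)
  }
  out
}
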