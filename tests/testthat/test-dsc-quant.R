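test_that("gamma-variate model matches its closed form", {
  a <- aif_model(amplitude = 2, shape = 3, scale = 1.5, t0 = 10)
  expect_equal(gamma_variate(10, a), 0)            # t = t0
  expect_equal(gamma_variate(c(0, 5), a), c(0, 0)) # before arrival
  # maximum at t0 + alpha*beta (calculus)
  tt <- seq(10, 40, by = 0.001)
  expect_equal(tt[which.max(gamma_variate(tt, a))], 10 + 3 * 1.5,
               tolerance = 1e-3)
  # quadrature oracle: integral = A * beta^(alpha+1) * Gamma(alpha+1)
  num <- stats::integrate(function(t) gamma_variate(t, a), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(num, 2 * 1.5^4 * gamma(4), tolerance = 1e-3 * 0.001)
  expect_error(aif_model(amplitude = -1), "invalid")
  expect_error(gamma_variate(-1, a), ">= 0")
})

test_that("signal-concentration conversion is exact and self-inverse", {
  # direct substitution: S = S0 * exp(-0.06), TE 0.03, kappa 1 -> C = 2
  sig <- array(100, dim = c(1, 1, 1, 12))
  sig[1, 1, 1, 9:12] <- 100 * exp(-0.06)
  ser <- structure(list(signal = sig, tr = 1, te = 0.03, time = 0:11,
                        baseline_window = 1:8), class = "dsc_series")
  cs <- signal_to_concentration(ser)
  expect_equal(cs$conc[1, 1, 1, 1], 0)
  expect_equal(cs$conc[1, 1, 1, 10], 2)
  # roundtrip with the phantom forward model, noise 0
  nb <- null_bundle()
  cs2 <- signal_to_concentration(nb$series)
  v <- which(nb$truth$cbf > 0 & !nb$phantom$artery)[123]
  idx <- arrayInd(v, dim(nb$truth$cbf))
  f <- nb$truth$cbf[v] / 6000
  r <- exp(-nb$series$time / nb$truth$mtt[v])
  ca <- gamma_variate(nb$series$time, aif_model())
  ct <- f * 1 * as.vector(stats::convolve(ca, rev(r), type = "open"))[1:80]
  expect_equal(as.vector(cs2$conc[idx[1], idx[2], idx[3], ]), ct,
               tolerance = 1e-9)
  # clamped voxels are flagged
  sig2 <- sig
  sig2[1, 1, 1, 10] <- 0.001
  ser2 <- structure(list(signal = sig2, tr = 1, te = 0.03, time = 0:11,
                         baseline_window = 1:8), class = "dsc_series")
  expect_true(signal_to_concentration(ser2)$flagged[1, 1, 1])
})

test_that("automated AIF selection finds the planted artery", {
  nb <- null_bundle()
  sel <- select_aif(nb$series, nb$brain)
  expect_gte(mean(sel$candidates %in% which(nb$phantom$artery)), 0.9)
  # the fitted gamma-variate reproduces the simulated arterial curve
  expect_equal(gamma_variate(nb$series$time, sel$aif),
               gamma_variate(nb$series$time, aif_model()), tolerance = 0.02)
  # flat series: no candidates
  flat <- nb$series
  flat$signal[] <- ifelse(flat$signal > 0, 100, 0)
  expect_error(select_aif(flat, nb$brain), "no AIF candidates")
  # selection is invariant to scaling the contrast effect
  scen <- scenario_spec("null", noise_sigma = 0)
  tr2 <- make_perfusion_truth(nb$phantom, scen)
  tr2$cbf <- tr2$cbf * 1.7
  tr2$cbv <- tr2$cbv * 1.7
  ser2 <- simulate_dsc(tr2, aif = aif_model(amplitude = 17), noise_sigma = 0,
                       arterial_mask = nb$phantom$artery)
  sel2 <- select_aif(ser2, nb$brain)
  expect_setequal(sel$candidates, sel2$candidates)
  expect_error(select_aif(nb$series, array(FALSE, dim(nb$brain))), "50")
})

test_that("SVD deconvolution recovers flow, delay and degenerate cases", {
  dt <- 1; nt <- 80; tt <- (0:(nt - 1)) * dt
  narrow <- aif_model(amplitude = 45, shape = 1.5, scale = 0.8, t0 = 10)
  ca <- gamma_variate(tt, narrow)
  f <- 60 / 6000
  fwd <- function(r) f * dt * as.vector(stats::convolve(ca, rev(r),
                                                        type = "open"))[1:nt]
  # noiseless recovery at the default truncation threshold
  d <- svd_deconvolve(fwd(exp(-tt / 6)), ca, dt, threshold_fraction = 0.1)
  expect_lt(abs(d$cbf - f) / f, 0.05)
  # zero tissue curve
  z <- svd_deconvolve(rep(0, nt), ca, dt)
  expect_equal(z$cbf, 0)
  expect_equal(z$residue, rep(0, 2 * nt))
  expect_error(svd_deconvolve(fwd(exp(-tt / 6)), rep(0, nt), dt), "zero")
  expect_error(svd_deconvolve(1:5, 1:5, 1), "10")
  # shift oracle: delaying ct by d shifts tmax by d within one sample
  base <- svd_deconvolve(fwd(exp(-tt / 6)), ca, dt, 0.002)
  for (del in c(2, 4, 6)) {
    rd <- exp(-pmax(tt - del, 0) / 6) * (tt >= del)
    dd <- svd_deconvolve(fwd(rd), ca, dt, 0.002)
    expect_lte(abs((dd$tmax - base$tmax) - del), dt)
  }
})

test_that("compute_maps produces exactly the six maps with consistent units", {
  nb <- null_bundle()
  expect_named(nb$maps, c("rcbf", "rcbv", "mtt", "ttp", "tmip", "tmax",
                          "mask", "aif_curve"))
  sel <- which(!is.na(nb$maps$rcbf) & nb$maps$rcbf > 0)
  # central-volume identity holds by construction
  expect_equal(nb$maps$mtt[sel],
               60 * nb$maps$rcbv[sel] / nb$maps$rcbf[sel])
  # ttp and tmax lie within the acquisition span
  expect_true(all(nb$maps$ttp[sel] >= 0 & nb$maps$ttp[sel] <= max(nb$series$time)))
  # voxel with C_t = C_a has rcbv = 1: arterial voxels carry the AIF itself
  art <- which(nb$phantom$artery & !is.na(nb$maps$rcbv))
  expect_equal(unname(nb$maps$rcbv[art]), rep(1, length(art)), tolerance = 1e-6)
})

test_that("focus-ratio and rank order survive quantification", {
  nb <- null_bundle()
  foc <- scenario_spec("ictal", focus_region = "temporal_1",
                       focus_side = "left", focus_cbf_multiplier = 1.5,
                       noise_sigma = 0)
  trf <- make_perfusion_truth(nb$phantom, foc)
  serf <- simulate_dsc(trf, noise_sigma = 0, arterial_mask = nb$phantom$artery)
  mpf <- compute_maps(serf, nb$brain, aif = aif_model(),
                      threshold_fraction = 0.002)
  rs <- roi_statistics(mpf$rcbf, nb$phantom$labels)
  st <- rs$stats
  lh <- st$mean[st$name == "temporal_1" & st$hemisphere == "left"]
  rh <- st$mean[st$name == "temporal_1" & st$hemisphere == "right"]
  expect_lt(abs(lh / rh - 1.5), 0.05 * 1.5)
  # monotone CBF ranking: recovered vs truth rank order (excluding artery)
  sel <- which(trf$cbf > 0 & !nb$phantom$artery & !is.na(mpf$rcbf))
  expect_gt(stats::cor(mpf$rcbf[sel], trf$cbf[sel], method = "spearman"), 0.99)
})

test_that("maps obey scale equivariance in the contrast dose", {
  nb <- null_bundle()
  c_scale <- 1.6
  tr2 <- nb$truth
  tr2$cbf <- tr2$cbf * c_scale
  tr2$cbv <- tr2$cbv * c_scale
  ser2 <- simulate_dsc(tr2, noise_sigma = 0, arterial_mask = nb$phantom$artery)
  mp2 <- compute_maps(ser2, nb$brain, aif = aif_model(),
                      threshold_fraction = 0.002)
  sel <- which(nb$truth$cbf > 0 & !nb$phantom$artery & !is.na(nb$maps$rcbf))
  expect_equal(mp2$rcbf[sel], nb$maps$rcbf[sel] * c_scale, tolerance = 1e-6)
  expect_equal(mp2$rcbv[sel], nb$maps$rcbv[sel] * c_scale, tolerance = 1e-6)
  expect_equal(mp2$tmip[sel], nb$maps$tmip[sel] * c_scale, tolerance = 1e-6)
  expect_equal(mp2$mtt[sel], nb$maps$mtt[sel], tolerance = 1e-6)
  expect_equal(mp2$ttp[sel], nb$maps$ttp[sel])
  expect_equal(mp2$tmax[sel], nb$maps$tmax[sel])
})
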