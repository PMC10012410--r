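# small random map + labels fixture with a brute-force accumulation oracle
random_roi_fixture <- function(seed = 5) {
  set.seed(seed)
  dm <- c(16, 16, 16)
  lut <- data.frame(id = c(1:6, 10L, 20L),
                    name = c("frontal_1", "frontal_2", "temporal_1",
                             "temporal_1", "frontal_1", "frontal_2",
                             "thalamus", "thalamus"),
                    hemisphere = c("left", "left", "left", "right", "right",
                                   "right", "left", "right"),
                    lobe = c("frontal", "frontal", "temporal", "temporal",
                             "frontal", "frontal", "subcortical",
                             "subcortical"),
                    stringsAsFactors = FALSE)
  labels <- array(sample(c(0L, lut$id), prod(dm), replace = TRUE), dim = dm)
  map <- array(stats::rnorm(prod(dm), 50, 10), dim = dm)
  list(map = map,
       labels = structure(list(labels = labels, lut = lut, affine = diag(4)),
                          class = "label_map"))
}

test_that("ROI statistics agree with brute-force voxel accumulation", {
  fx <- random_roi_fixture()
  rs <- roi_statistics(fx$map, fx$labels)
  for (i in seq_len(nrow(fx$labels$lut))) {
    id <- fx$labels$lut$id[i]
    vox <- fx$map[fx$labels$labels == id]
    expect_equal(rs$stats$n_voxels[i], length(vox))
    expect_equal(rs$stats$mean[i], mean(vox))
    expect_equal(rs$stats$sd[i], stats::sd(vox))
  }
  # grey-matter pool is the union of cortical parcels
  cort_ids <- fx$labels$lut$id[fx$labels$lut$lobe %in% c("frontal", "temporal")]
  gv <- fx$map[fx$labels$labels %in% cort_ids]
  expect_equal(rs$gm$mean, mean(gv))
  expect_equal(rs$gm$sd, stats::sd(gv))
  expect_equal(rs$gm$n_voxels,
               sum(rs$stats$n_voxels[rs$stats$lobe %in% c("frontal", "temporal")]))
})

test_that("constant maps and empty ROIs are handled per contract", {
  fx <- random_roi_fixture()
  fx$map[] <- 7
  rs <- roi_statistics(fx$map, fx$labels)
  expect_true(all(rs$stats$mean == 7))
  expect_true(all(rs$stats$sd == 0))
  # fully masked-out ROI flagged with n = 0
  mask <- fx$labels$labels != 10L
  rs2 <- roi_statistics(fx$map, fx$labels, mask = mask)
  row <- rs2$stats[rs2$stats$id == 10L, ]
  expect_equal(row$n_voxels, 0L)
  expect_true(row$flagged)
  expect_error(roi_statistics(fx$map[1:8, , ], fx$labels), "same grid")
})

test_that("z-scores follow the definition and are scale invariant", {
  # direct substitution: mu_roi 50, mu_GM 40, sigma_GM 5 -> z = 2
  st <- data.frame(id = 1, name = "frontal_1", hemisphere = "left",
                   lobe = "frontal", n_voxels = 10, mean = 50, sd = 1)
  z <- intra_subject_zscores(st, gm = list(mean = 40, sd = 5, n_voxels = 100))
  expect_equal(z$z, 2)
  # mu_roi = mu_GM -> 0
  st$mean <- 40
  expect_equal(intra_subject_zscores(st, gm = list(mean = 40, sd = 5))$z, 0)
  expect_error(intra_subject_zscores(st, gm = list(mean = 40, sd = 0)),
               "degenerate")
  # positive rescaling of the whole map leaves every z unchanged
  fx <- random_roi_fixture(8)
  rs <- roi_statistics(fx$map, fx$labels)
  z1 <- intra_subject_zscores(rs)
  for (c_scale in c(0.25, 3, 17)) {
    rs2 <- roi_statistics(fx$map * c_scale, fx$labels)
    z2 <- intra_subject_zscores(rs2)
    expect_equal(z2$z, z1$z, tolerance = 1e-12)
  }
})

test_that("asymmetry indices follow their algebraic identities", {
  st <- data.frame(name = c("a", "b", "a", "b"),
                   hemisphere = c("left", "left", "right", "right"),
                   lobe = "frontal", mean = c(3, 5, 1, 5),
                   stringsAsFactors = FALSE)
  ai <- asymmetry_indices(st)
  expect_equal(ai$ai[ai$name == "a"], 0.5)    # (3-1)/(3+1)
  expect_equal(ai$ai[ai$name == "b"], 0)      # lh = rh
  # antisymmetry under swapping hemispheres
  st2 <- st
  st2$hemisphere <- c("right", "right", "left", "left")
  expect_equal(asymmetry_indices(st2)$ai, -ai$ai)
  # degenerate pair flagged
  st3 <- st
  st3$mean <- c(0, 1, 0, 1)
  ai3 <- asymmetry_indices(st3)
  expect_true(is.na(ai3$ai[ai3$name == "a"]) && ai3$flagged[ai3$name == "a"])
  expect_error(asymmetry_indices(st[1:3, ]), "unpaired")
  # bounded in [-1, 1] for nonnegative inputs
  set.seed(2)
  stn <- data.frame(name = rep(sprintf("r%02d", 1:20), 2),
                    hemisphere = rep(c("left", "right"), each = 20),
                    lobe = "parietal", mean = stats::runif(40, 0, 100))
  expect_true(all(abs(asymmetry_indices(stn)$ai) <= 1))
})

test_that("lobar aggregation equals direct voxelwise pooling", {
  fx <- random_roi_fixture(11)
  rs <- roi_statistics(fx$map, fx$labels)
  lob <- lobar_aggregate(rs)
  for (lobe in c("frontal", "temporal")) {
    ids <- fx$labels$lut$id[fx$labels$lut$lobe == lobe]
    vox <- fx$map[fx$labels$labels %in% ids]
    expect_equal(lob$mean[lob$region == lobe], mean(vox))
    expect_equal(lob$sd[lob$region == lobe], stats::sd(vox))
  }
  # whole-cortex row equals the grey-matter summary (consistency identity)
  expect_equal(lob$mean[lob$region == "whole_cortex"], rs$gm$mean)
  expect_equal(lob$sd[lob$region == "whole_cortex"], rs$gm$sd)
  # thalamus reported alongside but not inside whole cortex
  expect_equal(lob$n_voxels[lob$region == "whole_cortex"], rs$gm$n_voxels)
  # aggregation is associative: parcels->lobes->cortex == parcels->cortex
  lb <- lob[lob$region %in% c("frontal", "temporal"), ]
  lb2 <- data.frame(id = seq_len(nrow(lb)), name = lb$region,
                    hemisphere = "left", lobe = lb$region,
                    n_voxels = lb$n_voxels, mean = lb$mean, sd = lb$sd)
  again <- lobar_aggregate(lb2)
  expect_equal(again$mean[again$region == "whole_cortex"],
               lob$mean[lob$region == "whole_cortex"])
  expect_equal(again$sd[again$region == "whole_cortex"],
               lob$sd[lob$region == "whole_cortex"])
  # singleton lobe mean equals the parcel mean
  single <- rs$stats[rs$stats$id == 3, ]
  expect_equal(lobar_aggregate(single)$mean[1], single$mean)
})

test_that("tidy ROI tables are written as advertised", {
  fx <- random_roi_fixture()
  rs <- roi_statistics(fx$map, fx$labels)
  z <- intra_subject_zscores(rs)
  ai <- asymmetry_indices(rs)
  dir <- withr::local_tempdir()
  files <- write_roi_tables(z, ai, dir, subject_id = "sub-77")
  tab <- utils::read.csv(files[1])
  expect_true(all(c("subject_id", "name", "hemisphere", "n_voxels", "mean",
                    "sd", "z") %in% names(tab)))
  pair <- utils::read.csv(files[2])
  expect_true(all(c("lh", "rh", "ai") %in% names(pair)))
})
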