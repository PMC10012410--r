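#' Rigid (6 DOF) world-space transform
#'
#' Rotation angles are applied in the order Rz %*% Ry %*% Rx about `center`
#' (world mm), followed by the translation. The homogeneous matrix maps
#' moving-image world coordinates into fixed-image world coordinates.
#'
#' @param angles Rotations about x, y, z in radians.
#' @param translation Offsets in mm.
#' @param center World-space rotation centre in mm.
#' @return An object of class `rigid_transform` with fields `angles`,
#'   `translation`, `center` and the 4x4 `matrix`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(translation) == 3, length(center) == 3)
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center + translation - R %*% center
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center), matrix = M),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- matrix(points, ncol = 3)
  t(transform$matrix[1:3, 1:3] %*% t(points) + transform$matrix[1:3, 4])
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform` (angles/offsets recovered from the
#'   inverted matrix, same rotation centre).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$matrix[1:3, 1:3]
  tvec <- transform$matrix[1:3, 4]
  Ri <- t(R)
  ti <- -Ri %*% tvec
  # recover ZYX Euler angles from Ri
  ay <- asin(pmin(pmax(-Ri[3, 1], -1), 1))
  ax <- atan2(Ri[3, 2], Ri[3, 3])
  az <- atan2(Ri[2, 1], Ri[1, 1])
  ctr <- transform$center
  # translation such that rigid_transform() reproduces the exact inverse:
  # M[,4] = c + t - Ri c  =>  t = ti + Ri c - c
  rigid_transform(c(ax, ay, az), as.numeric(ti + Ri %*% ctr - ctr), ctr)
}

#' Mutual information between two images
#'
#' MI in nats from the joint histogram of finite, overlapping voxels.
#'
#' @param image_a,image_b Numeric arrays on the same grid.
#' @param n_bins Histogram bins per axis (>= 4).
#' @param mask Optional logical array restricting the evaluation.
#' @return Mutual information (nats), >= 0.
#' @export
mutual_information <- function(image_a, image_b, n_bins = 32L, mask = NULL) {
  if (!all(dim(image_a) == dim(image_b))) stop("images must share a grid")
  if (n_bins < 4) stop("n_bins must be >= 4")
  a <- as.vector(image_a); b <- as.vector(image_b)
  keep <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  if (!any(keep)) stop("empty overlap between images")
  a <- a[keep]; b <- b[keep]
  ra <- range(a); rb <- range(b)
  bina <- if (diff(ra) == 0) rep(1L, length(a)) else
    pmin(pmax(findInterval(a, seq(ra[1], ra[2], length.out = n_bins + 1),
                           rightmost.closed = TRUE), 1L), n_bins)
  binb <- if (diff(rb) == 0) rep(1L, length(b)) else
    pmin(pmax(findInterval(b, seq(rb[1], rb[2], length.out = n_bins + 1),
                           rightmost.closed = TRUE), 1L), n_bins)
  joint <- tabulate(bina + n_bins * (binb - 1L), nbins = n_bins * n_bins)
  p <- joint / sum(joint)
  pj <- matrix(p, n_bins, n_bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

# trilinear interpolation of vol at fractional 1-based voxel coordinates
.trilinear <- function(vol, i, j, k) {
  dm <- dim(vol)
  out <- rep(NA_real_, length(i))
  ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]; k <- k[ok]
  i0 <- pmin(floor(i), dm[1] - 1); j0 <- pmin(floor(j), dm[2] - 1)
  k0 <- pmin(floor(k), dm[3] - 1)
  di <- i - i0; dj <- j - j0; dk <- k - k0
  at <- function(a, b, c) vol[cbind(a, b, c)]
  v <- at(i0, j0, k0) * (1 - di) * (1 - dj) * (1 - dk) +
    at(i0 + 1, j0, k0) * di * (1 - dj) * (1 - dk) +
    at(i0, j0 + 1, k0) * (1 - di) * dj * (1 - dk) +
    at(i0, j0, k0 + 1) * (1 - di) * (1 - dj) * dk +
    at(i0 + 1, j0 + 1, k0) * di * dj * (1 - dk) +
    at(i0 + 1, j0, k0 + 1) * di * (1 - dj) * dk +
    at(i0, j0 + 1, k0 + 1) * (1 - di) * dj * dk +
    at(i0 + 1, j0 + 1, k0 + 1) * di * dj * dk
  out[ok] <- v
  out
}

# Parzen-windowed (linear soft-binning) MI estimator on masked vectors.
# Hard binning makes the MI cost wiggle at sub-voxel offsets (interpolation
# artifacts); spreading each sample linearly over two adjacent bins per
# image yields a smooth cost surface for the optimizer. The exported
# mutual_information() keeps the classic hard-binned joint histogram.
.mi_parzen <- function(a, b, n_bins = 32L, ra = NULL, rb = NULL) {
  # robust intensity window: a handful of extreme voxels (vessels) would
  # otherwise compress the whole parenchyma into one or two bins; callers
  # evaluating many transforms pass frozen windows so the cost stays a
  # clean function of the transform
  if (is.null(ra)) ra <- stats::quantile(a, c(0.005, 0.995), names = FALSE)
  if (is.null(rb)) rb <- stats::quantile(b, c(0.005, 0.995), names = FALSE)
  a <- pmin(pmax(a, ra[1]), ra[2])
  b <- pmin(pmax(b, rb[1]), rb[2])
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ua <- 1 + (a - ra[1]) / (ra[2] - ra[1]) * (n_bins - 1)
  ub <- 1 + (b - rb[1]) / (rb[2] - rb[1]) * (n_bins - 1)
  ia <- pmin(floor(ua), n_bins - 1); ib <- pmin(floor(ub), n_bins - 1)
  wa <- ua - ia; wb <- ub - ib
  v <- numeric(n_bins * n_bins)
  for (cmb in list(list(ia, ib, (1 - wa) * (1 - wb)),
                   list(ia + 1, ib, wa * (1 - wb)),
                   list(ia, ib + 1, (1 - wa) * wb),
                   list(ia + 1, ib + 1, wa * wb))) {
    k <- cmb[[1]] + n_bins * (cmb[[2]] - 1)
    tmp <- rowsum(cmb[[3]], k)
    kk <- as.integer(rownames(tmp))
    v[kk] <- v[kk] + tmp[, 1]
  }
  p <- v / sum(v)
  pj <- matrix(p, n_bins, n_bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

# world coordinates (n x 3) of every voxel of a grid
.grid_world <- function(dm, affine) {
  g <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1, j = seq_len(dm[2]) - 1,
                             k = seq_len(dm[3]) - 1))
  t(affine[1:3, 1:3] %*% t(g) + affine[1:3, 4])
}

#' Resample a volume through a rigid transform
#'
#' Pull-back resampling onto a target grid: each target voxel is mapped to
#' world space, sent through the inverse of `transform` (which maps
#' moving-image world coordinates to target world coordinates) and
#' interpolated in the moving volume.
#'
#' @param vol Moving 3D array.
#' @param affine Moving voxel-to-world 4x4 affine.
#' @param transform A `rigid_transform` mapping moving world to target world.
#' @param target_affine,target_dim Target grid definition.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return 3D array on the target grid (NA where outside the moving volume).
#' @export
apply_transform <- function(vol, affine, transform, target_affine = affine,
                            target_dim = dim(vol),
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (any(target_dim < 1)) stop("degenerate target grid")
  w <- .grid_world(target_dim, target_affine)
  wm <- transform_points(invert_transform(transform), w)
  Ainv <- solve(affine)
  vidx <- t(Ainv[1:3, 1:3] %*% t(wm) + Ainv[1:3, 4]) + 1  # 1-based
  # snap coordinates that are integer up to floating-point round-trip
  # noise, so an identity transform resamples exactly
  near <- abs(vidx - round(vidx)) < 1e-9
  vidx[near] <- round(vidx[near])
  if (interpolation == "nearest") {
    ri <- round(vidx[, 1]); rj <- round(vidx[, 2]); rk <- round(vidx[, 3])
    dm <- dim(vol)
    out <- rep(NA_real_, nrow(vidx))
    ok <- ri >= 1 & ri <= dm[1] & rj >= 1 & rj <= dm[2] & rk >= 1 & rk <= dm[3]
    out[ok] <- vol[cbind(ri[ok], rj[ok], rk[ok])]
  } else {
    out <- .trilinear(vol, vidx[, 1], vidx[, 2], vidx[, 3])
  }
  array(out, dim = target_dim)
}

#' Rigid registration by mutual-information maximization
#'
#' Registers a moving image (typically the tMIP map) to a fixed anatomical
#' image with 6 degrees of freedom. Optimization runs at full resolution:
#' a coarse grid search over translations, then over rotations, then
#' restarted Nelder-Mead refinement of all 6 parameters. The cost is a
#' Parzen-windowed (linearly soft-binned) mutual information, which keeps
#' the surface smooth at sub-voxel offsets; the moving image is trilinearly
#' resampled at each evaluation and the joint histogram restricted to the
#' fixed-image mask.
#'
#' @param moving,fixed 3D arrays.
#' @param moving_affine,fixed_affine 4x4 voxel-to-world affines.
#' @param mask Optional logical array in fixed space (default: fixed image
#'   above its 5th percentile of nonzero values).
#' @param n_bins Joint-histogram bins (default 32).
#' @param translation_search Half-width of the coarse translation grid, mm.
#' @param rotation_search Half-width of the coarse rotation grid, radians.
#' @param maxit Nelder-Mead iteration budget per level.
#' @return A `rigid_transform` mapping moving world coordinates to fixed
#'   world coordinates, with attributes `mi` (final mutual information) and
#'   `converged`. Non-convergence raises a warning carrying the best-so-far
#'   transform as the return value.
#' @export
rigid_register <- function(moving, fixed, moving_affine, fixed_affine,
                           mask = NULL, n_bins = 32L, translation_search = 6,
                           rotation_search = 6 * pi / 180, maxit = 600L) {
  if (is.null(mask)) {
    nzv <- fixed[fixed > 0]
    thr <- if (length(nzv)) stats::quantile(nzv, 0.05) else 0
    mask <- fixed > thr
  }
  center <- as.numeric(fixed_affine[1:3, 1:3] %*% ((dim(fixed) - 1) / 2) +
                         fixed_affine[1:3, 4])
  # strict-improvement tracker: optimization stages can drift along
  # cost plateaus (below the estimator's numeric resolution); the returned
  # transform is the first point attaining the best cost seen anywhere
  track <- new.env(parent = emptyenv())
  track$value <- Inf
  track$par <- rep(0, 6)
  win_f <- stats::quantile(fixed[mask], c(0.005, 0.995), names = FALSE)
  win_m <- stats::quantile(moving[is.finite(moving)], c(0.005, 0.995),
                           names = FALSE)
  cost <- function(par) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    res <- apply_transform(moving, moving_affine, tf, fixed_affine, dim(fixed))
    keep <- mask & is.finite(res)
    v <- if (sum(keep) < 100) 1e6
         else -.mi_parzen(fixed[keep], res[keep], n_bins = n_bins,
                          ra = win_f, rb = win_m)
    if (v < track$value) { track$value <- v; track$par <- par }
    v
  }

  # coarse grids: translations first, then rotations around the best
  # translation (captures the stated search ranges)
  steps <- seq(-translation_search, translation_search, by = 2)
  best <- c(0, 0, 0, 0, 0, 0)
  bestc <- cost(best)
  for (tx in steps) for (ty in steps) for (tz in steps) {
    p <- c(0, 0, 0, tx, ty, tz)
    cc <- cost(p)
    if (cc < bestc) { bestc <- cc; best <- p }
  }
  rots <- seq(-rotation_search, rotation_search, by = 2 * pi / 180)
  cand <- list(list(par = best, value = bestc))
  for (ax in rots) for (ay in rots) for (az in rots) {
    p <- c(ax, ay, az, best[4:6])
    cand[[length(cand) + 1L]] <- list(par = p, value = cost(p))
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "value"))]
  # multi-start short simplex from the top grid candidates (the MI surface
  # has nearby local optima; a single start can get trapped)
  starts <- cand[seq_len(min(4L, length(cand)))]
  probes <- lapply(starts, function(s)
    stats::optim(s$par, cost, method = "Nelder-Mead",
                 control = list(maxit = 250L, reltol = 1e-9,
                                parscale = c(rep(0.02, 3), rep(0.8, 3)))))
  o2 <- probes[[which.min(vapply(probes, `[[`, numeric(1), "value"))]]
  # restarted simplex refinement of the winner (restarting rebuilds the
  # simplex, which avoids premature collapse in narrow valleys)
  for (ps in list(c(0.01, 0.5), c(0.004, 0.15)))
    o2 <- stats::optim(o2$par, cost, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10,
                                      parscale = c(rep(ps[1], 3), rep(ps[2], 3))))
  # coordinate pattern-search polish: hops over residual fine-scale pits
  # that stall the simplex
  par <- o2$par; val <- o2$value
  for (dl in c(1, 0.5, 0.25, 0.1, 0.04, 0.015)) {
    step <- c(rep(dl * pi / 180, 3), rep(dl, 3))
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (j in 1:6) for (sg in c(-1, 1)) {
        p <- par; p[j] <- p[j] + sg * step[j]
        cc <- cost(p)
        if (cc < val) { val <- cc; par <- p; improved <- TRUE }
      }
    }
  }
  # final tight simplex around the polished point
  stats::optim(par, cost, method = "Nelder-Mead",
               control = list(maxit = 200L, reltol = 1e-12,
                              parscale = c(rep(2e-4, 3), rep(8e-3, 3))))
  o2 <- list(par = track$par, value = track$value, convergence = 0L)
  tf <- rigid_transform(o2$par[1:3], o2$par[4:6], center)
  attr(tf, "mi") <- -o2$value
  attr(tf, "converged") <- o2$convergence == 0
  if (o2$convergence != 0)
    warning("rigid_register: optimizer did not converge within the iteration ",
            "budget; returning best-so-far transform")
  tf
}

#' Pull anatomical labels into perfusion space
#'
#' Applies the inverse of the perfusion-to-anatomy registration transform by
#' nearest-neighbour pull-back resampling, so that the label value set is a
#' subset of the input's.
#'
#' @param labels A `label_map` in anatomical space.
#' @param transform The `rigid_transform` from registering the perfusion tMIP
#'   (moving) to the anatomy (fixed).
#' @param target_affine,target_dim Perfusion grid definition.
#' @return A `label_map` on the perfusion grid.
#' @export
resample_labels <- function(labels, transform, target_affine, target_dim) {
  stopifnot(inherits(labels, "label_map"))
  if (any(target_dim < 1)) stop("degenerate target grid")
  # target (perfusion) voxel -> world -> anatomy world via the forward
  # transform (= inverse of the label->perfusion mapping), then nearest label
  w <- .grid_world(target_dim, target_affine)
  wa <- transform_points(transform, w)
  Ainv <- solve(labels$affine)
  vidx <- t(Ainv[1:3, 1:3] %*% t(wa) + Ainv[1:3, 4]) + 1
  ri <- round(vidx[, 1]); rj <- round(vidx[, 2]); rk <- round(vidx[, 3])
  dm <- dim(labels$labels)
  out <- rep(0L, nrow(vidx))
  ok <- ri >= 1 & ri <= dm[1] & rj >= 1 & rj <= dm[2] & rk >= 1 & rk <= dm[3]
  out[ok] <- labels$labels[cbind(ri[ok], rj[ok], rk[ok])]
  structure(list(labels = array(out, dim = target_dim), lut = labels$lut,
                 affine = target_affine),
            class = "label_map")
}

#' Write / read a transform as a 4x4 text matrix
#'
#' Plain-text, row-major, whitespace-separated (FSL .mat style layout).
#'
#' @param transform A `rigid_transform`.
#' @param path File path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a `rigid_transform` (angles/translation recovered from the
#'   matrix, centre at the origin).
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  utils::write.table(format(transform$matrix, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  M <- as.matrix(utils::read.table(path))
  dimnames(M) <- NULL
  if (!all(dim(M) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  R <- M[1:3, 1:3]
  ay <- asin(pmin(pmax(-R[3, 1], -1), 1))
  ax <- atan2(R[3, 2], R[3, 3])
  az <- atan2(R[2, 1], R[1, 1])
  tf <- rigid_transform(c(ax, ay, az), M[1:3, 4], c(0, 0, 0))
  tf$matrix <- M
  tf
}
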