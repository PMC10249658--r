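# Input-gradient saliency of site predictions, back-projection onto atoms,
# and radial frequency / saliency distributions by atom type.
#
# The prediction score of a site is the sum of the predicted probabilities
# over a target voxel region (by default all voxels within 3 A of the
# site). Saliency is the absolute gradient of that score with respect to
# each input channel, optionally averaged over noisy copies of the input
# (SmoothGrad); with n_samples = 1 and zero noise it reduces to the plain
# gradient.

#' Voxel indices within a radius of a point
#'
#' @param image a `voxel_image`.
#' @param point numeric length-3 coordinate (A).
#' @param radius radius in A (default 3).
#' @return integer vector of flat voxel indices.
#' @export
voxels_near <- function(image, point, radius = 3.0) {
  ctr <- .voxel_centers(image$origin, image$n, image$spacing)
  which((ctr[, 1] - point[1])^2 + (ctr[, 2] - point[2])^2 +
          (ctr[, 3] - point[3])^2 <= radius^2)
}

#' Gradient saliency of a prediction score
#'
#' @param model a trained `mg_model`.
#' @param image a `voxel_image`.
#' @param target_region integer vector of flat voxel indices over which
#'   the predicted probabilities are summed to form the score.
#' @param n_samples number of noisy input copies to average (SmoothGrad);
#'   1 with `noise_sigma = 0` gives the plain input gradient.
#' @param noise_sigma noise standard deviation as a fraction of each
#'   channel's value range.
#' @param seed seed for the noise draws.
#' @return an object of class `saliency_map`: per-channel non-negative
#'   gradient arrays `occupancy` and `charge` with the image's geometry.
#' @export
saliency_grid <- function(model, image, target_region, n_samples = 25,
                          noise_sigma = 0.1, seed = 1) {
  n <- image$n
  V <- n^3
  if (!length(target_region)) stop("target_region is empty")
  if (any(target_region < 1 | target_region > V))
    stop("target_region outside the grid")
  x0 <- .image_matrix(image)
  dims <- c(n, n, n)
  gp <- matrix(0, V, 1)
  gp[target_region, 1] <- 1
  rng <- apply(x0, 2, function(col) diff(range(col)))
  set.seed(seed)
  acc <- matrix(0, V, 2)
  for (s in seq_len(n_samples)) {
    x <- x0
    if (noise_sigma > 0)
      for (ch in 1:2) if (rng[ch] > 0)
        x[, ch] <- x[, ch] + rnorm(V, sd = noise_sigma * rng[ch])
    fw <- .net_forward(model, x, dims, keep_cache = TRUE)
    g <- .net_backward(model, fw, gp, dims)
    acc <- acc + abs(g$gx)
  }
  acc <- acc / n_samples
  structure(list(origin = image$origin, spacing = image$spacing, n = n,
                 occupancy = array(acc[, 1], dims),
                 charge = array(acc[, 2], dims),
                 smoothing = list(n_samples = n_samples,
                                  noise_sigma = noise_sigma, seed = seed)),
            class = "saliency_map")
}

# trilinear interpolation of a grid array at one point (voxel-centre lattice)
.trilinear <- function(arr, origin, spacing, n, pt) {
  u <- (pt - origin) / spacing - 0.5 # 0-based voxel-centre coordinates
  i0 <- floor(u)
  f <- u - i0
  val <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1] + dx; iy <- i0[2] + dy; iz <- i0[3] + dz
    if (ix < 0 || iy < 0 || iz < 0 || ix >= n || iy >= n || iz >= n) next
    wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    val <- val + wgt * arr[ix + 1, iy + 1, iz + 1]
  }
  val
}

#' Project voxel saliency onto atoms
#'
#' Each atom's saliency per channel is the trilinear interpolation of the
#' channel grid at the atom position; atoms outside the box get 0.
#'
#' @param map a `saliency_map`.
#' @param structure an `rna_structure`.
#' @return the structure's atom table with `occ_saliency` and
#'   `chg_saliency` columns appended.
#' @export
atom_saliency <- function(map, structure) {
  a <- structure$atoms
  occ <- numeric(nrow(a)); chg <- numeric(nrow(a))
  hi <- map$origin + map$n * map$spacing
  for (i in seq_len(nrow(a))) {
    pt <- c(a$x[i], a$y[i], a$z[i])
    if (any(pt < map$origin) || any(pt > hi)) next
    occ[i] <- .trilinear(map$occupancy, map$origin, map$spacing, map$n, pt)
    chg[i] <- .trilinear(map$charge, map$origin, map$spacing, map$n, pt)
  }
  a$occ_saliency <- occ
  a$chg_saliency <- chg
  a
}

#' Radial frequency or saliency distribution by atom type
#'
#' Histograms of centre-atom distances per atom class (the six-type
#' scheme), weighted by 1 (frequency) or by a per-atom saliency column,
#' then normalized so each non-empty class curve has maximum 1.
#'
#' @param centers site table (`x`, `y`, `z`) of the ions of interest.
#' @param atoms atom table carrying `atom_class` (and saliency columns
#'   when `weight != "frequency"`).
#' @param weight one of `"frequency"`, `"occ_saliency"`, `"chg_saliency"`.
#' @param breaks bin edges in A (default 0 to 8 by 0.25).
#' @param by group by `"atom_class"` (default) or `"name"`.
#' @return a data.frame with `group`, `bin_lo`, `bin_hi`, `value`
#'   (normalized to max 1 per group).
#' @export
radial_profile <- function(centers, atoms,
                           weight = c("frequency", "occ_saliency",
                                      "chg_saliency"),
                           breaks = seq(0, 8, by = 0.25),
                           by = "atom_class") {
  weight <- match.arg(weight)
  stopifnot(!is.unsorted(breaks), all(breaks >= 0))
  if (!nrow(centers) || !nrow(atoms))
    return(data.frame(group = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), value = numeric(0)))
  atoms <- atoms[!atoms$is_water & !atoms$is_ion, , drop = FALSE]
  nb <- length(breaks) - 1
  groups <- sort(unique(atoms[[by]]))
  out <- list()
  for (g in groups) {
    sub <- atoms[atoms[[by]] == g, , drop = FALSE]
    acc <- numeric(nb)
    for (ci in seq_len(nrow(centers))) {
      d <- sqrt((sub$x - centers$x[ci])^2 + (sub$y - centers$y[ci])^2 +
                  (sub$z - centers$z[ci])^2)
      w <- if (weight == "frequency") rep(1, nrow(sub)) else sub[[weight]]
      inb <- findInterval(d, breaks, rightmost.closed = TRUE)
      ok <- inb >= 1 & inb <= nb
      if (any(ok))
        acc <- acc + as.numeric(tapply(w[ok], factor(inb[ok],
          levels = seq_len(nb)), sum, default = 0))
    }
    if (max(acc) > 0) acc <- acc / max(acc)
    out[[g]] <- data.frame(group = g, bin_lo = breaks[-length(breaks)],
                           bin_hi = breaks[-1], value = acc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove coordinating atoms from a structure
#'
#' Returns a copy of the structure with the listed atoms deleted, for
#' prediction-before/after perturbation experiments (a model that relies
#' on the coordinating atoms should lose the site when they are removed).
#'
#' @param structure an `rna_structure`.
#' @param serials atom serial numbers to delete.
#' @return the perturbed `rna_structure`.
#' @export
ablate_coordinators <- function(structure, serials) {
  if (!length(serials)) return(structure)
  miss <- setdiff(serials, structure$atoms$serial)
  if (length(miss)) stop("unknown atom serial(s): ",
                         paste(miss, collapse = ", "))
  structure$atoms <- structure$atoms[!structure$atoms$serial %in% serials, ,
                                     drop = FALSE]
  rownames(structure$atoms) <- NULL
  structure
}
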