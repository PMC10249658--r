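# Two-channel voxel featurization of the local environment of a nucleotide.
#
# A voxel_image is a cubic grid (default 24 A edge) centred on the
# heavy-atom centroid of a nucleotide, with two channels:
#   occupancy  max over atoms of 1 - exp(-(r_vdw/d)^12)   in [0, 1]
#   charge     sum over atoms of q * Gaussian(sigma = 1 voxel)
# Waters and ions are never featurized: the model must not see the answer.

#' Grid configuration
#'
#' @param edge box edge length in Angstrom.
#' @param spacing voxel spacing in Angstrom.
#' @param sigma_charge Gaussian smearing width of the charge channel, in
#'   voxel units (the physical sigma is `sigma_charge * spacing`).
#' @param label_sigma Gaussian width of the training label kernel (A).
#' @param atom_margin atoms farther than `edge/2 + atom_margin` from the
#'   box centre are skipped.
#' @return a list of class `grid_config`.
#' @export
grid_config <- function(edge = 24, spacing = 1.0, sigma_charge = 1.0,
                        label_sigma = 1.5, atom_margin = 5) {
  stopifnot(edge > 0, spacing > 0, label_sigma > 0)
  n <- round(edge / spacing)
  structure(list(edge = edge, spacing = spacing, n = n,
                 sigma_charge = sigma_charge, label_sigma = label_sigma,
                 atom_margin = atom_margin), class = "grid_config")
}

#' Heavy-atom centroid of a residue
#'
#' @param structure an `rna_structure`.
#' @param chain,resseq residue key.
#' @return numeric length-3 centre (A).
#' @export
residue_center <- function(structure, chain, resseq) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resseq == resseq & !a$is_water & !a$is_ion
  if (!any(sel)) stop("residue ", chain, ":", resseq, " not found or empty")
  c(mean(a$x[sel]), mean(a$y[sel]), mean(a$z[sel]))
}

#' Occupancy kernel
#'
#' Soft volume indicator `1 - exp(-(r_vdw/d)^12)`; the d -> 0 limit is 1.
#' Strictly decreasing in `d` for fixed `r_vdw`.
#'
#' @param d distance(s) in Angstrom, `>= 0`.
#' @param r_vdw van der Waals radius (A), `> 0`.
#' @return occupancy value(s) in `[0, 1]`.
#' @export
occupancy_value <- function(d, r_vdw) {
  stopifnot(all(d >= 0), all(r_vdw > 0))
  out <- ifelse(d == 0, 1, 1 - exp(-(r_vdw / d)^12))
  out
}

# voxel centres of a grid with the given origin, as an (n^3, 3) matrix;
# index v = ix + n*(iy - 1 + n*(iz - 1)), x fastest (R array order)
.voxel_centers <- function(origin, n, spacing) {
  s <- (seq_len(n) - 0.5) * spacing
  cbind(rep(origin[1] + s, times = n * n),
        rep(rep(origin[2] + s, each = n), times = n),
        rep(origin[3] + s, each = n * n))
}

#' Voxelize the neighbourhood of one nucleotide
#'
#' @param structure an annotated `rna_structure` (see [assign_attributes()]).
#' @param chain,resseq residue key of the centre nucleotide.
#' @param cfg a [grid_config()].
#' @return an object of class `voxel_image` with `occupancy` and `charge`
#'   arrays of dim `c(n, n, n)`.
#' @export
make_image <- function(structure, chain, resseq, cfg = grid_config()) {
  a <- structure$atoms
  if (is.null(a$charge))
    stop("assign_attributes() must be called before make_image()")
  ctr <- residue_center(structure, chain, resseq)
  origin <- ctr - cfg$edge / 2
  sel <- !a$is_water & !a$is_ion
  d2ctr <- (a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2
  sel <- sel & d2ctr <= (cfg$edge / 2 + cfg$atom_margin)^2
  n <- cfg$n
  centers <- .voxel_centers(origin, n, cfg$spacing)
  if (!any(sel)) {
    occ <- array(0, c(n, n, n)); chg <- array(0, c(n, n, n))
  } else {
    f <- cpp_featurize(centers, as.matrix(a[sel, c("x", "y", "z")]),
                       a$vdw[sel], a$charge[sel],
                       cfg$sigma_charge * cfg$spacing)
    occ <- array(f$occupancy, c(n, n, n))
    chg <- array(f$charge, c(n, n, n))
  }
  structure(list(origin = origin, edge = cfg$edge, spacing = cfg$spacing,
                 n = n, occupancy = occ, charge = chg, center = ctr,
                 center_residue = list(chain = chain, resseq = resseq)),
            class = "voxel_image")
}

#' Build the training label grid for an image
#'
#' The label at a voxel centre v is `max over ions of
#' exp(-||v - ion||^2 / (2 sigma^2))` with `sigma = cfg$label_sigma`
#' (default 1.5 A, half the 3 A hit radius). Without ions the grid is all
#' zeros; ions outside the box still contribute their Gaussian tail.
#'
#' @param image a `voxel_image`.
#' @param ions a data.frame with `x`, `y`, `z` columns (e.g. [bound_ions()]).
#' @param cfg a [grid_config()] (for `label_sigma`).
#' @return an object of class `probability_grid`.
#' @export
make_label <- function(image, ions, cfg = grid_config()) {
  n <- image$n
  vals <- array(0, c(n, n, n))
  if (!is.null(ions) && nrow(ions)) {
    centers <- .voxel_centers(image$origin, n, image$spacing)
    s2 <- 2 * cfg$label_sigma^2
    for (i in seq_len(nrow(ions))) {
      d2 <- (centers[, 1] - ions$x[i])^2 + (centers[, 2] - ions$y[i])^2 +
        (centers[, 3] - ions$z[i])^2
      vals <- pmax(vals, array(exp(-d2 / s2), c(n, n, n)))
    }
  }
  structure(list(origin = image$origin, spacing = image$spacing, n = n,
                 values = vals), class = "probability_grid")
}

#' Enumerate per-nucleotide images (and labels) of a structure
#'
#' One image per RNA nucleotide, in deterministic residue order (chain,
#' then residue number). Non-RNA chains (protein, DNA) contribute context
#' atoms but no images.
#'
#' @param structure an annotated `rna_structure`.
#' @param cfg a [grid_config()].
#' @param with_labels also build label grids from the structure's bound
#'   Mg ions.
#' @return a list with elements `images` (list of `voxel_image`) and,
#'   when `with_labels`, `labels` (list of `probability_grid`).
#' @export
enumerate_images <- function(structure, cfg = grid_config(),
                             with_labels = FALSE) {
  keys <- residue_keys(structure)
  imgs <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys)))
    imgs[[i]] <- make_image(structure, keys$chain[i], keys$resseq[i], cfg)
  out <- list(images = imgs, keys = keys)
  if (with_labels) {
    ions <- bound_ions(structure)
    out$labels <- lapply(imgs, make_label, ions = ions, cfg = cfg)
  }
  out
}

# stack an image into the (V, 2) matrix consumed by the network
.image_matrix <- function(image) {
  cbind(as.numeric(image$occupancy), as.numeric(image$charge))
}
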