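# Assembling per-nucleotide probability grids into a global field and
# extracting discrete ranked Mg2+ site predictions.
#
# Boxes from neighbouring nucleotides overlap. Each global lattice voxel
# takes the arithmetic mean over all boxes covering it (the mean avoids
# double counting in the ranking score). High-probability voxels are
# grouped by DBSCAN; within each cluster, representative points come from
# probability-weighted k-means (k from the cluster-diameter rule), and
# each representative is scored by the summed probability of its k-means
# partition.

#' Assemble probability grids into a global sparse field
#'
#' Voxel centres are snapped to a global lattice with the common grid
#' spacing; a voxel covered by several boxes stores the mean probability
#' and the number of contributing boxes.
#'
#' @param grids list of `probability_grid` objects sharing one spacing.
#' @return a data.frame of class `ion_field` with columns
#'   `x`, `y`, `z` (voxel centre, A), `p` (mean probability), `n_boxes`.
#' @export
assemble_field <- function(grids) {
  if (!length(grids)) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      p = numeric(0), n_boxes = integer(0))
    class(out) <- c("ion_field", class(out))
    attr(out, "spacing") <- NA_real_
    return(out)
  }
  sp <- vapply(grids, function(g) g$spacing, 1)
  if (max(sp) - min(sp) > 1e-9) stop("grids have mismatched spacing")
  sp <- sp[1]
  # global lattice of voxel centres at (k + 1/2) * spacing: every box's own
  # centres land bijectively on it (they are spaced by exactly `sp`)
  snap <- function(v) as.integer(floor(v / sp))
  parts <- lapply(grids, function(g) {
    ctr <- .voxel_centers(g$origin, g$n, g$spacing)
    data.table::data.table(ix = snap(ctr[, 1]), iy = snap(ctr[, 2]),
                           iz = snap(ctr[, 3]), p = as.numeric(g$values))
  })
  dt <- data.table::rbindlist(parts)
  ix <- iy <- iz <- p <- NULL # data.table NSE
  agg <- dt[, list(p = mean(p), n_boxes = .N), by = list(ix, iy, iz)]
  out <- data.frame(x = (agg$ix + 0.5) * sp, y = (agg$iy + 0.5) * sp,
                    z = (agg$iz + 0.5) * sp,
                    p = agg$p, n_boxes = agg$n_boxes)
  class(out) <- c("ion_field", class(out))
  attr(out, "spacing") <- sp
  out
}

# plain DBSCAN on an (n, 3) coordinate matrix; a point is core when it has
# at least min_samples neighbours within eps (the point itself included).
# Returns integer cluster ids, 0 = noise.
.dbscan3 <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  if (!n) return(integer(0))
  D <- as.matrix(dist(xyz))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_samples
  lab <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (lab[j] == 0L) {
        lab[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][lab[nb[[j]]] == 0L])
      }
    }
  }
  lab
}

# probability-weighted k-means with seeded k-means++ initialization
.wkmeans <- function(xyz, w, k, max_iter = 50) {
  n <- nrow(xyz)
  if (k >= n) return(list(assign = seq_len(n), centers = xyz))
  # k-means++ seeding (weighted)
  centers <- matrix(0, k, 3)
  i0 <- sample.int(n, 1, prob = w)
  centers[1, ] <- xyz[i0, ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(vapply(seq_len(j - 1), function(c)
      rowSums((xyz - matrix(centers[c, ], n, 3, byrow = TRUE))^2),
      numeric(n)), 1, min)
    pr <- w * d2
    if (sum(pr) <= 0) pr <- rep(1, n)
    centers[j, ] <- xyz[sample.int(n, 1, prob = pr), ]
  }
  assign <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(c)
      rowSums((xyz - matrix(centers[c, ], n, 3, byrow = TRUE))^2),
      numeric(n))
    new_assign <- max.col(-d2, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
    for (c in seq_len(k)) {
      sel <- assign == c
      if (any(sel))
        centers[c, ] <- colSums(xyz[sel, , drop = FALSE] * w[sel]) /
          sum(w[sel])
    }
  }
  list(assign = assign, centers = centers)
}

#' Extract ranked ion sites from a global probability field
#'
#' Voxels with `p >= threshold` are clustered with DBSCAN (`eps`,
#' `min_samples`); inside every cluster, k representative points are found
#' by probability-weighted k-means, with `k = max(1, floor(diameter / 6))`
#' so that elongated high-probability channels can yield several sites.
#' Each representative becomes a site at the probability-weighted centroid
#' of its partition, scored by the partition's summed probability. Sites
#' are ranked by score (ties broken lexicographically by coordinates).
#'
#' @param field an `ion_field` from [assemble_field()].
#' @param threshold probability threshold in (0, 1).
#' @param eps DBSCAN radius (A).
#' @param min_samples DBSCAN minimum neighbour count (self included).
#' @param seed seed for the k-means++ initialization.
#' @param diameter_per_site cluster diameter (A) granted per extra
#'   representative point.
#' @return a data.frame of predicted sites: `rank`, `x`, `y`, `z`,
#'   `score`, `cluster_id`, `n_member_voxels`, `provenance`.
#' @export
extract_sites <- function(field, threshold = 0.5, eps = 2.0,
                          min_samples = 4, seed = 1,
                          diameter_per_site = 6) {
  stopifnot(threshold > 0, threshold < 1)
  empty <- data.frame(rank = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), score = numeric(0),
                      cluster_id = integer(0), n_member_voxels = integer(0),
                      provenance = character(0))
  sel <- field$p >= threshold
  if (!any(sel)) return(empty)
  xyz <- as.matrix(field[sel, c("x", "y", "z")])
  w <- field$p[sel]
  lab <- .dbscan3(xyz, eps, min_samples)
  if (!any(lab > 0)) return(empty)
  out <- list()
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (cl in sort(unique(lab[lab > 0]))) {
    m <- lab == cl
    cx <- xyz[m, , drop = FALSE]
    cw <- w[m]
    diam <- if (nrow(cx) > 1) max(dist(cx)) else 0
    k <- max(1L, floor(diam / diameter_per_site))
    km <- .wkmeans(cx, cw, k)
    for (j in seq_len(max(km$assign))) {
      ps <- km$assign == j
      if (!any(ps)) next
      ctr <- colSums(cx[ps, , drop = FALSE] * cw[ps]) / sum(cw[ps])
      out[[length(out) + 1]] <- data.frame(
        x = ctr[1], y = ctr[2], z = ctr[3], score = sum(cw[ps]),
        cluster_id = cl, n_member_voxels = sum(ps))
    }
  }
  out <- do.call(rbind, out)
  ord <- order(-out$score, out$x, out$y, out$z)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$provenance <- "predicted"
  rownames(out) <- NULL
  out[, c("rank", "x", "y", "z", "score", "cluster_id",
          "n_member_voxels", "provenance")]
}

#' Keep the top-n ranked sites
#'
#' @param sites a ranked site table.
#' @param n number of sites to keep (`>= 0`).
#' @return the first `min(n, nrow(sites))` rows, order preserved.
#' @export
topn <- function(sites, n) {
  stopifnot(n >= 0)
  head(sites, n)
}

#' Write predicted sites as TSV
#'
#' @param sites a site table from [extract_sites()].
#' @param path output path.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(sites[, c("rank", "x", "y", "z", "score", "cluster_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site TSV written by [write_sites_tsv()]
#'
#' @param path input path.
#' @return a site table.
#' @export
read_sites_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE)
}

#' Write predicted sites as PDB HETATM MG records
#'
#' The occupancy column carries the score normalized to the top site.
#'
#' @param sites a site table.
#' @param path output path.
#' @export
write_sites_pdb <- function(sites, path) {
  n <- nrow(sites)
  if (!n) {
    writeLines("END", path)
    return(invisible(path))
  }
  occ <- sites$score / max(sites$score)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(sites[, c("x", "y", "z")]))),
                   type = rep("HETATM", n), resno = seq_len(n),
                   resid = rep("MG", n), eleno = seq_len(n),
                   elety = rep("MG", n), chain = rep("M", n),
                   o = occ, b = rep(0, n), elesy = rep("MG", n))
  invisible(path)
}
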