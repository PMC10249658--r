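# Seeded generator of synthetic RNA-like structures with planted Mg2+
# sites, so that training, prediction and motif analysis can be exercised
# end to end without any external data.
#
# Chains are idealized single strands: a rigid all-heavy-atom
# ribonucleotide template propagated along a helical axis with fixed rise
# and twist (the template and screw parameters live in
# inst/extdata/nt_templates.tsv). Sites are planted by placing an MG at a
# position that realizes the requested inner-sphere motif exactly: the
# coordinating phosphate oxygen is re-pointed along the P -> Mg direction
# so that |Mg-O| equals the configured inner-sphere distance; the
# 16-member-ring geometry additionally bends the chain at the intervening
# phosphate; clamp/base-contact motifs place a rigid single-nucleotide
# fragment on a second chain. Waters can complete the octahedral shell
# (they are parsed and counted downstream but never featurized).

.screw_twist_deg <- 32.7
.screw_rise <- 2.81

.template_env <- new.env(parent = emptyenv())

.nt_templates <- function() {
  if (is.null(.template_env$tab)) {
    path <- system.file("extdata", "nt_templates.tsv", package = "voxmg")
    .template_env$tab <- read.table(path, header = TRUE, sep = "\t",
                                    quote = "", stringsAsFactors = FALSE)
  }
  .template_env$tab
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.rot_axis <- function(axis, angle) {
  # Rodrigues rotation matrix
  u <- .unit(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

.rot_a_to_b <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rot_axis(pracma_cross(a, ref), pi))
  }
  .rot_axis(v / s, atan2(s, cth))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generator configuration
#'
#' @param n_structures number of structures in the corpus.
#' @param n_residues residues per chain.
#' @param motif_mix named fractions over planted motif labels (must sum
#'   to 1).
#' @param inner_distance planted Mg-O inner-sphere distance (A); 2.1 is
#'   the canonical inner-sphere bond length.
#' @param decoy_fraction fraction of structures generated without a site.
#' @param coordinate_noise Gaussian noise (A, per coordinate) added to
#'   RNA and water atoms after planting.
#' @param add_waters complete planted shells to octahedral six-coordination
#'   with water oxygens.
#' @param seed master seed.
#' @return a list of class `gen_config`.
#' @export
gen_config <- function(n_structures = 50, n_residues = 6,
                       motif_mix = c(ring_10 = 0.30, ring_16 = 0.20,
                                     magnesium_clamp = 0.15,
                                     phosphate_pyramid = 0.10,
                                     g_phosphate = 0.10, y_clamp = 0.05,
                                     u_phosphate = 0.05,
                                     single_atom = 0.05),
                       inner_distance = 2.1, decoy_fraction = 0.2,
                       coordinate_noise = 0.15, add_waters = TRUE,
                       seed = 1) {
  stopifnot(abs(sum(motif_mix) - 1) < 1e-6, coordinate_noise >= 0,
            inner_distance > 0)
  structure(list(n_structures = n_structures, n_residues = n_residues,
                 motif_mix = motif_mix, inner_distance = inner_distance,
                 decoy_fraction = decoy_fraction,
                 coordinate_noise = coordinate_noise,
                 add_waters = add_waters, seed = seed),
            class = "gen_config")
}

.atoms_skeleton <- function(name, resname, chain, resseq, xyz,
                            is_water = FALSE, is_ion = FALSE,
                            is_rna = !(is_water | is_ion)) {
  data.frame(serial = NA_integer_, name = name,
             altloc = "", resname = resname, chain = chain,
             resseq = resseq, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 1)),
             is_water = is_water, is_ion = is_ion, is_rna = is_rna,
             stringsAsFactors = FALSE)
}

.renumber <- function(structure) {
  structure$atoms$serial <- seq_len(nrow(structure$atoms))
  structure$atoms$element[structure$atoms$name == "MG"] <- "MG"
  rownames(structure$atoms) <- NULL
  structure
}

#' Generate an idealized single-strand RNA chain
#'
#' A rigid per-residue heavy-atom template is propagated along a helical
#' axis with fixed rise and twist; the sequence is drawn uniformly from
#' A/C/G/U under the seed. Consecutive residues are linked by an
#' O3'-P bond of 1.60 A by construction.
#'
#' @param n number of residues (`>= 2`).
#' @param seed sequence seed.
#' @param chain chain identifier.
#' @return an annotated `rna_structure`.
#' @export
generate_chain <- function(n, seed = 1, chain = "A") {
  if (n < 2) stop("a chain needs at least 2 residues")
  tab <- .nt_templates()
  set.seed(seed)
  seqv <- sample(.std_nt, n, replace = TRUE)
  th <- .screw_twist_deg * pi / 180
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- tab[tab$resname == seqv[i], , drop = FALSE]
    X <- as.matrix(tt[, c("x", "y", "z")])
    Rm <- .rot_axis(c(0, 0, 1), th * (i - 1))
    X <- t(Rm %*% t(X))
    X[, 3] <- X[, 3] + .screw_rise * (i - 1)
    rows[[i]] <- .atoms_skeleton(tt$atom, seqv[i], chain, i, X)
  }
  s <- structure(list(atoms = do.call(rbind, rows), resolution = 2.0,
                      source_id = sprintf("synth-%s", chain)),
                 class = "rna_structure")
  s <- .renumber(s)
  assign_attributes(s)
}

.atom_xyz <- function(structure, chain, resseq, name) {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resseq == resseq & a$name == name)
  if (!length(i)) stop("atom ", chain, ":", resseq, ":", name, " not found")
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

.set_atom_xyz <- function(structure, chain, resseq, name, xyz) {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resseq == resseq & a$name == name)
  structure$atoms$x[i[1]] <- xyz[1]
  structure$atoms$y[i[1]] <- xyz[2]
  structure$atoms$z[i[1]] <- xyz[3]
  structure
}

# distance from point to every O/N heavy atom except the listed (chain,
# resseq, name) triples; used to check a planted site's clearance
.clearance <- function(structure, pt, exclude) {
  a <- structure$atoms
  sel <- a$element %in% c("O", "N") & !a$is_water & !a$is_ion
  if (length(exclude)) {
    key <- paste(a$chain, a$resseq, a$name)
    sel <- sel & !(key %in% exclude)
  }
  if (!any(sel)) return(Inf)
  min(sqrt((a$x[sel] - pt[1])^2 + (a$y[sel] - pt[2])^2 +
             (a$z[sel] - pt[3])^2))
}

# candidate unit vectors orthogonal to axis, biased toward out_dir
.perp_candidates <- function(axis, out_dir, n_cand = 16) {
  e1 <- out_dir - sum(out_dir * .unit(axis)) * .unit(axis)
  if (sqrt(sum(e1^2)) < 1e-8) {
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- pracma_cross(axis, ref)
  }
  e1 <- .unit(e1)
  e2 <- .unit(pracma_cross(.unit(axis), e1))
  lapply(seq(0, 2 * pi, length.out = n_cand + 1)[-(n_cand + 1)],
         function(a) cos(a) * e1 + sin(a) * e2)
}

# place Mg equidistant (R) from two phosphorus atoms, choosing the
# direction on the perpendicular circle with the best clearance
.mg_between <- function(structure, pa, pb, R, exclude) {
  axis <- pb - pa
  half <- sqrt(sum(axis^2)) / 2
  if (half >= R) return(NULL)
  rad <- sqrt(R^2 - half^2)
  m <- (pa + pb) / 2
  a <- structure$atoms
  heavy <- !a$is_water & !a$is_ion
  ctr <- c(mean(a$x[heavy]), mean(a$y[heavy]), mean(a$z[heavy]))
  out_dir <- m - ctr
  if (sqrt(sum(out_dir^2)) < 1e-8) out_dir <- c(1, 0, 0)
  best <- NULL; best_cl <- -Inf
  for (u in .perp_candidates(axis, .unit(out_dir))) {
    pt <- m + rad * u
    cl <- .clearance(structure, pt, exclude)
    if (cl > best_cl) { best_cl <- cl; best <- pt }
  }
  best
}

.repoint_op <- function(structure, chain, resseq, mg, op_name = "OP1",
                        pbond = 1.48) {
  p <- .atom_xyz(structure, chain, resseq, "P")
  .set_atom_xyz(structure, chain, resseq, op_name,
                p + pbond * .unit(mg - p))
}

# rigid hinge: rotate all atoms of residues >= pivot about an axis through
# P(pivot) so that |P(pivot-1) - P(pivot+1)| becomes target_dist
.hinge_bend <- function(structure, chain, pivot, target_dist) {
  pprev <- .atom_xyz(structure, chain, pivot - 1, "P")
  ppiv <- .atom_xyz(structure, chain, pivot, "P")
  pnext <- .atom_xyz(structure, chain, pivot + 1, "P")
  v1 <- pprev - ppiv; v2 <- pnext - ppiv
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (target_dist >= l1 + l2 || target_dist <= abs(l1 - l2))
    stop("hinge target distance infeasible")
  cth <- (l1^2 + l2^2 - target_dist^2) / (2 * l1 * l2)
  phi_target <- acos(pmin(1, pmax(-1, cth)))
  phi_now <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (l1 * l2))))
  axis <- pracma_cross(v1, v2)
  if (sqrt(sum(axis^2)) < 1e-8) axis <- c(0, 0, 1)
  sel <- structure$atoms$chain == chain & structure$atoms$resseq >= pivot
  X <- as.matrix(structure$atoms[sel, c("x", "y", "z")])
  best <- NULL; best_err <- Inf
  for (sgn in c(1, -1)) {
    Rm <- .rot_axis(axis, sgn * (phi_now - phi_target))
    Xr <- t(Rm %*% t(sweep(X, 2, ppiv))) + matrix(ppiv, nrow(X), 3,
                                                  byrow = TRUE)
    pn <- Xr[which(structure$atoms$name[sel] == "P" &
                     structure$atoms$resseq[sel] == pivot + 1)[1], ]
    err <- abs(sqrt(sum((pprev - pn)^2)) - target_dist)
    if (err < best_err) { best_err <- err; best <- Xr }
  }
  structure$atoms$x[sel] <- best[, 1]
  structure$atoms$y[sel] <- best[, 2]
  structure$atoms$z[sel] <- best[, 3]
  structure
}

# rigidly place a single-nucleotide fragment (its own chain) so that the
# named child atom sits at distance `dist` from mg along direction u, with
# the child->parent bond pointing away from the ion; the roll about u is
# chosen for maximal clearance from the ion
.place_fragment <- function(structure, mg, u, resname, child, parent,
                            dist, chain_id) {
  tab <- .nt_templates()
  tt <- tab[tab$resname == resname, , drop = FALSE]
  X <- as.matrix(tt[, c("x", "y", "z")])
  rownames(X) <- tt$atom
  tchild <- X[child, ]; tparent <- X[parent, ]
  R1 <- .rot_a_to_b(tparent - tchild, u)
  X0 <- t(R1 %*% t(sweep(X, 2, tchild)))
  best <- NULL; best_cl <- -Inf
  for (roll in seq(0, 2 * pi, length.out = 13)[-13]) {
    Rr <- .rot_axis(u, roll)
    Xr <- t(Rr %*% t(X0)) + matrix(mg + dist * u, nrow(X0), 3, byrow = TRUE)
    other <- setdiff(rownames(X), child)
    isON <- grepl("^[ON]", other)
    d <- sqrt(rowSums((Xr[other[isON], , drop = FALSE] -
                         matrix(mg, sum(isON), 3, byrow = TRUE))^2))
    cl <- min(d)
    if (cl > best_cl) { best_cl <- cl; best <- Xr }
  }
  add <- .atoms_skeleton(tt$atom, resname, chain_id, 1L, best)
  structure$atoms <- rbind(structure$atoms, add[, names(structure$atoms)])
  structure
}

# complete the shell to octahedral six-coordination with water oxygens
.add_octahedral_waters <- function(structure, mg, ligand_dirs, dist) {
  k <- length(ligand_dirs)
  need <- 6 - k
  if (need <= 0) return(structure)
  e1 <- ligand_dirs[[1]]
  e2cand <- if (k >= 2) ligand_dirs[[2]] else c(0, 0, 1)
  e2 <- e2cand - sum(e2cand * e1) * e1
  if (sqrt(sum(e2^2)) < 1e-6) {
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1
  }
  e2 <- .unit(e2)
  e3 <- pracma_cross(e1, e2)
  cand <- list(e1, -e1, e2, -e2, e3, -e3)
  sep <- vapply(cand, function(d)
    min(vapply(ligand_dirs, function(l) acos(pmin(1, pmax(-1, sum(d * l)))),
               1)), 1)
  ord <- order(-sep)
  placed <- 0L
  wseq <- max(structure$atoms$resseq[structure$atoms$is_water], 0) + 1L
  rows <- list()
  for (ci in ord) {
    if (placed >= need) break
    if (sep[ci] < pi / 6) next
    pt <- mg + dist * cand[[ci]]
    rows[[length(rows) + 1]] <- .atoms_skeleton("O", "HOH", "W",
                                                wseq + placed,
                                                matrix(pt, 1, 3),
                                                is_water = TRUE)
    placed <- placed + 1L
  }
  if (length(rows))
    structure$atoms <- rbind(structure$atoms,
                             do.call(rbind, rows)[, names(structure$atoms)])
  structure
}

#' Plant an Mg2+ site realizing a named inner-sphere motif
#'
#' Places an MG ion (written as a HETATM record downstream) at a position
#' that realizes the requested motif exactly at `cfg$inner_distance`,
#' re-pointing the coordinating phosphate oxygens along the P-to-ion
#' direction, bending the chain at the intervening phosphate for the
#' 16-member ring, and adding rigid single-nucleotide fragments on extra
#' chains for clamp- and base-contact motifs. Optionally completes the
#' shell to octahedral six-coordination with waters, then adds coordinate
#' noise to RNA and water atoms (never to the ion).
#'
#' @param chain_structure an annotated `rna_structure` from
#'   [generate_chain()].
#' @param motif one of `ring_10`, `ring_16`, `phosphate_pyramid`,
#'   `magnesium_clamp`, `y_clamp`, `g_phosphate`, `u_phosphate`,
#'   `single_atom`.
#' @param cfg a [gen_config()].
#' @param seed noise seed.
#' @param anchor index of the first anchored residue (defaults to 2).
#' @return a list: `structure` (with the MG and any fragments/waters) and
#'   `site` (one-row data.frame `x`, `y`, `z`, `label`).
#' @export
plant_site <- function(chain_structure, motif, cfg = gen_config(),
                       seed = 1, anchor = 2L) {
  s <- chain_structure
  # work on the bare atom table; attributes are re-assigned at the end
  base_cols <- c("serial", "name", "altloc", "resname", "chain", "resseq",
                 "x", "y", "z", "element", "is_water", "is_ion", "is_rna")
  s$atoms <- s$atoms[, base_cols]
  ch <- s$atoms$chain[1]
  nres <- max(s$atoms$resseq[s$atoms$chain == ch])
  R <- 1.48 + cfg$inner_distance
  need_span <- switch(motif, ring_16 = 3L, phosphate_pyramid = 2L,
                      ring_10 = 2L, 1L)
  if (anchor + need_span - 1L > nres || (motif == "ring_16" && anchor < 2))
    stop("chain too short for motif ", motif)
  coord <- list() # (chain, resseq, name) of coordinating atoms
  frag_chain <- "B"

  if (motif %in% c("ring_10", "phosphate_pyramid")) {
    i <- anchor
    pa <- .atom_xyz(s, ch, i, "P"); pb <- .atom_xyz(s, ch, i + 1, "P")
    excl <- c(paste(ch, i, "OP1"), paste(ch, i + 1, "OP1"))
    mg <- .mg_between(s, pa, pb, R, excl)
    if (is.null(mg)) stop("infeasible ring_10 geometry")
    s <- .repoint_op(s, ch, i, mg); s <- .repoint_op(s, ch, i + 1, mg)
    coord <- list(c(ch, i, "OP1"), c(ch, i + 1, "OP1"))
    if (motif == "phosphate_pyramid") {
      d1 <- .unit(.atom_xyz(s, ch, i, "OP1") - mg)
      d2 <- .unit(.atom_xyz(s, ch, i + 1, "OP1") - mg)
      u3 <- .unit(pracma_cross(d1, d2))
      a <- s$atoms; heavy <- !a$is_water & !a$is_ion
      ctr <- c(mean(a$x[heavy]), mean(a$y[heavy]), mean(a$z[heavy]))
      if (sum(u3 * (mg - ctr)) < 0) u3 <- -u3
      s <- .place_fragment(s, mg, u3, "G", "OP1", "P",
                           cfg$inner_distance, frag_chain)
      coord <- c(coord, list(c(frag_chain, 1, "OP1")))
    }
  } else if (motif == "ring_16") {
    i <- anchor
    s <- .hinge_bend(s, ch, i + 1, 6.2)
    pa <- .atom_xyz(s, ch, i, "P"); pb <- .atom_xyz(s, ch, i + 2, "P")
    excl <- c(paste(ch, i, "OP1"), paste(ch, i + 2, "OP1"))
    mg <- .mg_between(s, pa, pb, R, excl)
    if (is.null(mg)) stop("infeasible ring_16 geometry")
    s <- .repoint_op(s, ch, i, mg); s <- .repoint_op(s, ch, i + 2, mg)
    coord <- list(c(ch, i, "OP1"), c(ch, i + 2, "OP1"))
  } else {
    # single-anchor motifs: one coordinating O_ph on the chain; the ion
    # direction is searched on a cone fan around the outward axis for
    # maximal clearance from all non-coordinating O/N atoms
    i <- anchor
    p <- .atom_xyz(s, ch, i, "P")
    a <- s$atoms; heavy <- !a$is_water & !a$is_ion
    ctr <- c(mean(a$x[heavy]), mean(a$y[heavy]), mean(a$z[heavy]))
    u0 <- .unit(p - ctr)
    excl1 <- paste(ch, i, "OP1")
    best_u <- u0; best_cl <- .clearance(s, p + R * u0, excl1)
    perp <- .perp_candidates(u0, c(0, 0, 1), n_cand = 8)
    for (pol in c(20, 40, 60) * pi / 180) for (pc in perp) {
      u <- .unit(cos(pol) * u0 + sin(pol) * pc)
      cl <- .clearance(s, p + R * u, excl1)
      if (cl > best_cl) { best_cl <- cl; best_u <- u }
    }
    u <- best_u
    mg <- p + R * u
    s <- .repoint_op(s, ch, i, mg)
    coord <- list(c(ch, i, "OP1"))
    dirs2 <- .perp_candidates(u, c(0, 0, 1))
    if (motif == "magnesium_clamp" || motif == "y_clamp") {
      s <- .place_fragment(s, mg, dirs2[[1]], "G", "OP1", "P",
                           cfg$inner_distance, frag_chain)
      coord <- c(coord, list(c(frag_chain, 1, "OP1")))
      if (motif == "y_clamp") {
        u3 <- .unit(pracma_cross(u, dirs2[[1]]))
        s <- .place_fragment(s, mg, u3, "C", "O2", "C2",
                             cfg$inner_distance, "C")
        coord <- c(coord, list(c("C", 1, "O2")))
      }
    } else if (motif == "g_phosphate") {
      s <- .place_fragment(s, mg, dirs2[[1]], "G", "O6", "C6",
                           cfg$inner_distance, frag_chain)
      coord <- c(coord, list(c(frag_chain, 1, "O6")))
    } else if (motif == "u_phosphate") {
      s <- .place_fragment(s, mg, dirs2[[1]], "U", "O4", "C4",
                           cfg$inner_distance, frag_chain)
      coord <- c(coord, list(c(frag_chain, 1, "O4")))
    } else if (motif != "single_atom") {
      stop("unknown motif: ", motif)
    }
  }

  if (cfg$add_waters) {
    dirs <- lapply(coord, function(k)
      .unit(.atom_xyz(s, k[1], as.integer(k[2]), k[3]) - mg))
    s <- .add_octahedral_waters(s, mg, dirs, cfg$inner_distance)
  }

  set.seed(seed)
  if (cfg$coordinate_noise > 0) {
    n <- nrow(s$atoms)
    s$atoms$x <- s$atoms$x + rnorm(n, sd = cfg$coordinate_noise)
    s$atoms$y <- s$atoms$y + rnorm(n, sd = cfg$coordinate_noise)
    s$atoms$z <- s$atoms$z + rnorm(n, sd = cfg$coordinate_noise)
  }
  mg <- round(mg, 3)
  s$atoms$x <- round(s$atoms$x, 3)
  s$atoms$y <- round(s$atoms$y, 3)
  s$atoms$z <- round(s$atoms$z, 3)
  mgrow <- .atoms_skeleton("MG", "MG", "Z", 1L, matrix(mg, 1, 3),
                           is_ion = TRUE)
  s$atoms <- rbind(s$atoms, mgrow[, names(s$atoms)])
  s <- .renumber(s)
  s <- assign_attributes(s)
  list(structure = s,
       site = data.frame(x = mg[1], y = mg[2], z = mg[3], label = motif,
                         stringsAsFactors = FALSE))
}

#' Generate a synthetic corpus on disk
#'
#' Writes `n_structures` PDB files with deterministic names
#' (`synth_001.pdb`, ...) plus a `ground_truth.tsv` of planted site
#' coordinates and motif labels. A `decoy_fraction` of the structures
#' carry no site. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [gen_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `files` and the ground-truth data.frame
#'   `truth`.
#' @export
make_corpus <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_structures
  set.seed(cfg$seed)
  sub_seeds <- sample.int(1e6, 2 * n)
  n_decoy <- round(cfg$decoy_fraction * n)
  decoys <- sample.int(n, n_decoy)
  motifs <- sample(names(cfg$motif_mix), n, replace = TRUE,
                   prob = cfg$motif_mix)
  files <- character(n)
  truth <- list()
  for (s in seq_len(n)) {
    chain <- generate_chain(cfg$n_residues, seed = sub_seeds[s])
    fn <- file.path(out_dir, sprintf("synth_%03d.pdb", s))
    if (s %in% decoys) {
      write_structure(chain, fn)
    } else {
      anchor <- 2L
      pl <- plant_site(chain, motifs[s], cfg, seed = sub_seeds[n + s],
                       anchor = anchor)
      write_structure(pl$structure, fn)
      truth[[length(truth) + 1]] <-
        cbind(data.frame(file = basename(fn), stringsAsFactors = FALSE),
              pl$site)
    }
    files[s] <- fn
  }
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(file = character(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), label = character(0))
  write.table(truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(files = files, truth = truth))
}
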