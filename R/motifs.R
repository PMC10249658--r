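# Inner-sphere coordination analysis and geometric motif classification.
#
# An Mg2+ ion typically coordinates six atoms in octahedral geometry;
# here only direct (inner-sphere) contacts with RNA O/N heavy atoms are
# classified, with waters counted separately. The backbone ring size of a
# pair of coordinating phosphate oxygens is the atom count of the minimal
# cycle ion-a1-...(bond graph)...-a2-ion: 10 for consecutive phosphates,
# 16 for phosphates separated by one residue.

#' Inner coordination shell of a site
#'
#' RNA O/N heavy atoms within `inner_cutoff` of the site are the
#' inner-sphere coordinating atoms; waters within the same cutoff are
#' counted separately and never enter `inner_atoms`.
#'
#' @param site a list or one-row data.frame with `x`, `y`, `z`.
#' @param structure an annotated `rna_structure`.
#' @param inner_cutoff inner-sphere cutoff (A), default 2.6 (clears the
#'   ~2.3 A inner-sphere contact peak while excluding the ~4.3 A
#'   water-mediated outer shell).
#' @return a list of class `coordination_shell`: `inner_atoms` (atom
#'   table rows), `n_inner`, `water_count`, `site`, `inner_cutoff`.
#' @export
coordination_shell <- function(site, structure, inner_cutoff = 2.6) {
  stopifnot(inner_cutoff > 0)
  a <- structure$atoms
  d <- sqrt((a$x - site$x)^2 + (a$y - site$y)^2 + (a$z - site$z)^2)
  within <- d <= inner_cutoff
  inner <- within & !a$is_water & !a$is_ion &
    a$element %in% c("O", "N")
  waters <- within & a$is_water & a$element == "O"
  ia <- a[inner, , drop = FALSE]
  ia$distance <- d[inner]
  structure(list(site = site, inner_atoms = ia, n_inner = nrow(ia),
                 water_count = sum(waters), inner_cutoff = inner_cutoff),
            class = "coordination_shell")
}

#' Backbone ring size bridged by an ion
#'
#' The atom count (ion included) of the minimal cycle formed by the ion
#' bonded to two coordinating atoms `a1` and `a2`: the shortest bond-graph
#' path a1...a2 plus the ion closing the cycle.
#'
#' @param graph bond graph from [build_bond_graph()].
#' @param serial1,serial2 serials of the two coordinating atoms (distinct).
#' @return integer ring size, or `NA` if the two atoms are disconnected
#'   in the bond graph.
#' @export
ring_size <- function(graph, serial1, serial2) {
  if (serial1 == serial2) stop("ring_size needs two distinct atoms")
  v1 <- as.character(serial1); v2 <- as.character(serial2)
  if (!all(c(v1, v2) %in% igraph::V(graph)$name))
    stop("atom serial not in bond graph")
  d <- igraph::distances(graph, v1, v2)[1, 1]
  if (!is.finite(d)) return(NA_integer_)
  as.integer(d + 2L) # path atoms = d + 1, plus the ion
}

#' Classify a coordination shell into a named binding motif
#'
#' Rules are applied in priority order so every shell gets exactly one
#' label: phosphate pyramid (three or more phosphate oxygens from
#' distinct phosphate groups, one pair forming a 10- or 16-member ring),
#' 16-member ring, 10-member ring, magnesium clamp (a phosphate-oxygen
#' pair bridging juxtaposed strands or distant segments, i.e. with no
#' backbone ring of 16 or fewer atoms), Y-clamp (such a pair plus an
#' inner pyrimidine base oxygen), G-phosphate / U-phosphate (one
#' phosphate oxygen plus a base oxygen of G / U), single-atom sites, and
#' `unclassified` otherwise.
#'
#' @param shell a `coordination_shell`.
#' @param graph bond graph of the same structure.
#' @param structure the annotated `rna_structure` (to locate each O_ph
#'   atom's parent phosphorus).
#' @return a list of class `motif_assignment`: `label`, `evidence`
#'   (coordinating atoms, ring sizes), `n_inner`.
#' @export
classify_motif <- function(shell, graph, structure) {
  ia <- shell$inner_atoms
  lab <- "unclassified"
  rings <- data.frame(serial1 = integer(0), serial2 = integer(0),
                      size = integer(0))
  oph <- ia[ia$atom_class == "O_ph", , drop = FALSE]
  # group phosphate oxygens by their parent phosphorus (same residue)
  if (nrow(oph)) {
    a <- structure$atoms
    pidx <- match(paste(oph$chain, oph$resseq, "P"),
                  paste(a$chain, a$resseq, a$name))
    oph$p_serial <- a$serial[pidx]
  }
  n_groups <- if (nrow(oph)) length(unique(oph$p_serial)) else 0L
  # ring sizes over O_ph pairs from distinct phosphate groups
  if (nrow(oph) >= 2) {
    cmb <- utils::combn(seq_len(nrow(oph)), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (identical(oph$p_serial[i], oph$p_serial[j])) next
      rs <- ring_size(graph, oph$serial[i], oph$serial[j])
      rings <- rbind(rings, data.frame(serial1 = oph$serial[i],
                                       serial2 = oph$serial[j],
                                       size = rs))
    }
  }
  has_ring <- function(sz) nrow(rings) && any(!is.na(rings$size) &
                                                rings$size %in% sz)
  no_short_ring <- nrow(rings) && all(is.na(rings$size) | rings$size > 16)
  has_pyr_ob <- any(ia$atom_class == "O_b_pyrimidine")
  ob_res <- ia$resname[ia$atom_class %in% c("O_b_purine",
                                            "O_b_pyrimidine")]
  if (shell$n_inner == 1) {
    lab <- "single_atom"
  } else if (n_groups >= 3 && has_ring(c(10, 16))) {
    lab <- "phosphate_pyramid"
  } else if (has_ring(16)) {
    lab <- "ring_16"
  } else if (has_ring(10)) {
    lab <- "ring_10"
  } else if (n_groups >= 2 && no_short_ring && !has_pyr_ob) {
    lab <- "magnesium_clamp"
  } else if (n_groups >= 2 && no_short_ring && has_pyr_ob) {
    lab <- "y_clamp"
  } else if (nrow(oph) == 1 && "G" %in% ob_res) {
    lab <- "g_phosphate"
  } else if (nrow(oph) == 1 && "U" %in% ob_res) {
    lab <- "u_phosphate"
  }
  structure(list(site = shell$site, label = lab, n_inner = shell$n_inner,
                 evidence = list(inner_atoms = ia, rings = rings)),
            class = "motif_assignment")
}

#' Relative motif abundance
#'
#' Percentages are taken over the sites with at least one inner-sphere
#' coordinating RNA atom (the denominator used for reporting motif
#' abundance); sites with `n_inner = 0` are excluded.
#'
#' @param assignments list of `motif_assignment` objects.
#' @return a data.frame with `label`, `count`, `percent`.
#' @export
motif_abundance <- function(assignments) {
  if (!length(assignments))
    return(data.frame(label = character(0), count = integer(0),
                      percent = numeric(0)))
  inner <- Filter(function(a) a$n_inner >= 1, assignments)
  denom <- length(inner)
  labs <- vapply(inner, function(a) a$label, "")
  tab <- table(labs)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    percent = if (denom) 100 * as.integer(tab) / denom
                    else numeric(length(tab)))
  out[order(-out$count), , drop = FALSE]
}

#' Classify every site of a structure
#'
#' Convenience wrapper: builds the bond graph once, computes each site's
#' coordination shell and motif assignment.
#'
#' @param sites site table (`x`, `y`, `z`).
#' @param structure annotated `rna_structure`.
#' @param inner_cutoff inner-sphere cutoff (A).
#' @return list of `motif_assignment`.
#' @export
classify_sites <- function(sites, structure, inner_cutoff = 2.6) {
  g <- build_bond_graph(structure)
  lapply(seq_len(nrow(sites)), function(i) {
    sh <- coordination_shell(sites[i, ], structure, inner_cutoff)
    classify_motif(sh, g, structure)
  })
}
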