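# Reading, writing and annotating RNA-containing structures.
#
# A structure is held as an S3 object of class "rna_structure": a list with
#   atoms      data.frame (one row per heavy atom, see read_structure)
#   resolution numeric (Angstrom) or NA when the file carries no REMARK 2
#   source_id  character label (file stem by default)
# The covalent bond graph is built on demand by build_bond_graph().

#' Parse an RNA-containing structure file
#'
#' Reads a PDB (or mmCIF) file into an `rna_structure` object. Only the
#' first MODEL is used; for atoms present in several alternate locations
#' only the first variant encountered is kept. Waters and monoatomic ions
#' are parsed and flagged (`is_water`, `is_ion`) but never dropped.
#' Residues that are neither standard ribonucleotides, amino acids, DNA
#' nucleotides, waters nor ions (e.g. modified nucleotides) are skipped
#' with a warning unless `keep_nonstandard = TRUE`.
#'
#' @param path path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param keep_nonstandard keep residues with unrecognised residue codes.
#' @return an object of class `rna_structure`.
#' @export
read_structure <- function(path, keep_nonstandard = FALSE) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                           rm.insert = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  # heavy atoms only
  el <- trimws(at$elesy)
  el[is.na(el) | el == ""] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[is.na(el) | el == ""])), 1, 1)
  keep <- toupper(el) != "H" & toupper(el) != "D"
  at <- at[keep, , drop = FALSE]
  el <- toupper(el[keep])

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = el,
    stringsAsFactors = FALSE)

  # first alternate-location variant per (chain, residue, atom name)
  key <- paste(atoms$chain, atoms$resseq, atoms$resname, atoms$name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]

  atoms$is_water <- atoms$resname %in% .water_names
  atoms$is_ion <- atoms$resname %in% .ion_names & !atoms$is_water
  known <- atoms$resname %in% c(.std_nt, .amino3, .dna_nt) |
    atoms$is_water | atoms$is_ion
  if (any(!known) && !keep_nonstandard) {
    skipped <- unique(atoms$resname[!known])
    warning("skipping non-standard residue(s): ",
            paste(skipped, collapse = ", "),
            " (use keep_nonstandard = TRUE to retain)", call. = FALSE)
    atoms <- atoms[known, , drop = FALSE]
  }
  atoms$is_rna <- atoms$resname %in% .std_nt
  if (keep_nonstandard) {
    # a retained unknown residue counts as an RNA nucleotide if it has a ribose
    known2 <- atoms$resname %in% c(.std_nt, .amino3, .dna_nt) |
      atoms$is_water | atoms$is_ion
    rkey <- paste(atoms$chain, atoms$resseq)
    for (u in unique(rkey[!known2])) {
      sel <- rkey == u
      if (any(atoms$name[sel] == "C1'")) atoms$is_rna[sel] <- TRUE
    }
  }
  if (sum(atoms$is_rna) == 0)
    stop("no RNA residues found in ", path, call. = FALSE)
  rownames(atoms) <- NULL

  res <- .parse_resolution(path, is_cif)
  structure(list(atoms = atoms, resolution = res,
                 source_id = sub("\\.(pdb|cif)$", "", basename(path),
                                 ignore.case = TRUE)),
            class = "rna_structure")
}

.parse_resolution <- function(path, is_cif = FALSE) {
  ln <- tryCatch(readLines(path, n = 2000, warn = FALSE),
                 error = function(e) character())
  if (is_cif) {
    hit <- grep("_reflns\\.d_resolution_high|_refine\\.ls_d_res_high", ln,
                value = TRUE)
    if (length(hit)) {
      v <- suppressWarnings(as.numeric(sub(".*\\s", "", hit[1])))
      return(if (is.na(v)) NA_real_ else v)
    }
    return(NA_real_)
  }
  hit <- grep("^REMARK   2 RESOLUTION\\.", ln, value = TRUE)
  if (!length(hit)) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)",
                                  hit[1], perl = TRUE))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' @export
print.rna_structure <- function(x, ...) {
  a <- x$atoms
  nres <- length(unique(paste(a$chain, a$resseq)[a$is_rna]))
  cat("rna_structure '", x$source_id, "': ", nrow(a), " atoms, ",
      nres, " RNA residues, ", sum(a$is_ion & a$element == "MG"),
      " bound Mg ion(s)", sep = "")
  if (!is.na(x$resolution)) cat(", resolution ", x$resolution, " A", sep = "")
  cat("\n")
  invisible(x)
}

#' Experimentally bound Mg ions of a structure
#'
#' @param structure an `rna_structure`.
#' @param elements ion element symbols to report (default `"MG"`).
#' @return a site table (data.frame with x, y, z, provenance).
#' @export
bound_ions <- function(structure, elements = "MG") {
  a <- structure$atoms
  sel <- a$is_ion & a$element %in% elements
  out <- data.frame(x = a$x[sel], y = a$y[sel], z = a$z[sel],
                    provenance = rep("experimental", sum(sel)),
                    stringsAsFactors = FALSE)
  out
}

#' Write a structure back to PDB
#'
#' @param structure an `rna_structure`.
#' @param path output file path.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  type <- ifelse(a$is_water | a$is_ion, "HETATM", "ATOM")
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = type, resno = a$resseq, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   o = rep(1, n), b = rep(0, n), elesy = a$element)
  if (!is.na(structure$resolution)) {
    ln <- readLines(path, warn = FALSE)
    rem <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                   structure$resolution)
    writeLines(c(rem, ln), path)
  }
  invisible(path)
}

#' Load the shipped partial-charge / van-der-Waals table
#'
#' The package ships an AMBER-style per-atom table for the four standard
#' ribonucleotides in which hydrogen charges have been folded into their
#' parent heavy atoms, so each standard nucleotide (with both phosphate
#' oxygens) carries a net charge of -1 e.
#'
#' @param path optional path to a custom TSV with columns
#'   `resname`, `atom`, `charge`, `vdw_radius`.
#' @return a data.frame of class `charge_table`.
#' @export
default_charge_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charges.tsv", package = "voxmg")
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("resname", "atom", "charge", "vdw_radius") %in% names(tab)))
  class(tab) <- c("charge_table", class(tab))
  tab
}

#' Assign partial charges, vdW radii and atom classes
#'
#' Every atom receives `charge`, `vdw` and `atom_class` columns. Atoms
#' absent from the table fall back to the default entry (charge 0,
#' radius 1.5 A); for RNA atoms this is reported with a warning.
#'
#' @param structure an `rna_structure`.
#' @param table a `charge_table` (default: the shipped table).
#' @return the annotated `rna_structure`.
#' @export
assign_attributes <- function(structure, table = default_charge_table()) {
  a <- structure$atoms
  idx <- match(paste(a$resname, a$name), paste(table$resname, table$atom))
  a$charge <- table$charge[idx]
  a$vdw <- table$vdw_radius[idx]
  miss <- is.na(idx)
  if (any(miss & a$is_rna)) {
    warning("default attributes (charge 0, radius 1.5 A) for ",
            sum(miss & a$is_rna), " RNA atom(s): ",
            paste(unique(paste(a$resname, a$name)[miss & a$is_rna])[1:min(5,
              length(unique(paste(a$resname, a$name)[miss & a$is_rna])))],
              collapse = ", "), call. = FALSE)
  }
  a$charge[miss] <- 0
  a$vdw[miss] <- 1.5
  a$atom_class <- classify_atom(a$name, a$resname)
  structure$atoms <- a
  structure
}

#' Classify an atom into the six-type coordination scheme
#'
#' Atom classes follow the six-type scheme used throughout the package:
#' `O_ph` phosphate oxygens (OP1/OP2), `O_r` ribose and bridging oxygens
#' (O2'/O4'/O3'/O5'), nucleobase oxygens and nitrogens split by purine
#' (A, G) versus pyrimidine (C, U), and `other` for everything else.
#'
#' @param name atom name(s), PDB convention.
#' @param resname residue code(s) of the atom(s).
#' @return character vector of class labels.
#' @export
classify_atom <- function(name, resname) {
  n <- max(length(name), length(resname))
  name <- rep_len(name, n); resname <- rep_len(resname, n)
  out <- rep("other", n)
  is_nt <- resname %in% .std_nt
  pur <- resname %in% c("A", "G")
  pyr <- resname %in% c("C", "U")
  out[is_nt & name %in% c("OP1", "OP2")] <- "O_ph"
  out[is_nt & name %in% c("O2'", "O4'", "O3'", "O5'")] <- "O_r"
  base_o <- is_nt & name %in% c("O2", "O4", "O6")
  base_n <- is_nt & name %in% c("N1", "N2", "N3", "N4", "N6", "N7", "N9")
  out[base_o & pur] <- "O_b_purine"
  out[base_o & pyr] <- "O_b_pyrimidine"
  out[base_n & pur] <- "N_b_purine"
  out[base_n & pyr] <- "N_b_pyrimidine"
  out
}

# intra-residue covalent bond templates (heavy atoms)
.bb_bonds <- list(c("P", "OP1"), c("P", "OP2"), c("P", "O5'"),
  c("O5'", "C5'"), c("C5'", "C4'"), c("C4'", "O4'"), c("C4'", "C3'"),
  c("C3'", "O3'"), c("C3'", "C2'"), c("C2'", "O2'"), c("C2'", "C1'"),
  c("C1'", "O4'"))
.base_bonds <- list(
  A = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "N6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N3"), c("N3", "C4"), c("C4", "C5"), c("C4", "N9")),
  G = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "O6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
           c("C4", "N9")),
  C = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "N4"), c("C4", "C5"), c("C5", "C6"),
           c("C6", "N1")),
  U = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "O4"), c("C4", "C5"), c("C5", "C6"),
           c("C6", "N1")))

#' Build the covalent bond graph of a structure
#'
#' Intra-residue bonds come from the standard ribonucleotide template;
#' consecutive residues are joined by an O3'(i)-P(i+1) bond whenever the
#' two atoms are within `link_cutoff` (default 2.25 A, the 1.8 A P-O bond
#' sanity bound with a 1.25 tolerance factor, so that coordinate noise at
#' the scale of crystallographic uncertainty does not sever backbones). A
#' larger gap is a chain break and leaves the residues disconnected. Waters and ions are
#' excluded from the graph. Residues without a template (protein, DNA,
#' retained non-standard residues) fall back to distance-based
#' intra-residue bonds (< 1.85 A).
#'
#' @param structure an `rna_structure`.
#' @param link_cutoff maximum O3'-P distance for an inter-residue bond (A).
#' @return an `igraph` whose vertex names are atom serials.
#' @export
build_bond_graph <- function(structure, link_cutoff = 2.25) {
  a <- structure$atoms
  a <- a[!a$is_water & !a$is_ion, , drop = FALSE]
  vs <- as.character(a$serial)
  edges <- character(0)
  rkey <- paste(a$chain, a$resseq)
  for (rk in unique(rkey)) {
    sel <- which(rkey == rk)
    res <- a$resname[sel[1]]
    nm <- a$name[sel]
    if (res %in% .std_nt) {
      bonds <- c(.bb_bonds, .base_bonds[[res]])
      for (b in bonds) {
        i <- sel[match(b[1], nm)]; j <- sel[match(b[2], nm)]
        if (!is.na(i) && !is.na(j))
          edges <- c(edges, as.character(a$serial[i]), as.character(a$serial[j]))
      }
    } else if (length(sel) > 1) {
      xyz <- as.matrix(a[sel, c("x", "y", "z")])
      d <- as.matrix(dist(xyz))
      pr <- which(d < 1.85 & upper.tri(d), arr.ind = TRUE)
      if (nrow(pr))
        edges <- c(edges, rbind(as.character(a$serial[sel[pr[, 1]]]),
                                as.character(a$serial[sel[pr[, 2]]])))
    }
  }
  # inter-residue O3'(i) -- P(i+1) links
  o3 <- a[a$name == "O3'", , drop = FALSE]
  p <- a[a$name == "P", , drop = FALSE]
  if (nrow(o3) && nrow(p)) {
    for (i in seq_len(nrow(o3))) {
      cand <- p[p$chain == o3$chain[i] & p$resseq == o3$resseq[i] + 1, ,
                drop = FALSE]
      if (nrow(cand)) {
        d <- sqrt((cand$x[1] - o3$x[i])^2 + (cand$y[1] - o3$y[i])^2 +
                    (cand$z[1] - o3$z[i])^2)
        if (d <= link_cutoff)
          edges <- c(edges, as.character(o3$serial[i]),
                     as.character(cand$serial[1]))
        else
          message("chain break at ", o3$chain[i], ":", o3$resseq[i],
                  " (O3'-P distance ", round(d, 2), " A)")
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vs), name = vs)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Filter structure records by crystallographic resolution
#'
#' Keeps records whose resolution is 3.0 A or better; records without a
#' reported resolution are dropped.
#'
#' @param records a data.frame with (at least) a `resolution` column.
#' @param max_resolution cutoff in Angstrom (default 3.0).
#' @return the kept subset of `records`.
#' @export
curate <- function(records, max_resolution = 3.0) {
  if (!nrow(records)) return(records)
  keep <- !is.na(records$resolution) & records$resolution <= max_resolution
  records[keep, , drop = FALSE]
}

# residue keys in deterministic order (chain, then residue number)
residue_keys <- function(structure, rna_only = TRUE) {
  a <- structure$atoms
  if (rna_only) a <- a[a$is_rna, , drop = FALSE]
  u <- unique(a[, c("chain", "resseq")])
  u <- u[order(u$chain, u$resseq), , drop = FALSE]
  rownames(u) <- NULL
  u
}
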