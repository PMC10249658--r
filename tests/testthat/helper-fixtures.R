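# Fixtures are built in code: tiny handwritten PDB records for parser
# edge cases, bare structures for geometry units, and small random images
# for network tests.

pdb_atom_line <- function(serial, name, alt, resname, chain, resseq,
                          xyz, element, het = FALSE) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, resname, chain,
          resseq, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

# one guanosine from the shipped template, written as a PDB file
write_guanosine_pdb <- function(path, extra_lines = character(0)) {
  tt <- voxmg:::.nt_templates()
  tt <- tt[tt$resname == "G", ]
  ln <- vapply(seq_len(nrow(tt)), function(i)
    pdb_atom_line(i, tt$atom[i], "", "G", "A", 1,
                  c(tt$x[i], tt$y[i], tt$z[i]),
                  substr(tt$atom[i], 1, 1)), "")
  writeLines(c(ln, extra_lines, "END"), path)
  path
}

# bare annotated structure from an atom spec data.frame with columns
# name, resname, chain, resseq, x, y, z (waters/ions inferred)
toy_structure <- function(df) {
  df$serial <- seq_len(nrow(df))
  df$altloc <- ""
  df$element <- toupper(substr(gsub("[^A-Za-z].*", "", df$name), 1, 1))
  df$element[df$name == "MG"] <- "MG"
  df$is_water <- df$resname %in% "HOH"
  df$is_ion <- df$resname %in% "MG"
  df$is_rna <- !df$is_water & !df$is_ion
  s <- structure(list(atoms = df, resolution = NA_real_,
                      source_id = "toy"), class = "rna_structure")
  assign_attributes(s)
}

# random two-channel image of side n on a unit lattice at the origin
random_image <- function(n = 8, seed = 1) {
  set.seed(seed)
  structure(list(origin = c(0, 0, 0), edge = n, spacing = 1, n = n,
                 occupancy = array(runif(n^3), c(n, n, n)),
                 charge = array(rnorm(n^3, sd = 0.3), c(n, n, n)),
                 center = rep(n / 2, 3),
                 center_residue = list(chain = "A", resseq = 1)),
            class = "voxel_image")
}

# probability grid with given values on the image geometry
grid_like <- function(image, values) {
  structure(list(origin = image$origin, spacing = image$spacing,
                 n = image$n, values = array(values,
                                             rep(image$n, 3))),
            class = "probability_grid")
}

# a Gaussian blob field on an integer lattice, as an ion_field
blob_field <- function(center, peak = 0.9, sigma = 1.5, lo = -8, hi = 8,
                       spacing = 1) {
  g <- expand.grid(x = seq(lo, hi, by = spacing),
                   y = seq(lo, hi, by = spacing),
                   z = seq(lo, hi, by = spacing))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g$p <- peak * exp(-d2 / (2 * sigma^2))
  g$n_boxes <- 1L
  class(g) <- c("ion_field", class(g))
  attr(g, "spacing") <- spacing
  g
}

merge_fields <- function(a, b) {
  # union of two disjoint-support fields on the same lattice (max merge)
  key_a <- paste(a$x, a$y, a$z)
  key_b <- paste(b$x, b$y, b$z)
  stopifnot(identical(key_a, key_b))
  a$p <- pmax(a$p, b$p)
  a
}

# brute-force maximum bipartite matching cardinality under a cutoff
bf_max_matching <- function(pred, truth, cutoff) {
  np <- nrow(pred); nt <- nrow(truth)
  D <- matrix(Inf, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt))
    D[i, j] <- sqrt(sum((as.numeric(pred[i, c("x", "y", "z")]) -
                           as.numeric(truth[j, c("x", "y", "z")]))^2))
  ok <- D <= cutoff
  best <- 0L
  rec <- function(i, used) {
    if (i > np) return(0L)
    most <- rec(i + 1L, used)
    for (j in seq_len(nt)) {
      if (ok[i, j] && !(j %in% used))
        most <- max(most, 1L + rec(i + 1L, c(used, j)))
    }
    most
  }
  rec(1L, integer(0))
}
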