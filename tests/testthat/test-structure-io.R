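test_that("only the first MODEL and first altloc variant are parsed", {
  tt <- voxmg:::.nt_templates()
  tg <- tt[tt$resname == "G", ]
  line <- function(i, alt, shift)
    pdb_atom_line(i, tg$atom[i], alt, "G", "A", 1,
                  c(tg$x[i] + shift, tg$y[i], tg$z[i]),
                  substr(tg$atom[i], 1, 1))
  body1 <- vapply(seq_len(nrow(tg)), line, "", alt = "", shift = 0)
  body2 <- vapply(seq_len(nrow(tg)), line, "", alt = "", shift = 50)
  # altloc B duplicate of O2' inside model 1
  i_o2 <- which(tg$atom == "O2'")
  altb <- pdb_atom_line(99, "O2'", "B", "G", "A", 1,
                        c(tg$x[i_o2] + 9, tg$y[i_o2], tg$z[i_o2]), "O")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", body1[seq_len(i_o2)], altb,
               body1[-seq_len(i_o2)], "ENDMDL",
               "MODEL     2", body2, "ENDMDL", "END"), f)
  s <- read_structure(f)
  a <- s$atoms
  expect_equal(nrow(a), 23) # first model only, one O2'
  o2 <- a[a$name == "O2'", ]
  expect_equal(nrow(o2), 1)
  # first variant (the unshifted altloc "" record appears first)
  expect_equal(o2$x, tg$x[i_o2], tolerance = 1e-3)
})

test_that("a single guanosine has 23 heavy atoms and hydrogens are dropped", {
  f <- tempfile(fileext = ".pdb")
  extra <- pdb_atom_line(90, "H21", "", "G", "A", 1, c(0, 0, 0), "H")
  write_guanosine_pdb(f, extra_lines = extra)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 23)
  expect_equal(length(unique(paste(s$atoms$chain, s$atoms$resseq))), 1)
  expect_false(any(s$atoms$element == "H"))
})

test_that("non-standard residues are skipped unless kept", {
  f <- tempfile(fileext = ".pdb")
  extra <- c(pdb_atom_line(50, "XX", "", "UNK", "B", 1, c(30, 0, 0), "X"))
  write_guanosine_pdb(f, extra_lines = extra)
  expect_warning(s <- read_structure(f), "non-standard")
  expect_false("UNK" %in% s$atoms$resname)
  s2 <- suppressWarnings(read_structure(f, keep_nonstandard = TRUE))
  expect_true("UNK" %in% s2$atoms$resname)
  s2 <- assign_attributes(s2)
  unk <- s2$atoms[s2$atoms$resname == "UNK", ]
  expect_equal(unk$charge, 0)
  expect_equal(unk$vdw, 1.5)
  expect_equal(unk$atom_class, "other")
})

test_that("per-nucleotide charges sum to about -1 e and OP1 is negative", {
  s <- assign_attributes(generate_chain(8, seed = 5))
  a <- s$atoms
  sums <- tapply(a$charge, a$resseq, sum)
  expect_true(all(sums > -1.2 & sums < -0.8))
  expect_true(all(a$charge[a$name == "OP1"] < 0))
  expect_true(all(a$vdw > 0))
})

test_that("atom classification is total, deterministic and six-typed", {
  expect_equal(classify_atom("OP2", "G"), "O_ph")
  expect_equal(classify_atom("O4'", "U"), "O_r")
  expect_equal(classify_atom("O3'", "A"), "O_r")
  expect_equal(classify_atom("N7", "A"), "N_b_purine")
  expect_equal(classify_atom("C1'", "A"), "other")
  expect_equal(classify_atom("O2", "C"), "O_b_pyrimidine")
  expect_equal(classify_atom("O6", "G"), "O_b_purine")
  expect_equal(classify_atom("N3", "U"), "N_b_pyrimidine")
  # over all template atoms exactly six non-"other" classes occur
  tt <- voxmg:::.nt_templates()
  cls <- classify_atom(tt$atom, tt$resname)
  expect_setequal(setdiff(unique(cls), "other"),
                  c("O_ph", "O_r", "O_b_purine", "O_b_pyrimidine",
                    "N_b_purine", "N_b_pyrimidine"))
})

test_that("bond graph has template connectivity and chain breaks split it", {
  s <- assign_attributes(generate_chain(2, seed = 1))
  g <- build_bond_graph(s)
  a <- s$atoms
  # exactly one inter-residue O3'-P bond
  o3 <- as.character(a$serial[a$resseq == 1 & a$name == "O3'"])
  p2 <- as.character(a$serial[a$resseq == 2 & a$name == "P"])
  expect_true(igraph::are_adjacent(g, o3, p2))
  inter <- sum(apply(igraph::as_edgelist(g), 1, function(e) {
    r <- a$resseq[match(as.integer(e), a$serial)]
    r[1] != r[2]
  }))
  expect_equal(inter, 1)
  # P is bonded to OP1, OP2, O5'
  p1 <- as.character(a$serial[a$resseq == 1 & a$name == "P"])
  nb <- igraph::neighbors(g, p1)$name
  nbn <- a$name[match(as.integer(nb), a$serial)]
  expect_setequal(nbn, c("OP1", "OP2", "O5'"))
  # connected single chain with edges = atoms - 1 + rings
  expect_equal(igraph::components(g)$no, 1)
  ring_count <- sum(ifelse(unique(a[, c("resseq", "resname")])$resname
                           %in% c("A", "G"), 3, 2))
  expect_equal(igraph::ecount(g),
               nrow(a) - 1 + ring_count)
  # two far-apart chains give two components
  s2 <- s
  b <- assign_attributes(generate_chain(2, seed = 2, chain = "B"))$atoms
  b$x <- b$x + 100
  b$serial <- b$serial + max(a$serial)
  s2$atoms <- rbind(s2$atoms, b)
  expect_equal(igraph::components(build_bond_graph(s2))$no, 2)
})

test_that("curation keeps structures at 3 A or better and drops the rest", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    resolution = c(2.5, 3.0, 3.5, NA))
  kept <- curate(rec)
  expect_setequal(kept$id, c("a", "b"))
  expect_equal(nrow(curate(rec[0, ])), 0)
})

test_that("write/read round trip preserves names, residues and coordinates", {
  pl <- plant_site(generate_chain(4, seed = 9), "ring_10",
                   gen_config(coordinate_noise = 0), seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_structure(pl$structure, f)
  s2 <- read_structure(f)
  a1 <- pl$structure$atoms; a2 <- s2$atoms
  expect_equal(a1$name, a2$name)
  expect_equal(a1$resseq, a2$resseq)
  expect_equal(as.matrix(a1[, c("x", "y", "z")]),
               as.matrix(a2[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(s2$resolution, 2.0)
  expect_equal(nrow(bound_ions(s2)), 1)
})
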