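test_that("the coordination shell separates RNA atoms from waters by distance", {
  df <- data.frame(name = c("OP1", "OP2", "O"),
                   resname = c("G", "G", "HOH"),
                   chain = c("A", "A", "W"), resseq = c(1, 1, 1),
                   x = c(2.1, 3.5, 2.0), y = 0, z = 0)
  s <- toy_structure(df)
  sh <- coordination_shell(data.frame(x = 0, y = 0, z = 0), s)
  expect_equal(sh$n_inner, 1)
  expect_equal(sh$inner_atoms$name, "OP1")
  expect_equal(sh$water_count, 1)
})

test_that("ring sizes agree with exhaustive simple-path enumeration", {
  s <- assign_attributes(generate_chain(4, seed = 13))
  g <- build_bond_graph(s)
  a <- s$atoms
  serial_of <- function(r, nm) a$serial[a$resseq == r & a$name == nm]
  # independent oracle: depth-limited DFS over all simple paths
  adj <- lapply(igraph::V(g)$name, function(v)
    igraph::neighbors(g, v)$name)
  names(adj) <- igraph::V(g)$name
  shortest_path_len <- function(v1, v2, maxlen = 18) {
    best <- Inf
    dfs <- function(v, target, seen, len) {
      if (len >= best || len > maxlen) return()
      if (v == target) { best <<- min(best, len); return() }
      for (w in adj[[v]]) if (!(w %in% seen))
        dfs(w, target, c(seen, w), len + 1)
    }
    dfs(v1, v2, v1, 0)
    best
  }
  cases <- list(c(1, "OP1", 2, "OP1"), c(1, "OP1", 3, "OP1"),
                c(1, "OP1", 1, "OP2"), c(2, "OP2", 3, "OP1"))
  for (cs in cases) {
    s1 <- serial_of(as.integer(cs[1]), cs[2])
    s2 <- serial_of(as.integer(cs[3]), cs[4])
    oracle <- shortest_path_len(as.character(s1), as.character(s2)) + 2
    expect_equal(ring_size(g, s1, s2), oracle)
  }
  expect_equal(ring_size(g, serial_of(1, "OP1"), serial_of(2, "OP1")), 10)
  expect_equal(ring_size(g, serial_of(1, "OP1"), serial_of(3, "OP1")), 16)
  expect_equal(ring_size(g, serial_of(1, "OP1"), serial_of(1, "OP2")), 4)
  expect_error(ring_size(g, serial_of(1, "OP1"), serial_of(1, "OP1")),
               "distinct")
})

test_that("disconnected coordinating atoms have no ring", {
  s <- assign_attributes(generate_chain(2, seed = 3))
  b <- assign_attributes(generate_chain(2, seed = 4, chain = "B"))$atoms
  b$x <- b$x + 40
  b$serial <- b$serial + max(s$atoms$serial)
  s$atoms <- rbind(s$atoms, b)
  g <- build_bond_graph(s)
  a <- s$atoms
  sA <- a$serial[a$chain == "A" & a$resseq == 1 & a$name == "OP1"]
  sB <- a$serial[a$chain == "B" & a$resseq == 1 & a$name == "OP1"]
  expect_true(is.na(ring_size(g, sA, sB)))
})

test_that("every planted motif is recovered by the classifier (clean geometry)", {
  cfg <- gen_config(coordinate_noise = 0)
  for (m in names(cfg$motif_mix)) {
    pl <- plant_site(generate_chain(6, seed = 17), m, cfg, seed = 2)
    asg <- classify_sites(pl$site, pl$structure)[[1]]
    expect_equal(asg$label, m)
    sh <- coordination_shell(pl$site, pl$structure)
    min_inner <- switch(m, phosphate_pyramid = 3, y_clamp = 3,
                        single_atom = 1, 2)
    expect_gte(sh$n_inner, min_inner)
  }
})

test_that("classification priority resolves overlapping evidence", {
  # a pyramid also contains a ring; the pyramid label wins
  cfg <- gen_config(coordinate_noise = 0)
  pl <- plant_site(generate_chain(6, seed = 21), "phosphate_pyramid", cfg,
                   seed = 2)
  asg <- classify_sites(pl$site, pl$structure)[[1]]
  expect_equal(asg$label, "phosphate_pyramid")
  expect_true(any(asg$evidence$rings$size %in% c(10, 16)))
  # exactly one inner atom is always single_atom
  pl2 <- plant_site(generate_chain(6, seed = 21), "single_atom", cfg,
                    seed = 2)
  sh2 <- coordination_shell(pl2$site, pl2$structure)
  expect_equal(sh2$n_inner, 1)
  g2 <- build_bond_graph(pl2$structure)
  expect_equal(classify_motif(sh2, g2, pl2$structure)$label, "single_atom")
})

test_that("motif abundance uses inner-sphere sites as the denominator", {
  mk <- function(label, n_inner)
    structure(list(label = label, n_inner = n_inner),
              class = "motif_assignment")
  asg <- list(mk("ring_10", 2), mk("ring_10", 2), mk("magnesium_clamp", 2),
              mk("single_atom", 1), mk("unclassified", 0))
  ab <- motif_abundance(asg)
  expect_equal(ab$percent[ab$label == "ring_10"], 50)
  expect_equal(sum(ab$count), 4) # the n_inner = 0 site is excluded
  expect_lte(sum(ab$percent), 100 + 1e-9)
  one <- motif_abundance(list(mk("ring_16", 2)))
  expect_equal(one$percent, 100)
  expect_equal(nrow(motif_abundance(list())), 0)
})
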