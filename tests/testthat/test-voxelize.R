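test_that("residue centre is the heavy-atom centroid and equivariant", {
  df <- data.frame(name = c("P", "OP1"), resname = "G", chain = "A",
                   resseq = 1, x = c(0, 2), y = 0, z = 0)
  s <- toy_structure(df)
  expect_equal(residue_center(s, "A", 1), c(1, 0, 0))
  df1 <- df[1, ]; df1$x <- 1; df1$y <- 2; df1$z <- 3
  expect_equal(residue_center(toy_structure(df1), "A", 1), c(1, 2, 3))
  s2 <- assign_attributes(generate_chain(2, seed = 4))
  c0 <- residue_center(s2, "A", 1)
  s2$atoms$x <- s2$atoms$x + 5; s2$atoms$y <- s2$atoms$y + 5
  s2$atoms$z <- s2$atoms$z + 5
  expect_equal(residue_center(s2, "A", 1), c0 + 5)
  expect_error(residue_center(s2, "A", 99), "not found")
})

test_that("occupancy kernel has the right closed form, limits and monotonicity", {
  expect_equal(occupancy_value(1.52, 1.52), 1 - exp(-1))
  expect_equal(occupancy_value(0, 1.52), 1)
  expect_lt(occupancy_value(15.2, 1.52), 1e-12)
  # strict decrease checked where the kernel is not saturated at 1 in
  # double precision (below ~1.3 A the value is exactly 1.0)
  d <- seq(1.4, 8, by = 0.05)
  v <- occupancy_value(d, 1.7)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(occupancy_value(seq(0.1, 8, 0.05), 1.7)) <= 0))
})

test_that("voxelization matches a brute-force per-voxel loop", {
  df <- data.frame(name = c("OP1", "N7", "C1'"), resname = "G",
                   chain = "A", resseq = 1,
                   x = c(0.3, 1.2, -0.8), y = c(-0.5, 0.9, 0.2),
                   z = c(0.1, -1.1, 0.7))
  s <- toy_structure(df)
  cfg <- grid_config(edge = 6, spacing = 1)
  img <- make_image(s, "A", 1, cfg)
  ctr <- residue_center(s, "A", 1)
  origin <- ctr - 3
  n <- 6
  occ <- array(0, c(n, n, n)); chg <- array(0, c(n, n, n))
  sg <- cfg$sigma_charge * cfg$spacing
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    v <- origin + (c(i, j, k) - 0.5) * cfg$spacing
    for (t in seq_len(nrow(s$atoms))) {
      d <- sqrt(sum((v - c(s$atoms$x[t], s$atoms$y[t], s$atoms$z[t]))^2))
      occ[i, j, k] <- max(occ[i, j, k], occupancy_value(d, s$atoms$vdw[t]))
      chg[i, j, k] <- chg[i, j, k] +
        s$atoms$charge[t] * exp(-d^2 / (2 * sg^2))
    }
  }
  expect_lt(max(abs(img$occupancy - occ)), 1e-10)
  expect_lt(max(abs(img$charge - chg)), 1e-10)
  expect_true(all(img$occupancy >= 0 & img$occupancy <= 1))
  expect_equal(img$origin, ctr - cfg$edge / 2)
})

test_that("distant atoms are skipped, channels are translation-equivariant", {
  # an atom far beyond edge/2 + margin contributes nothing
  df <- data.frame(name = c("P", "OP1"), resname = "G", chain = "A",
                   resseq = c(1, 2), x = c(0, 100), y = 0, z = 0)
  s <- toy_structure(df)
  img_with_far <- make_image(s, "A", 1, grid_config(edge = 6))
  s_alone <- toy_structure(df[1, ])
  img_alone <- make_image(s_alone, "A", 1, grid_config(edge = 6))
  expect_identical(img_with_far$occupancy, img_alone$occupancy)
  expect_identical(img_with_far$charge, img_alone$charge)
  # translation of everything leaves channels identical
  s3 <- assign_attributes(generate_chain(3, seed = 8))
  a <- make_image(s3, "A", 2, grid_config(edge = 12, spacing = 1.5))
  s3$atoms$x <- s3$atoms$x + 5; s3$atoms$y <- s3$atoms$y + 5
  s3$atoms$z <- s3$atoms$z + 5
  b <- make_image(s3, "A", 2, grid_config(edge = 12, spacing = 1.5))
  expect_equal(a$occupancy, b$occupancy, tolerance = 1e-12)
  expect_equal(a$charge, b$charge, tolerance = 1e-12)
  expect_named(a[c("occupancy", "charge")], c("occupancy", "charge"))
})

test_that("waters and ions never enter the input channels", {
  df <- data.frame(name = c("P", "OP1"), resname = "G", chain = "A",
                   resseq = 1, x = c(0, 1.5), y = 0, z = 0)
  s <- toy_structure(df)
  img0 <- make_image(s, "A", 1, grid_config(edge = 8))
  df2 <- rbind(df,
               data.frame(name = c("O", "MG"), resname = c("HOH", "MG"),
                          chain = c("W", "Z"), resseq = c(1, 1),
                          x = c(1, -1), y = 0.5, z = 0.5))
  s2 <- toy_structure(df2)
  img1 <- make_image(s2, "A", 1, grid_config(edge = 8))
  expect_identical(img0$occupancy, img1$occupancy)
  expect_identical(img0$charge, img1$charge)
})

test_that("label grids follow the Gaussian kernel and never exceed 1", {
  img <- random_image(8)
  expect_true(all(make_label(img, NULL)$values == 0))
  # ion exactly at a voxel centre
  ion_at <- img$origin + (c(4, 4, 4) - 0.5) * img$spacing
  lab <- make_label(img, data.frame(x = ion_at[1], y = ion_at[2],
                                    z = ion_at[3]))
  expect_equal(max(lab$values), 1)
  expect_equal(lab$values[4, 4, 4], 1)
  # ion 1.5 A from a voxel centre scores exp(-0.5) there
  lab2 <- make_label(img, data.frame(x = ion_at[1] + 1.5, y = ion_at[2],
                                     z = ion_at[3]))
  expect_equal(lab2$values[4, 4, 4], exp(-0.5))
  expect_lt(max(lab2$values), 1)
  # off-lattice ion: maximum strictly below 1
  lab3 <- make_label(img, data.frame(x = ion_at[1] + 0.31,
                                     y = ion_at[2] + 0.17,
                                     z = ion_at[3] + 0.29))
  expect_lt(max(lab3$values), 1)
})

test_that("image enumeration is per-RNA-residue, ordered and deterministic", {
  pl <- plant_site(generate_chain(4, seed = 2), "ring_10", gen_config(),
                   seed = 3)
  s <- pl$structure
  cfg <- grid_config(edge = 12, spacing = 2)
  en1 <- enumerate_images(s, cfg, with_labels = TRUE)
  # 4 chain residues + 0 fragments for ring_10; waters/ions excluded
  expect_equal(length(en1$images), 4)
  en2 <- enumerate_images(s, cfg, with_labels = TRUE)
  expect_identical(en1$images, en2$images)
  expect_identical(en1$labels, en2$labels)
  expect_true(all(vapply(en1$labels, function(l) max(l$values), 1) <= 1))
})
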