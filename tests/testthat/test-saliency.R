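test_that("a constant model has zero saliency and plain gradients are deterministic", {
  cfg <- model_config(n_blocks = 1, base_channels = 4, seed = 2)
  m <- build_model(cfg)
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  img <- random_image(6, seed = 3)
  sal <- saliency_grid(m, img, target_region = 1:10, n_samples = 1,
                       noise_sigma = 0)
  expect_equal(max(abs(sal$occupancy)), 0)
  expect_equal(max(abs(sal$charge)), 0)
  m2 <- build_model(cfg)
  s1 <- saliency_grid(m2, img, 1:20, n_samples = 1, noise_sigma = 0)
  s2 <- saliency_grid(m2, img, 1:20, n_samples = 1, noise_sigma = 0)
  expect_identical(s1$occupancy, s2$occupancy)
  expect_identical(s1$charge, s2$charge)
  expect_true(all(s1$occupancy >= 0) && all(s1$charge >= 0))
  expect_error(saliency_grid(m2, img, integer(0)), "empty")
  expect_error(saliency_grid(m2, img, 10^6), "outside")
})

test_that("plain-gradient saliency matches central finite differences", {
  cfg <- model_config(n_blocks = 1, base_channels = 4, seed = 5)
  m <- build_model(cfg)
  img <- random_image(6, seed = 7)
  region <- voxels_near(img, img$origin + 3, 2.0)
  sal <- saliency_grid(m, img, region, n_samples = 1, noise_sigma = 0)
  score_of <- function(x) {
    fw <- voxmg:::.net_forward(m, x, rep(img$n, 3))
    sum(fw$p[region, 1])
  }
  x0 <- voxmg:::.image_matrix(img)
  h <- 1e-5
  set.seed(11)
  for (t in 1:20) {
    v <- sample(img$n^3, 1)
    ch <- sample(2, 1)
    xp <- x0; xp[v, ch] <- xp[v, ch] + h
    xm <- x0; xm[v, ch] <- xm[v, ch] - h
    fd <- (score_of(xp) - score_of(xm)) / (2 * h)
    an <- (if (ch == 1) sal$occupancy else sal$charge)[v]
    expect_equal(an, abs(fd), tolerance = 1e-4)
  }
})

test_that("atom back-projection interpolates trilinearly and zeroes outside", {
  n <- 4
  occ <- array(0, c(n, n, n))
  occ[2, 2, 2] <- 1
  map <- structure(list(origin = c(0, 0, 0), spacing = 1, n = n,
                        occupancy = occ, charge = occ * 2),
                   class = "saliency_map")
  at <- function(x, y, z) {
    df <- data.frame(name = "P", resname = "G", chain = "A", resseq = 1,
                     x = x, y = y, z = z)
    atom_saliency(map, toy_structure(df))
  }
  # atom exactly at voxel centre (1.5, 1.5, 1.5) -> that voxel's value
  expect_equal(at(1.5, 1.5, 1.5)$occ_saliency, 1)
  expect_equal(at(1.5, 1.5, 1.5)$chg_saliency, 2)
  # midway along x between voxels valued 1 and 0
  expect_equal(at(2.0, 1.5, 1.5)$occ_saliency, 0.5)
  # outside the box
  expect_equal(at(40, 0, 0)$occ_saliency, 0)
})

test_that("radial profiles are per-type, normalized to 1, and peak at the planted distance", {
  ctr <- data.frame(x = 0, y = 0, z = 0)
  df <- data.frame(name = c("OP1", "N7"), resname = c("G", "G"),
                   chain = "A", resseq = 1:2,
                   x = c(2.3, 4.1), y = 0, z = 0)
  s <- toy_structure(df)
  rp <- radial_profile(ctr, s$atoms, "frequency")
  oph <- rp[rp$group == "O_ph", ]
  expect_equal(sum(oph$value > 0), 1)
  expect_equal(oph$value[oph$bin_lo <= 2.3 & oph$bin_hi > 2.3], 1)
  nb <- rp[rp$group == "N_b_purine", ]
  expect_equal(max(nb$value), 1) # independent normalization per type
  expect_equal(nb$value[nb$bin_lo <= 4.1 & nb$bin_hi > 4.1], 1)
  # planted octahedral geometry: O_ph frequency peaks at the bond length
  pl <- plant_site(generate_chain(5, seed = 6), "ring_10",
                   gen_config(coordinate_noise = 0), seed = 1)
  rp2 <- radial_profile(pl$site, pl$structure$atoms, "frequency")
  oph2 <- rp2[rp2$group == "O_ph", ]
  peak_bin <- oph2[which.max(oph2$value), ]
  expect_true(peak_bin$bin_lo <= 2.1 && peak_bin$bin_hi > 2.1)
})

test_that("coordinator removal deletes exactly the listed atoms", {
  s <- assign_attributes(generate_chain(3, seed = 2))
  expect_identical(ablate_coordinators(s, integer(0)), s)
  two <- s$atoms$serial[s$atoms$name %in% c("OP1")][1:2]
  s2 <- ablate_coordinators(s, two)
  expect_equal(nrow(s2$atoms), nrow(s$atoms) - 2)
  expect_false(any(two %in% s2$atoms$serial))
  expect_error(ablate_coordinators(s, 10^6), "unknown atom")
})
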