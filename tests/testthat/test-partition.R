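RKJ <- 8.314462618e-3

test_that("Boltzmann inversion between free energy and probability", {
  z <- seq(0, 5, length.out = 50)
  flat <- fe_profile(z, G = rep(2, 50), temperature_K = 300)
  flat <- probability_from_free_energy(flat)
  expect_equal(flat$P, rep(1, 50))

  dG <- 6
  well <- fe_profile(z, G = c(rep(-dG, 10), rep(0, 40)), temperature_K = 300)
  well <- probability_from_free_energy(well)
  expect_equal(well$P[1] / well$P[50], exp(dG / (RKJ * 300)),
               tolerance = 1e-12)

  # round trip restores G up to the additive constant
  back <- free_energy_from_probability(well)
  expect_equal(back$G - back$G[50], well$G - well$G[50], tolerance = 1e-10)
})

test_that("adaptive cutoff finds the first deviation from bulk", {
  z <- seq(0, 5, length.out = 100)
  flat <- fe_profile(z, G = rep(0, 100))
  expect_true(is.na(adaptive_cutoff(flat)$R))

  # large step below layer 25: crossing at the step edge
  step <- fe_profile(z, G = c(rep(-20, 25), rep(0, 75)))
  res <- adaptive_cutoff(step, threshold = 0.1)
  expect_lte(abs(res$R - 25), 1)
  expect_gt(res$rmsd[res$R], 0.1)
  expect_true(all(res$rmsd[(res$R + 1):100] <= 0.1))

  # RMSD trace is non-increasing outward for monotone |G - G_bulk|
  mono <- fe_profile(z, G = -seq(10, 0, length.out = 100))
  tr <- adaptive_cutoff(mono)$rmsd
  expect_true(all(diff(tr) <= 1e-12))

  expect_error(adaptive_cutoff(fe_profile(c(0, 1), G = c(0, 0))), NA)
})

test_that("K_MW evaluates the layered partition sum correctly", {
  z <- seq(0, 5, length.out = 100)
  V <- 0.002; M <- 8e-20
  # uniform probability with an imposed cutoff at layer r
  p <- fe_profile(z, P = rep(1, 100), V_layer = V, M = M)
  r <- 30
  res <- compute_kmw(p, cutoff = list(R = r))
  expect_equal(res$kmw, r * V / M, tolerance = 1e-12)

  # doubling the leaflet mass halves K_MW
  p2 <- p; p2$M <- 2 * M
  expect_equal(compute_kmw(p2, cutoff = list(R = r))$kmw, res$kmw / 2)

  # K_MW invariant under rescaling all probabilities
  p3 <- p; p3$P <- p$P * 7.3
  expect_equal(compute_kmw(p3, cutoff = list(R = r))$kmw, res$kmw)

  # flat profile: no membrane association
  flat <- fe_profile(z, G = rep(0, 100), V_layer = V, M = M)
  res <- compute_kmw(flat)
  expect_true(res$no_association)
  expect_equal(res$kmw, 0)

  expect_error(compute_kmw(fe_profile(z, P = rep(1, 100), V_layer = V,
                                      M = -1), cutoff = list(R = 5)),
               "leaflet mass")
})

test_that("square-well profiles recover the closed-form K_MW", {
  T_K <- 303
  depth <- 10 * RKJ * T_K              # 10 kT deep well
  layers <- 100
  z <- seq(0, 5, length.out = layers)
  width <- 25
  G <- c(rep(-depth, width), rep(0, layers - width))
  V <- 6.5^2 * (z[2] - z[1]) * 1e-24
  M <- 8.1e-20
  prof <- fe_profile(z, G = G, V_layer = V, M = M, temperature_K = T_K)
  res <- compute_kmw(prof)
  expect_equal(res$R, width)
  kmw_exact <- width * exp(depth / (RKJ * T_K)) * V / M
  expect_equal(res$kmw, kmw_exact, tolerance = 1e-6)

  # smooth noise-free generated well agrees with direct summation
  gen <- generate_synthetic_profile(depth_kj = depth, noise_sd_kj = 0,
                                    seed = 1)
  gen <- probability_from_free_energy(gen)
  res <- compute_kmw(gen)
  R <- adaptive_cutoff(gen)$R
  manual <- (sum(gen$P[seq_len(R)]) / gen$M) / (gen$P[100] / gen$V_layer)
  expect_equal(res$kmw, manual, tolerance = 1e-12)
})

test_that("octanol-water conversion helpers fix the sign convention", {
  expect_equal(dg_to_logk(0), 0)
  # more favourable octanol solvation (negative dG difference) -> logK > 0
  expect_gt(dg_to_logk(-10), 0)
  expect_equal(logk_to_dg(dg_to_logk(-7.3)), -7.3, tolerance = 1e-12)
})

test_that("synthetic profiles are seeded and statistically unbiased", {
  p1 <- generate_synthetic_profile(noise_sd_kj = 0.5, seed = 42)
  p2 <- generate_synthetic_profile(noise_sd_kj = 0.5, seed = 42)
  expect_identical(p1, p2)

  # noisy log K_MW is unbiased within 3 standard errors over 100 seeds
  ref <- compute_kmw(generate_synthetic_profile(depth_kj = 25,
                                                noise_sd_kj = 0))$log_kmw
  vals <- vapply(1:100, function(s) {
    compute_kmw(generate_synthetic_profile(depth_kj = 25, noise_sd_kj = 0.3,
                                           seed = s))$log_kmw
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - ref), 3 * se + 1e-3)
})

test_that("deep wells are threshold-insensitive, shallow wells are not", {
  deep <- generate_synthetic_profile(depth_kj = 25, noise_sd_kj = 0)
  conv <- kmw_convergence(deep)
  spread_deep <- diff(range(conv$log_kmw)) / abs(mean(conv$log_kmw))
  expect_lt(spread_deep, 0.01)

  shallow <- generate_synthetic_profile(depth_kj = 1.2,
                                        interface_dip_kj = 0.8,
                                        noise_sd_kj = 0)
  conv_s <- kmw_convergence(shallow)
  spread_shallow <- diff(range(conv_s$log_kmw)) / abs(mean(conv_s$log_kmw))
  expect_gt(spread_shallow, 0.05)
})

test_that("xvg-style profiles load with metadata", {
  f <- tempfile(fileext = ".xvg")
  writeLines(c("# produced by wham", "@ xaxis label \"z (nm)\"",
               paste(seq(0, 5, length.out = 20),
                     c(rep(-8, 5), rep(0, 15)))), f)
  meta <- tempfile(fileext = ".yaml")
  writeLines(c("M_kg: 8.0e-20", "V_layer_dm3: 2.0e-3",
               "temperature_K: 303"), meta)
  prof <- read_profile_xvg(f, meta)
  expect_length(prof$z, 20)
  expect_equal(prof$M, 8e-20)
  res <- compute_kmw(prof)
  expect_false(res$no_association)
  expect_gt(res$log_kmw, 0)
})
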