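test_that("spectrum files round-trip to full precision", {
  s <- exponential_spectrum(40, grid_max = 800, n_points = 100,
                            label = "roundtrip", let_kev_um = 0.4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$energy_ev, s$energy_ev, tolerance = 1e-14)
  expect_equal(r$density, s$density, tolerance = 1e-14)
  m <- glance(r)
  expect_identical(m$label, "roundtrip")
  expect_equal(m$let_kev_um, 0.4)
})

test_that("spectrum reader renormalizes small deviations and rejects bad files", {
  s <- exponential_spectrum(40, grid_max = 800, n_points = 100)
  path <- withr::local_tempfile(fileext = ".txt")

  write_spectrum(energy_spectrum(s$energy_ev, s$density, label = "x"), path)
  lines <- readLines(path)
  data_at <- grep("^[^#]", lines)
  # scale density by 1.005: inside the 1% tolerance, accepted and renormalized
  scaled <- lines
  scaled[data_at] <- vapply(strsplit(lines[data_at], " +"), function(f) {
    paste(f[1], format(as.numeric(f[2]) * 1.005, digits = 17))
  }, character(1))
  writeLines(scaled, path)
  r <- read_spectrum(path)
  expect_equal(pracma::trapz(r$energy_ev, r$density), 1, tolerance = 1e-9)

  # scale by 1.02: rejected with the measured integral
  scaled[data_at] <- vapply(strsplit(lines[data_at], " +"), function(f) {
    paste(f[1], format(as.numeric(f[2]) * 1.02, digits = 17))
  }, character(1))
  writeLines(scaled, path)
  expect_error(read_spectrum(path), "integral")

  # negative density names the line
  bad <- lines
  bad[data_at[3]] <- sub("^(\\S+) .*", "\\1 -0.001", bad[data_at[3]])
  writeLines(bad, path)
  expect_error(read_spectrum(path), paste0("line ", data_at[3]))

  # non-monotone grid names the line
  bad <- lines
  bad[data_at[4]] <- sub("^\\S+", "0.0", bad[data_at[4]])
  writeLines(bad, path)
  expect_error(read_spectrum(path), "non-monotone")
})

test_that("exponential spectra have the closed-form moments", {
  s <- exponential_spectrum(40, grid_max = 1000, n_points = 2000)
  mean_e <- pracma::trapz(s$energy_ev, s$energy_ev * s$density)
  expect_equal(mean_e, 40, tolerance = 0.01)
  # survival at epsilon0 is 1/e
  beyond <- s$energy_ev >= 40
  surv <- pracma::trapz(s$energy_ev[beyond], s$density[beyond])
  expect_equal(surv, exp(-1), tolerance = 0.01)
  expect_equal(s$density[1], 1 / 40, tolerance = 0.001)
  expect_error(exponential_spectrum(0), "positive")
})

test_that("specific energy follows the closed form and scalings", {
  grid <- c(99, 99.9, 100, 100.1, 101)
  spike <- energy_spectrum(grid, c(0, 0, 1, 0, 0))
  z <- mean_specific_energy(spike, site_mass_kg = 9.8e-23)
  expect_equal(z, 100 * 1.602176634e-19 / 9.8e-23, tolerance = 1e-6)
  expect_equal(mean_specific_energy(spike, site_mass_kg = 2 * 9.8e-23), z / 2)
  # proportional to the exponential mean
  z40 <- mean_specific_energy(exponential_spectrum(40, 4000, 4000))
  z80 <- mean_specific_energy(exponential_spectrum(80, 8000, 8000))
  expect_equal(z80 / z40, 2, tolerance = 1e-3)
  # default site mass ~9.8e-23 kg for the 5 x 5 nm unit-density cylinder
  expect_equal(site_cylinder()$mass_kg, 9.8175e-23, tolerance = 1e-4)
  expect_error(mean_specific_energy(spike, site_mass_kg = 0), "positive")
})

test_that("mixtures behave linearly and preserve normalization", {
  s1 <- exponential_spectrum(40, 900, 200, label = "a", let_kev_um = 1)
  s2 <- exponential_spectrum(120, 900, 150, label = "b", let_kev_um = 9)
  m10 <- mix_spectra(list(s1, s2), c(1, 0))
  d1 <- stats::approx(s1$energy_ev, s1$density, xout = m10$energy_ev,
                      yleft = 0, yright = 0)$y
  expect_equal(m10$density, d1, tolerance = 1e-12)
  self <- mix_spectra(list(s1, s1), c(0.5, 0.5))
  expect_equal(stats::approx(self$energy_ev, self$density, xout = s1$energy_ev)$y,
               s1$density, tolerance = 1e-9)
  mx <- mix_spectra(list(s1, s2), c(0.3, 0.7))
  expect_equal(pracma::trapz(mx$energy_ev, mx$density), 1, tolerance = 1e-9)
  mean_mx <- pracma::trapz(mx$energy_ev, mx$energy_ev * mx$density)
  mean_1 <- pracma::trapz(s1$energy_ev, s1$energy_ev * s1$density)
  mean_2 <- pracma::trapz(s2$energy_ev, s2$energy_ev * s2$density)
  expect_equal(mean_mx, 0.3 * mean_1 + 0.7 * mean_2, tolerance = 1e-3)
  expect_equal(glance(mx)$let_kev_um, 0.3 * 1 + 0.7 * 9)
  expect_error(mix_spectra(list(s1, s2), c(0.5, 0.6)), "sum to 1")
})

test_that("constructor rejects invalid spectra", {
  expect_error(energy_spectrum(c(1, 2, 2), c(1, 1, 1)), "increasing")
  expect_error(energy_spectrum(c(1, 2, 3), c(1, -1, 1)), "non-negative")
  expect_error(energy_spectrum(c(-1, 2, 3), c(1, 1, 1)), "non-negative")
  expect_error(energy_spectrum(c(1, 2, 3), c(0, 0, 0)), "zero integral")
})

test_that("fixture spectra are valid, labelled synthetic, and readable", {
  dir <- withr::local_tempdir()
  specs <- fixture_spectra(dir)
  expect_named(specs, c("electron_100keV", "he_1MeV_u", "c_10MeV_u", "c_1000MeV_u"))
  for (nm in names(specs)) {
    expect_match(glance(specs[[nm]])$label, "synthetic")
    r <- read_spectrum(file.path(dir, paste0("synthetic-", nm, ".txt")))
    expect_equal(r$density, specs[[nm]]$density, tolerance = 1e-12)
  }
  # harder spectra for the slow ions than for low-LET radiation
  expect_gt(glance(specs$he_1MeV_u)$mean_energy_ev,
            glance(specs$electron_100keV)$mean_energy_ev)
})
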