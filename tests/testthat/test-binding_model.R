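test_that("complex concentration matches the bisection oracle on spot cases", {
  # kas = p0 = L0 = 1: golden-ratio-style root of the depletion quadratic
  expect_equal(complex_concentration(1, 1, 1), bisect_complex(1, 1, 1),
               tolerance = 1e-10)
  expect_equal(complex_concentration(1, 1, 1), 0.3819660113, tolerance = 1e-9)
  # no ligand, no complex
  expect_identical(complex_concentration(5, 0.1, 0), 0)
  # tight-binding stoichiometric limit, numerically stable
  expect_equal(complex_concentration(1e9, 0.1, 5), 0.1, tolerance = 1e-6)
  expect_equal(complex_concentration(1e9, 0.1, 0.05), 0.05, tolerance = 1e-6)
})

test_that("complex concentration agrees with bisection over a parameter grid", {
  for (kas in c(1e-3, 1e-1, 1, 1e2, 1e4, 1e6)) {
    for (p0 in c(0.01, 0.1, 1, 10)) {
      L0 <- c(0, 10^seq(-3, 4, length.out = 30))
      got <- complex_concentration(kas, p0, L0)
      want <- bisect_complex_vec(kas, p0, L0)
      expect_lt(max(abs(got - want)), 1e-10 * p0)
      expect_true(all(got >= 0 & got <= pmin(p0, L0) + 1e-12))
    }
  }
})

test_that("complex concentration is monotone in each argument", {
  set.seed(11)
  for (i in 1:50) {
    kas <- 10^runif(1, -3, 6); p0 <- 10^runif(1, -2, 1)
    L0 <- 10^runif(1, -3, 4); eps <- 1.01
    base <- complex_concentration(kas, p0, L0)
    expect_gte(complex_concentration(kas * eps, p0, L0), base - 1e-14)
    expect_gte(complex_concentration(kas, p0 * eps, L0), base - 1e-14)
    expect_gte(complex_concentration(kas, p0, L0 * eps), base - 1e-14)
  }
})

test_that("model fluorescence combines quench and free-ligand emission", {
  inert <- binding_parameters(10, 0.1, 100, 0, 0)
  expect_equal(model_fluorescence(inert, c(0, 1, 100)), rep(100, 3))

  p <- binding_parameters(10, 0.1, 100, 500, 2)
  pl <- bisect_complex(10, 0.1, 0.05)
  expect_equal(pl, 0.0219223594, tolerance = 1e-8)
  expect_equal(model_fluorescence(p, 0.05), 100 - 500 * pl + 2 * (0.05 - pl),
               tolerance = 1e-9)
  expect_equal(model_fluorescence(p, 0), 100)
  # saturation asymptote: free-cap emission dominates
  expect_equal(model_fluorescence(p, 1000), 100 - 500 * 0.1 + 2 * (1000 - 0.1),
               tolerance = 1e-3)
  # pure quenching curve is monotone non-increasing in ligand
  q <- binding_parameters(5, 0.1, 100, 300, 0)
  F <- model_fluorescence(q, 10^seq(-3, 3, length.out = 50))
  expect_true(all(diff(F) <= 1e-12))
})

test_that("intensity corrections follow dilution and half-path absorbance", {
  expect_equal(correct_intensities(100), 100)  # identity with no options
  expect_equal(correct_intensities(100, a_ex = 0.1, a_em = 0.05),
               100 * 10^0.075, tolerance = 1e-12)
  expect_equal(correct_intensities(100, a_ex = 0.1, a_em = 0.05),
               118.8502227, tolerance = 1e-8)
  expect_equal(correct_intensities(100, volume = 1540, reference_volume = 1400),
               110)
  expect_error(correct_intensities(100, volume = 1300, reference_volume = 1400),
               "volume")
  expect_error(correct_intensities(100, a_ex = -0.2), "absorbances")
})

test_that("titration curves enforce their point-table invariants", {
  ok <- data.frame(ligand_total = c(0, 1, 2, 4, 8, 16),
                   fluorescence_raw = c(100, 90, 80, 70, 60, 50))
  expect_s3_class(titration_curve("p", "m7GTP", ok), "titration_curve")
  expect_error(titration_curve("p", "m7GTP", ok[1:5, ]), "6 points")
  bad_start <- ok; bad_start$ligand_total[1] <- 0.5
  expect_error(titration_curve("p", "m7GTP", bad_start), "zero-ligand")
  bad_order <- ok; bad_order$ligand_total[4] <- 0.5
  expect_error(titration_curve("p", "m7GTP", bad_order), "non-decreasing")
})

test_that("titration CSV round-trips points and metadata", {
  pts <- data.frame(ligand_total = c(0, 1, 2, 4, 8, 16),
                    fluorescence_raw = c(100, 90, 80, 70, 60, 50),
                    volume = 1400 + 10 * (0:5),
                    a_ex = seq(0, 0.05, length.out = 6),
                    a_em = rep(0.01, 6))
  cv <- titration_curve("heIF4E1a", "m7GTP", pts, buffer_tag = "glycerol10",
                        temperature = 293.15)
  path <- tempfile(fileext = ".csv")
  write_titration_csv(cv, path)
  back <- read_titration_csv(path)
  expect_identical(back$protein_id, "heIF4E1a")
  expect_identical(back$ligand, "m7GTP")
  expect_identical(back$buffer_tag, "glycerol10")
  expect_equal(back$points$ligand_total, pts$ligand_total)
  expect_equal(back$points$fluorescence_raw, pts$fluorescence_raw)
  expect_equal(back$points$volume, pts$volume)

  corrected <- correct_titration(back)
  expect_equal(corrected$points$fluorescence_raw,
               correct_intensities(pts$fluorescence_raw, pts$volume,
                                   pts$a_ex, pts$a_em,
                                   reference_volume = 1400))
})
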