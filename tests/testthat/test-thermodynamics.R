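rec <- function(protein, ligand, kas, se, buffer = "standard") {
  list(protein_id = protein, ligand = ligand, buffer_tag = buffer,
       kas = kas, kas_se = se)
}

test_that("delta_g applies -RT ln(Kas) with the 1 M standard state", {
  expect_equal(delta_g(1e-6, 293.15), 0)   # Kas = 1 M^-1
  expect_equal(delta_g(1e-6, 310), 0)
  expect_equal(delta_g(68.4, 293.15), -10.510, tolerance = 1e-4)
  # doubling the association constant gains RT ln 2
  expect_equal(delta_g(10, 293.15) - delta_g(20, 293.15),
               1.9872041e-3 * 293.15 * log(2))
  expect_equal(delta_g(10, 293.15) - delta_g(20, 293.15), 0.40380,
               tolerance = 1e-4)
  expect_error(delta_g(0), "kas")
  expect_error(delta_g(-1), "kas")
})

test_that("transition energies reproduce published spot cells", {
  # human eIF4E1a: N7 methyl -> ethyl costs ~1 kcal/mol
  te <- delta_delta_g(rec("heIF4E1a", "m7GTP", 68.4, 5.1),
                      rec("heIF4E1a", "et7GTP", 13.04, 0.31), 293.15)
  expect_equal(te$ddg, 0.965, tolerance = 1e-3)
  # propagated SE close to the printed 0.045 (exactness impossible from
  # rounded inputs)
  expect_equal(te$ddg_se, 0.0456, tolerance = 1e-2)

  # human eIF4E1b gains energy from the N7 benzyl group
  tb <- delta_delta_g(rec("heIF4E1b", "m7GDP", 7.64, 0.71),
                      rec("heIF4E1b", "bn7GDP", 35.4, 1.6), 293.15)
  expect_equal(tb$ddg, -0.893, tolerance = 1e-3)

  same <- delta_delta_g(rec("p", "A", 5, 0.1), rec("p", "A", 5, 0.1))
  expect_equal(same$ddg, 0)
})

test_that("transition energies refuse mismatched protein or buffer", {
  expect_error(delta_delta_g(rec("a", "x", 1, 0.1), rec("b", "x", 1, 0.1)),
               "protein_id")
  expect_error(delta_delta_g(rec("a", "x", 1, 0.1),
                             rec("a", "y", 1, 0.1, buffer = "glycerol10")),
               "buffer")
})

test_that("transition energies are antisymmetric, additive and unit-free", {
  a <- rec("p", "A", 3.2, 0.2); b <- rec("p", "B", 41.7, 1.1)
  cc <- rec("p", "C", 0.35, 0.05)
  ab <- delta_delta_g(a, b)$ddg
  ba <- delta_delta_g(b, a)$ddg
  expect_equal(ab, -ba, tolerance = 1e-12)
  ac <- delta_delta_g(a, cc)$ddg
  bc <- delta_delta_g(b, cc)$ddg
  expect_equal(ac, ab + bc, tolerance = 1e-12)
  # common rescaling of every kas cancels
  s <- 37.2
  a2 <- rec("p", "A", 3.2 * s, 0.2 * s); b2 <- rec("p", "B", 41.7 * s, 1.1 * s)
  expect_equal(delta_delta_g(a2, b2)$ddg, ab, tolerance = 1e-12)
  expect_equal(delta_delta_g(a2, b2)$ddg_se, delta_delta_g(a, b)$ddg_se,
               tolerance = 1e-12)
  # tighter binding of the target ligand is an energy gain (negative)
  expect_lt(delta_delta_g(a, b)$ddg, 0)
  expect_gt(delta_delta_g(b, a)$ddg, 0)
})

test_that("affinity ratios reproduce published two-decimal columns", {
  expect_equal(format_ratio(affinity_ratio(rec("h1a", "m7GTP", 68.4, 5.1),
                                           rec("h1b", "m7GTP", 22.0, 1.4))),
               3.11)
  expect_equal(format_ratio(affinity_ratio(rec("h1a", "bn7GDP", 16.79, 0.56),
                                           rec("h1b", "bn7GDP", 35.4, 1.6))),
               0.47)
  expect_equal(format_ratio(affinity_ratio(rec("a", "x", 5, 1),
                                           rec("a", "x", 5, 1))), 1.00)
  expect_error(affinity_ratio(rec("a", "x", 0, 1), rec("a", "x", 5, 1)),
               "positive")
})

test_that("the transition table handles gaps and bad input explicitly", {
  records <- data.frame(
    protein_id = c("P1", "P1", "P2"),
    ligand = c("GTP", "m7GTP", "m7GTP"),
    buffer_tag = "standard",
    kas = c(0.027, 68.4, 7.80),
    kas_se = c(0.001, 5.1, 0.41))
  trans <- data.frame(from = "GTP", to = "m7GTP")
  tab <- build_ddg_table(records, trans)
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$ddg[tab$protein_id == "P1"]))
  # P2 never measured GTP: explicit gap cell, not a dropped row
  expect_true(is.na(tab$ddg[tab$protein_id == "P2"]))

  expect_equal(nrow(build_ddg_table(records, data.frame(from = character(),
                                                        to = character()))), 0)
  expect_error(build_ddg_table(records, data.frame(from = "GTP", to = "xyz")),
               "xyz")
})

test_that("bundled affinity and transition tables are consistent", {
  kas <- published_kas_table()
  expect_true(all(c("protein_id", "ligand", "buffer_tag", "kas", "kas_se")
                  %in% names(kas)))
  expect_true(all(kas$kas > 0))
  expect_true(all(kas$kas_se > 0))
  trans <- cap_transitions()
  expect_true(all(unique(c(trans$from, trans$to)) %in% unique(kas$ligand)))
  # every ligand name in the bundled tables parses
  for (nm in unique(kas$ligand))
    expect_s3_class(parse_analogue_name(nm), "cap_analogue")
  pub <- published_ddg_table()
  expect_true(all(!is.na(pub$ddg) == !is.na(pub$ddg_se)))
})
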