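# The expected pathway-mode flux vectors below were derived independently by
# solving the internal species balances by hand on the alpha-GP = 3 scale
# (the linear system is fully determined for each restricted variant) and
# are frozen here as exact integers.

xpk_mode_expected <- c(
  aGP = 3, PGM = 3, PGI = 1, G6PDH = 2, `6PGDH` = 2, RPE = 4, RPI = -2,
  TK1 = -2, TK2 = -2, TAL = -2, TIM = 3, ALD = 3, FBP = 3, XPK = 8,
  PTA = 8, PhaA = 4, PhaB = 4, PhaC = 4
)
fpk_mode_expected <- c(
  aGP = 3, PGM = 3, PGI = 1, G6PDH = 2, `6PGDH` = 2, RPE = 4, RPI = -2,
  TK1 = -2, TK2 = 6, TAL = -2, TIM = 3, ALD = 3, FBP = 3, FPK = 8,
  PTA = 8, PhaA = 4, PhaB = 4, PhaC = 4
)

test_that("a linear chain has the single unit mode", {
  modes <- elementary_modes(toy_chain())
  expect_length(modes, 1)
  expect_equal(mode_fluxes(modes[[1]]), c(r1 = 1, r2 = 1))
})

test_that("a boundary-to-boundary reaction is its own mode", {
  net <- toy_network(
    data.frame(id = c("A", "B"), role = c("boundary", "boundary")),
    list(list(id = "r1", stoich = c(A = -1, B = 1), reversible = FALSE))
  )
  modes <- elementary_modes(net)
  expect_length(modes, 1)
  expect_equal(mode_fluxes(modes[[1]]), c(r1 = 1))
  expect_equal(unclass(net_equation(modes[[1]], net)), c(A = -1, B = 1),
               ignore_attr = TRUE)
})

test_that("the XPK pathway mode carries the published coefficients", {
  net <- build_network("xpk_only")
  pm <- pathway_modes(elementary_modes(net), net)
  expect_length(pm, 1)
  m <- normalize_mode(pm[[1]], "aGP", 3)
  v <- mode_fluxes(m)
  expect_equal(v[names(xpk_mode_expected)], xpk_mode_expected)
  # the published headline coefficients
  expect_equal(unname(v[c("aGP", "PGM", "PGI", "G6PDH")]), c(3, 3, 1, 2))
  expect_equal(v[["XPK"]], 8)
  expect_equal(v[["TK2"]], -2)
})

test_that("the FPK pathway mode mirrors the XPK mode with TK2 forward", {
  net <- build_network("fpk_only")
  pm <- pathway_modes(elementary_modes(net), net)
  expect_length(pm, 1)
  m <- normalize_mode(pm[[1]], "aGP", 3)
  expect_equal(mode_fluxes(m)[names(fpk_mode_expected)], fpk_mode_expected)
})

test_that("the overall equation is 3 glucose units -> 4 PHB + 2 CO2 + 3 H2O", {
  for (variant in c("xpk_only", "fpk_only")) {
    net <- build_network(variant)
    m <- normalize_mode(pathway_modes(elementary_modes(net), net)[[1]],
                        "aGP", 3)
    nq <- net_equation(m, net)
    expect_equal(unclass(nq)[c("MD", "PHB", "CO2", "H2O")],
                 c(MD = -3, PHB = 4, CO2 = 2, H2O = 3),
                 ignore_attr = TRUE)
  }
})

test_that("theoretical yields are exact: 133.3/88.9 full, 50 and 40 essential", {
  xpk <- build_network("xpk_only")
  y <- mode_yields(normalize_mode(
    pathway_modes(elementary_modes(xpk), xpk)[[1]], "aGP", 3), xpk)
  expect_equal(y$molar_yield, 400 / 3)
  expect_equal(y$carbon_yield, 800 / 9)
  expect_equal(y$molar_yield_display, 133.3)
  expect_equal(y$carbon_yield_display, 88.9)
  expect_equal(y$molar_yield_fraction, "400/3")
  expect_equal(y$carbon_yield, y$molar_yield * 2 / 3)
  expect_equal(y$co2_per_3_glucose, 2)

  ess_x <- build_network("xpk_essential")
  yx <- mode_yields(pathway_modes(elementary_modes(ess_x), ess_x)[[1]], ess_x)
  expect_equal(yx$molar_yield, 50)

  ess_f <- build_network("fpk_essential")
  yf <- mode_yields(pathway_modes(elementary_modes(ess_f), ess_f)[[1]], ess_f)
  expect_equal(yf$molar_yield, 40)
})

test_that("steady state holds exactly for every mode of every variant", {
  for (v in network_variants()) {
    net <- build_network(v)
    S <- stoichiometric_matrix(net, "internal")
    irr <- !vapply(net$reactions, function(r) r$reversible, logical(1))
    for (m in elementary_modes(net)) {
      num <- mode_flux_numerators(m)
      expect_true(all(S %*% num == 0))       # exact integer arithmetic
      expect_true(all(num[irr] >= 0))
      y <- tryCatch(mode_yields(m, net)$molar_yield, error = function(e) 0)
      expect_lte(y, 400 / 3)
    }
  }
})

test_that("cofactor moieties close for all productive modes", {
  for (v in network_variants()) {
    net <- build_network(v)
    for (m in pathway_modes(elementary_modes(net), net)) {
      expect_equal(cofactor_closure(m, net),
                   c(NADP = 0, CoA = 0, phosphate = 0))
    }
  }
})

test_that("deleting the reductase removes any steady PHB route", {
  # without PhaB there is no producer of 3HB-CoA and no consumer of NADPH,
  # so no steady-state mode can reach the synthase
  net <- build_network("xpk_only")
  net$reactions <- net$reactions[setdiff(names(net$reactions), "PhaB")]
  expect_length(pathway_modes(elementary_modes(net), net), 0)
})

test_that("normalization: identity, rescaling, and composition", {
  net <- build_network("xpk_only")
  m <- pathway_modes(elementary_modes(net), net)[[1]]
  v0 <- mode_fluxes(m)
  ref_val <- v0[["aGP"]]
  expect_equal(mode_fluxes(normalize_mode(m, "aGP", ref_val)), v0)

  m3 <- normalize_mode(m, "aGP", 3)
  expect_equal(mode_fluxes(m3)[["aGP"]], 3)
  # two successive normalizations equal one direct normalization
  m_b <- normalize_mode(normalize_mode(m, "XPK", 5), "PhaC", 2)
  expect_equal(mode_fluxes(m_b), mode_fluxes(normalize_mode(m, "PhaC", 2)))
  # rational reference values stay exact
  mh <- normalize_mode(m, "PGI", 0.5)
  expect_equal(mode_fluxes(mh)[["PGI"]], 0.5)
  expect_error(normalize_mode(m, "FPK", 3))     # absent reaction
})

test_that("yields are refused for modes that consume no glucose", {
  net <- toy_network(
    data.frame(id = c("A", "B"), role = c("boundary", "boundary")),
    list(list(id = "r1", stoich = c(A = -1, B = 1), reversible = FALSE))
  )
  m <- elementary_modes(net)[[1]]
  expect_error(mode_yields(m, net), "glucose")
})

test_that("enumeration agrees with brute force on assorted toy networks", {
  nets <- list(
    toy_chain(),
    toy_chain(rev = c(TRUE, FALSE)),
    toy_chain(rev = c(TRUE, TRUE)),
    # diamond: two parallel routes
    toy_network(
      data.frame(id = c("A", "x", "y", "B"),
                 role = c("boundary", "internal", "internal", "boundary")),
      list(list(id = "in", stoich = c(A = -1, x = 1), reversible = FALSE),
           list(id = "up", stoich = c(x = -1, y = 1), reversible = FALSE),
           list(id = "down", stoich = c(x = -1, y = 1), reversible = TRUE),
           list(id = "out", stoich = c(y = -1, B = 1), reversible = FALSE))
    ),
    # stoichiometric doubling with a cofactor loop
    toy_network(
      data.frame(id = c("A", "x", "c", "cP", "B"),
                 role = c("boundary", "internal", "internal", "internal",
                          "boundary")),
      list(list(id = "r1", stoich = c(A = -1, c = -1, x = 1, cP = 1),
                reversible = FALSE),
           list(id = "r2", stoich = c(x = -2, B = 1), reversible = FALSE),
           list(id = "r3", stoich = c(cP = -1, c = 1), reversible = TRUE))
    )
  )
  set.seed(7)
  for (k in 1:8) {
    nets[[length(nets) + 1]] <- random_toy_network(
      n_internal = sample(2:4, 1), n_reactions = sample(4:6, 1))
  }
  for (i in seq_along(nets)) {
    pkg <- elementary_modes(nets[[i]])
    oracle <- brute_force_efms(nets[[i]])
    expect_true(same_mode_set(pkg, oracle),
                label = paste("mode-set equality for toy network", i))
  }
})
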