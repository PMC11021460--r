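net_full <- build_network("full")
p1 <- default_parameters("model1")

test_that("rate laws reduce correctly in their limiting cases", {
  # irreversible uni at half saturation
  fbp <- net_full$reactions$FBP
  p <- p1; p$reactions$FBP$vmax <- 2
  km <- p$reactions$FBP$km[["F16P"]]
  st <- c(F16P = km)
  expect_equal(evaluate_rate(fbp, st, p), 1)

  # all substrates at zero -> zero (irreversible)
  expect_equal(evaluate_rate(fbp, c(F16P = 0), p), 0)
  expect_equal(evaluate_rate(net_full$reactions$XPK,
                             c(Xu5P = 0, Pi = 5), p1), 0)

  # reversible law with substrate absent and product present runs backwards
  pgi <- net_full$reactions$PGI
  expect_lt(evaluate_rate(pgi, c(G6P = 0, F6P = 1), p1), 0)

  # reversible uni-uni at its equilibrium mass-action ratio is exactly zero
  keq <- p1$reactions$PGI$keq
  expect_equal(evaluate_rate(pgi, c(G6P = 1, F6P = keq), p1), 0)

  # reversible bi-bi at equilibrium is exactly zero
  tk2 <- net_full$reactions$TK2
  keq <- p1$reactions$TK2$keq
  st <- c(Xu5P = 0.5, E4P = 0.2, G3P = 0.4, F6P = keq * 0.5 * 0.2 / 0.4)
  expect_equal(evaluate_rate(tk2, st, p1), 0, tolerance = 1e-12)
})

test_that("the synthase law reduces to Henri-Michaelis-Menten at PHB = 0", {
  phac <- net_full$reactions$PhaC
  p <- default_parameters("model0")   # C_bind 1000, n 1
  expect_equal(p$reactions$PhaC$c_bind, 1000)
  expect_equal(p$reactions$PhaC$n, 1)
  km <- p$reactions$PhaC$km[["HBCoA"]]
  for (s in c(0.01, km, 1)) {
    expect_equal(evaluate_rate(phac, c(HBCoA = s, PHB = 0), p),
                 p$reactions$PhaC$vmax * s / (km + s))
  }
  # binding term damps the rate once PHB accumulates
  r0 <- evaluate_rate(phac, c(HBCoA = 1, PHB = 0), p)
  r75 <- evaluate_rate(phac, c(HBCoA = 1, PHB = 75), p)
  expect_equal(r75 / r0, 1000 / 1075)
})

test_that("missing Km entries are rejected at assembly time", {
  p <- p1
  p$reactions$XPK$km <- p$reactions$XPK$km["Pi"]
  expect_error(validate_parameters(p, net_full), "XPK")
  expect_error(simulate_cascade(net_full, p, scenario_spec(t_end = 10)),
               "XPK")
})

test_that("parameter positivity constraints are enforced", {
  p <- p1; p$reactions$PGI$keq <- -1
  expect_error(validate_parameters(p), "keq")
  p <- p1; p$reactions$PhaC$c_bind <- 0
  expect_error(validate_parameters(p), "C_bind")
  expect_error(vmax_to_loading(-1), "non-negative")
  expect_equal(vmax_to_loading(c(0, 1, 8)), c(0, 1, 8))
})

test_that("zero Vmax everywhere leaves the state constant", {
  p <- set_vmax(p1, 0)
  sim <- simulate_cascade(net_full, p, scenario_spec(t_end = 30))
  expect_true(all(abs(sweep(sim$conc, 2, sim$conc[1, ])) < 1e-12))
  expect_true(is.na(sim$event_time))
})

test_that("simulation detects the stop event and conserves mass", {
  # the optimized loading: 5x base with the synthase raised to 8 mM/min
  p <- set_vmax(set_vmax(p1, 5), c(PhaC = 8))
  sc <- scenario_spec(t_end = 240)
  sim <- simulate_cascade(net_full, p, sc)

  # event: maltodextrin stops at exactly 40% of its initial value
  expect_false(is.na(sim$event_time))
  expect_equal(unname(sim$conc[nrow(sim$conc), "MD"]), 40, tolerance = 1e-6)
  expect_equal(sim$consumed, 60, tolerance = 1e-6)

  # maltodextrin is non-increasing throughout
  expect_true(all(diff(sim$conc[, "MD"]) <= 1e-9))

  # non-negativity within solver tolerance
  expect_true(all(sim$conc > -1e-9))

  # total carbon, NADP(H), CoA thioester pool and phosphate are conserved
  sp <- net_full$species; rownames(sp) <- sp$id
  carbon <- sim$conc %*% sp[colnames(sim$conc), "C"]
  expect_lt(max(abs(carbon - carbon[1])) / carbon[1], 1e-6)
  nadp <- rowSums(sim$conc[, c("NADP", "NADPH")])
  expect_lt(max(abs(nadp - nadp[1])) / nadp[1], 1e-6)
  coa <- rowSums(sim$conc[, c("CoA", "AcCoA", "AcAcCoA", "HBCoA")])
  expect_lt(max(abs(coa - coa[1])) / coa[1], 1e-6)
  phos <- sim$conc %*% sp[colnames(sim$conc), "P"]
  expect_lt(max(abs(phos - phos[1])) / phos[1], 1e-6)
})

test_that("freeze semantics hold the whole state after the event", {
  p <- set_vmax(set_vmax(p1, 5), c(PhaC = 8))
  sim <- simulate_cascade(net_full, p, scenario_spec(t_end = 240),
                          stop_mode = "freeze")
  expect_false(is.na(sim$event_time))
  expect_equal(final_phb(sim), sim$phb_at_event)
  after <- sim$conc[sim$times >= sim$event_time, , drop = FALSE]
  expect_true(all(abs(sweep(after, 2, after[1, ])) < 1e-9))
  # under halt-uptake the drain continues, so the final titer is higher
  sim2 <- simulate_cascade(net_full, p, scenario_spec(t_end = 240))
  expect_gt(final_phb(sim2), final_phb(sim))
  expect_equal(sim2$consumed, sim$consumed, tolerance = 1e-6)
})

test_that("re-simulating from the event state consumes no more substrate", {
  p <- set_vmax(set_vmax(p1, 5), c(PhaC = 8))
  sim <- simulate_cascade(net_full, p, scenario_spec(t_end = 240))
  expect_false(is.na(sim$event_time))
  y_end <- sim$conc[nrow(sim$conc), ]
  # keep the event referenced to the original 100 mM initial substrate
  sc2 <- scenario_spec(initial = y_end[y_end > 0], t_end = 60,
                       stop_reference = 100)
  sim2 <- simulate_cascade(net_full, p, sc2)
  expect_equal(sim2$event_time, 0)
  md <- sim2$conc[, "MD"]
  expect_lt(md[1] - min(md), 1e-4 * md[1])
})

test_that("timed additions raise the pools and the event reference", {
  p <- set_vmax(set_vmax(p1, 5), c(PhaC = 8))
  sc <- scenario_spec(initial = c(MD = 40), t_end = 300,
                      additions = list(list(time = 30, species = "MD",
                                            amount = 20)))
  sim <- simulate_cascade(net_full, p, sc)
  i30 <- max(which(sim$times <= 30))
  expect_gt(sim$conc[i30 + 1, "MD"], sim$conc[i30, "MD"] + 15)
  # event now refers to 40% of the cumulative 60 mM
  expect_false(is.na(sim$event_time))
  expect_equal(unname(sim$conc[nrow(sim$conc), "MD"]), 24, tolerance = 1e-5)
})

test_that("initial PHB rate follows its definition", {
  fake <- structure(list(times = 0:120,
                         conc = cbind(PHB = 0.1 * (0:120))),
                    class = "phb_simulation")
  expect_equal(initial_phb_rate(fake), 6)

  short <- structure(list(times = 0:30, conc = cbind(PHB = rep(0, 31))),
                     class = "phb_simulation")
  expect_error(initial_phb_rate(short), "60")

  p <- set_vmax(p1, 0)
  sim <- simulate_cascade(net_full, p, scenario_spec(t_end = 90))
  expect_equal(initial_phb_rate(sim), 0)
})

test_that("derived metrics reproduce the worked production arithmetic", {
  m <- derived_metrics(74.9, 59.7, 8)
  expect_equal(unname(m$display["molar_yield_pct"]), 125.5)
  expect_equal(unname(m$display["rate_mM_per_h"]), 9.4)

  m2 <- derived_metrics(208.3, 186.1, 24)
  expect_equal(unname(m2$display["molar_yield_pct"]), 111.9)
  expect_equal(unname(m2$display["rate_mM_per_h"]), 8.7)

  m3 <- derived_metrics(0, 10, 8)
  expect_equal(m3$molar_yield_pct, 0)
  expect_equal(m3$rate_mM_per_h, 0)

  expect_error(derived_metrics(10, 0, 8), "consumption")
})

test_that("trajectories write as delimited text", {
  p <- set_vmax(p1, 5)
  sim <- simulate_cascade(net_full, p, scenario_spec(t_end = 10))
  path <- tempfile(fileext = ".tsv")
  write_trajectory(sim, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), length(sim$times))
  expect_true(all(c("time_min", "MD", "PHB") %in% colnames(df)))
})
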