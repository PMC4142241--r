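# The synthetic-structure and synthetic-experiment generators.

test_that("the helix fixture carries the textbook i -> i-4 H-bond pattern", {
  hx <- build_amide_hydrogens(make_structure("ideal_helix", 20))
  counts <- oracle_counts(hx)
  inner <- counts$nh[counts$resno >= 5]
  expect_true(all(inner == 1))
  expect_true(all(counts$nh[counts$resno < 5] == 0))
  # and the acceptor really is the i-4 carbonyl oxygen
  H <- atom_xyz(hx, "A", 9, "H")
  O <- atom_xyz(hx, "A", 5, "O")
  expect_lt(sqrt(sum((H - O)^2)), 2.4)
})

test_that("the extended chain has no H-bonds anywhere", {
  ext <- build_amide_hydrogens(make_structure("extended_chain", 20))
  expect_true(all(oracle_counts(ext)$nh == 0))
})

test_that("ring oligomers are chain-symmetric with a real interface", {
  hex <- build_amide_hydrogens(make_structure("ring_oligomer", 10,
                                              n_chains = 6))
  p <- lnP_frame(hex)
  sym <- tapply(p$lnP[p$has_amide], p$resno[p$has_amide],
                function(v) diff(range(v)))
  expect_true(all(sym < 1e-9))
  # interface contacts: chain A gains contacts relative to the lone helix
  mono <- build_amide_hydrogens(make_structure("ideal_helix", 10))
  pm <- lnP_frame(mono)
  pa <- p[p$chain == "A", ]
  expect_gt(sum(pa$nc), sum(pm$nc))
})

test_that("ensembles are deterministic under a fixed seed", {
  base <- make_structure("ideal_helix", 8)
  e1 <- make_ensemble(base, 5, jitter_sigma = 0.3, seed = 99)
  e2 <- make_ensemble(base, 5, jitter_sigma = 0.3, seed = 99)
  expect_identical(e1, e2)
  e3 <- make_ensemble(base, 5, jitter_sigma = 0.3, seed = 100)
  expect_false(identical(e1, e3))
  # zero jitter reproduces the crystal exactly
  e0 <- make_ensemble(base, 3, jitter_sigma = 0, seed = 1)
  expect_equal(e0$frames[[2]]$atoms[, c("x", "y", "z")],
               base$atoms[, c("x", "y", "z")])
})

test_that("zero-jitter ensemble protection equals the crystal profile", {
  base <- make_structure("ideal_helix", 10)
  ens <- map_frames(make_ensemble(base, 3, jitter_sigma = 0, seed = 1),
                    build_amide_hydrogens)
  prof <- average_protection(ens)
  crystal <- lnP_frame(build_amide_hydrogens(base))
  m <- match(prof$by_chain$resno, crystal$resno)
  expect_equal(prof$by_chain$mean_lnP, crystal$lnP[m])
})

test_that("synthetic uptake tables round-trip against their ground truth", {
  planted <- data.frame(resno = 1:12,
                        lnP = c(NA, seq(0.5, 5.5, length.out = 11)),
                        k_int_s = 0.5, exchanger = c(FALSE, rep(TRUE, 11)))
  frs <- data.frame(id = c("a", "b"), start = c(2, 7), end = c(6, 12))
  made <- make_uptake_table(planted, frs, noise_sd = 0, seed = 1)
  # predicting from the planted parameters reproduces the table exactly
  pred <- made$truth$noiseless
  names(pred)[names(pred) == "D"] <- "D_pred"
  paired <- pair_predictions(pred, made$table)
  expect_equal(fragment_rmsd(paired)$global, 0, tolerance = 1e-12)
})

test_that("noise injection produces the requested RMS deviation", {
  planted <- data.frame(resno = 1:40,
                        lnP = rep(seq(1, 7, length.out = 20), 2),
                        k_int_s = 0.5, exchanger = TRUE)
  frs <- data.frame(id = as.character(1:20), start = seq(1, 39, 2),
                    end = seq(2, 40, 2))
  made <- make_uptake_table(planted, frs, noise_sd = 0.02, seed = 5)
  pred <- made$truth$noiseless
  names(pred)[names(pred) == "D"] <- "D_pred"
  paired <- pair_predictions(pred, made$table)
  g <- fragment_rmsd(paired)$global
  expect_gt(g, 0.02 * 0.8)
  expect_lt(g, 0.02 * 1.2)
})

test_that("two-state open/closed mixtures expose the interface", {
  hex <- make_structure("ring_oligomer", 10, n_chains = 6)
  closed <- map_frames(make_ensemble(hex, 4, jitter_sigma = 0.05, seed = 7),
                       build_amide_hydrogens)
  mixed <- map_frames(make_ensemble(hex, 4, jitter_sigma = 0.05, seed = 7,
                                    open_fraction = 0.5,
                                    open_displacement = 12),
                      build_amide_hydrogens)
  frs <- data.frame(id = "iface", start = 3, end = 8)
  pc <- average_protection(closed, mode = "mean_D")
  pm <- average_protection(mixed, mode = "mean_D")
  rates <- rates_for_structure(closed)
  f <- hdx_fragments(frs, closed)
  Dc <- fragment_uptake(f[1, ], pc, rates, times = 480, mode = "mean_D")
  Dm <- fragment_uptake(f[1, ], pm, rates, times = 480, mode = "mean_D")
  expect_gt(Dm$values, Dc$values)
})
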