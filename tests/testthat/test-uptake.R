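# Residue- and fragment-level deuterium uptake curves.

helix_setup <- function(n = 14, frames = 1, sigma = 0, seed = 5) {
  base <- make_structure("ideal_helix", n)
  ens <- if (frames == 1) hdx_ensemble(list(base)) else
    make_ensemble(base, n_frames = frames, jitter_sigma = sigma, seed = seed)
  ens <- map_frames(ens, build_amide_hydrogens)
  list(ens = ens,
       profile = average_protection(ens),
       rates = rates_for_structure(ens))
}

test_that("residue uptake obeys saturation, half-life and P=1 identities", {
  t <- c(0, 30, 300, 3000, 3e6)
  cur <- residue_uptake(lnP = 2, k_int = 0.05, times = t)
  expect_equal(cur$values[1], 0)
  expect_gt(cur$values[5], 0.999)
  expect_true(all(diff(cur$values) > 0))
  expect_true(all(cur$values >= 0 & cur$values <= 1))
  # half-life identity t1/2 = P ln2 / k_int
  P <- exp(2)
  th <- P * log(2) / 0.05
  expect_equal(residue_uptake(2, 0.05, th)$values, 0.5, tolerance = 1e-12)
  # lnP = 0: pure intrinsic curve
  expect_equal(residue_uptake(0, 0.01, t)$values, 1 - exp(-0.01 * t))
  expect_error(residue_uptake(0, 0.01, -5), "negative")
})

test_that("a one-amide fragment reduces to the residue curve", {
  s <- helix_setup()
  fr <- hdx_fragments(data.frame(id = "x", start = 6, end = 6), s$ens)
  cur <- fragment_uptake(fr[1, ], s$profile, s$rates)
  lnP <- s$profile$residue$mean_lnP[s$profile$residue$resno == 6]
  k <- s$rates$k_int_s[s$rates$resno == 6]
  expect_equal(cur$values, residue_uptake(lnP, k, cur$times)$values,
               tolerance = 1e-12)
})

test_that("fragment curve is the unweighted mean over its amides", {
  s <- helix_setup()
  fr <- hdx_fragments(data.frame(id = "x", start = 7, end = 8), s$ens)
  cur <- fragment_uptake(fr[1, ], s$profile, s$rates)
  per_res <- vapply(7:8, function(r) {
    lnP <- s$profile$residue$mean_lnP[s$profile$residue$resno == r]
    k <- s$rates$k_int_s[s$rates$resno == r]
    residue_uptake(lnP, k, cur$times)$values
  }, numeric(length(cur$times)))
  expect_equal(cur$values, rowMeans(per_res), tolerance = 1e-12)
  # and the arithmetic-mean identity itself: D = (0.2 + 0.4)/2
  expect_equal(mean(c(0.2, 0.4)), 0.3)
  # bracketed by slowest and fastest residue curves
  expect_true(all(cur$values >= apply(per_res, 1, min) - 1e-12))
  expect_true(all(cur$values <= apply(per_res, 1, max) + 1e-12))
})

test_that("fragments without amides or outside the chain are rejected", {
  s <- helix_setup(8)
  expect_error(hdx_fragments(data.frame(id = "z", start = 20, end = 25),
                             s$ens), "outside")
  pro <- make_structure("ideal_helix", 6, sequence = "APPPAA")
  ensp <- map_frames(hdx_ensemble(list(pro)), build_amide_hydrogens)
  prof <- average_protection(ensp)
  fr <- hdx_fragments(data.frame(id = "p", start = 2, end = 4), ensp)
  expect_equal(fr$n_amides, 0)
  expect_error(fragment_uptake(fr[1, ], prof, rates_for_structure(ensp)),
               "no exchange-competent amides")
})

test_that("mean_lnP and mean_D agree on single-frame single-chain input", {
  s <- helix_setup()
  fr <- hdx_fragments(data.frame(id = "x", start = 5, end = 10), s$ens)
  c1 <- fragment_uptake(fr[1, ], s$profile, s$rates, mode = "mean_lnP")
  c2 <- fragment_uptake(fr[1, ], s$profile, s$rates, mode = "mean_D")
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
})

test_that("per-frame series is constant for static ensembles and averages to mean_D", {
  base <- make_structure("ideal_helix", 12)
  static <- map_frames(make_ensemble(base, 4, jitter_sigma = 0, seed = 1),
                       build_amide_hydrogens)
  prof <- average_protection(static)
  rates <- rates_for_structure(static)
  fr <- hdx_fragments(data.frame(id = "s", start = 5, end = 9), static)
  pf <- perframe_uptake_series(fr[1, ], prof, rates, t_star = 480)
  expect_equal(diff(range(pf$series$D)), 0, tolerance = 1e-12)

  jit <- map_frames(make_ensemble(base, 6, jitter_sigma = 0.5, seed = 2),
                    build_amide_hydrogens)
  profj <- average_protection(jit)
  pfj <- perframe_uptake_series(fr[1, ], profj, rates, t_star = 480)
  cd <- fragment_uptake(fr[1, ], profj, rates, times = 480, mode = "mean_D")
  expect_equal(pfj$mean, cd$values, tolerance = 1e-12)
  # Jensen gap: averaging D exceeds D of the averaged lnP while the
  # per-conformation exponent k_int*t/P stays below 1 (convex branch);
  # short times keep the fixture in that regime
  cd60 <- fragment_uptake(fr[1, ], profj, rates, times = 60,
                          mode = "mean_D")
  cl60 <- fragment_uptake(fr[1, ], profj, rates, times = 60,
                          mode = "mean_lnP")
  expect_gte(cd60$values, cl60$values - 1e-12)
})

test_that("uptake tables cover fragments x times and stay in [0,1]", {
  s <- helix_setup(30)
  frs <- hdx_fragments(data.frame(id = as.character(1:20),
                                  start = 2:21, end = 8:27), s$ens)
  tab <- uptake_table(frs, s$profile, s$rates)
  expect_equal(nrow(tab), 200)
  expect_true(all(tab$D_pred >= 0 & tab$D_pred <= 1))
  expect_equal(nrow(uptake_table(frs[0, ], s$profile, s$rates)), 0)
  one <- uptake_table(frs, s$profile, s$rates, times = 480)
  expect_equal(nrow(one), 20)
})

test_that("raising a residue's protection slows every containing fragment", {
  s <- helix_setup()
  fr <- hdx_fragments(data.frame(id = "x", start = 6, end = 9), s$ens)
  prof2 <- s$profile
  i <- prof2$residue$resno == 7
  prof2$residue$mean_lnP[i] <- prof2$residue$mean_lnP[i] + 2
  c1 <- fragment_uptake(fr[1, ], s$profile, s$rates)
  c2 <- fragment_uptake(fr[1, ], prof2, s$rates)
  expect_true(all(c2$values <= c1$values + 1e-12))
})
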