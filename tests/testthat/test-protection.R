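# Contact and H-bond counting and the phenomenological protection factor.

mini_frame <- function(rows) {
  a <- do.call(rbind, lapply(rows, function(r)
    data.frame(eleno = NA_integer_, elety = r$elety, resid = r$resid,
               chain = r$chain, resno = r$resno, x = r$x, y = r$y, z = r$z,
               element = r$element,
               is_heavy = !(r$element %in% c("H", "D")),
               stringsAsFactors = FALSE)))
  a$eleno <- seq_len(nrow(a))
  hdxkin:::new_hdx_frame(a)
}

test_that("contact counting respects the strict cutoff and exclusions", {
  # residue 1 (chain A): N at origin with H; heavy atoms on chain B at
  # 6.4 and 6.6 A; an H atom nearby must never count
  fr <- mini_frame(list(
    list(elety = "N", resid = "ALA", chain = "A", resno = 1,
         x = 0, y = 0, z = 0, element = "N"),
    list(elety = "H", resid = "ALA", chain = "A", resno = 1,
         x = 1, y = 0, z = 0, element = "H"),
    list(elety = "CA", resid = "ALA", chain = "B", resno = 5,
         x = 6.4, y = 0, z = 0, element = "C"),
    list(elety = "C", resid = "ALA", chain = "B", resno = 6,
         x = 6.6, y = 0, z = 0, element = "C")))
  expect_equal(count_contacts(fr, "A", 1), 1L)
  # exactly at the cutoff: excluded (strict <)
  fr2 <- mini_frame(list(
    list(elety = "N", resid = "ALA", chain = "A", resno = 1,
         x = 0, y = 0, z = 0, element = "N"),
    list(elety = "CA", resid = "ALA", chain = "B", resno = 5,
         x = 6.5, y = 0, z = 0, element = "C")))
  expect_equal(count_contacts(fr2, "A", 1), 0L)
  # isolated residue: its own atoms fall in the exclusion window
  fr3 <- build_amide_hydrogens(make_structure("extended_chain", 2))
  one <- hdxkin:::new_hdx_frame(fr3$atoms[fr3$atoms$resno == 2, ])
  expect_equal(count_contacts(one, "A", 2), 0L)
})

test_that("H-bond counting finds constructed acceptors only", {
  fr <- mini_frame(list(
    list(elety = "N", resid = "ALA", chain = "A", resno = 2,
         x = 0, y = 0, z = 0, element = "N"),
    list(elety = "H", resid = "ALA", chain = "A", resno = 2,
         x = 1.0, y = 0, z = 0, element = "H"),
    list(elety = "O", resid = "ALA", chain = "A", resno = 5,
         x = 2.9, y = 0, z = 0, element = "O"),    # 1.9 A from H
    list(elety = "O", resid = "ALA", chain = "B", resno = 9,
         x = 3.5, y = 0, z = 0, element = "O")))   # 2.5 A from H
  expect_equal(count_hbonds(fr, "A", 2), 1L)
  # fully extended isolated chain: no H-bonds anywhere
  ext <- build_amide_hydrogens(make_structure("extended_chain", 15))
  p <- lnP_frame(ext)
  expect_true(all(p$nh == 0))
})

test_that("spatial counts equal brute-force all-pairs counts", {
  for (seed in 1:20) {
    fr <- random_frame(n_res = 30, seed = seed)
    p <- lnP_frame(fr)
    orc <- oracle_counts_fast(fr)
    m <- match(paste(p$chain, p$resno), paste(orc$chain, orc$resno))
    expect_equal(as.numeric(p$nc), as.numeric(orc$nc[m]))
    expect_equal(as.numeric(p$nh), as.numeric(orc$nh[m]))
  }
})

test_that("lnP is the beta-weighted sum of counts, for any beta", {
  hx <- build_amide_hydrogens(make_structure("ideal_helix", 20))
  p1 <- lnP_frame(hx)  # defaults beta_c=0.35, beta_h=2
  ok <- p1$has_amide
  expect_equal(p1$lnP[ok], 0.35 * p1$nc[ok] + 2 * p1$nh[ok])
  p2 <- lnP_frame(hx, protection_params(beta_c = 0.1, beta_h = 5))
  expect_equal(p2$lnP[ok], 0.1 * p2$nc[ok] + 5 * p2$nh[ok])
  # hand evaluation: Nc=10, Nh=1 at defaults
  expect_equal(0.35 * 10 + 2 * 1, 5.5)
  expect_true(all(p1$lnP[ok] >= 0))
})

test_that("adding a heavy atom within the cutoff never decreases lnP", {
  fr <- build_amide_hydrogens(make_structure("ideal_helix", 8))
  p0 <- lnP_frame(fr)
  N4 <- atom_xyz(fr, "A", 4, "N")
  extra <- data.frame(eleno = NA_integer_, elety = "CB", resid = "ALA",
                      chain = "A", resno = 999L,
                      x = N4[1] + 3, y = N4[2], z = N4[3],
                      element = "C", is_heavy = TRUE)
  fr2 <- hdxkin:::new_hdx_frame(rbind(fr$atoms, extra))
  p1 <- lnP_frame(fr2)
  p1s <- p1[p1$resno %in% p0$resno, ]
  expect_true(all(p1s$lnP[p1s$has_amide] >= p0$lnP[p0$has_amide]))
  expect_gt(p1$lnP[p1$resno == 4], p0$lnP[p0$resno == 4])
})

test_that("symmetric oligomers give identical per-chain profiles", {
  hex <- build_amide_hydrogens(make_structure("ring_oligomer", 10,
                                              n_chains = 6))
  p <- lnP_frame(hex)
  byres <- split(p$lnP[p$has_amide], p$resno[p$has_amide])
  expect_true(all(vapply(byres, function(v) diff(range(v)) < 1e-9,
                         logical(1))))
})

test_that("ensemble averaging is the weighted mean of per-frame lnP", {
  fr <- build_amide_hydrogens(make_structure("ideal_helix", 10))
  prof1 <- average_protection(hdx_ensemble(list(fr)))
  f1 <- lnP_frame(fr)
  m <- match(prof1$by_chain$resno, f1$resno)
  expect_equal(prof1$by_chain$mean_lnP, f1$lnP[m])

  ens <- make_ensemble(fr, n_frames = 2, jitter_sigma = 0.5, seed = 11)
  ens <- map_frames(ens, build_amide_hydrogens)
  prof <- average_protection(ens)
  l1 <- lnP_frame(ens$frames[[1]])$lnP
  l2 <- lnP_frame(ens$frames[[2]])$lnP
  expect_equal(prof$by_chain$mean_lnP, (l1 + l2)[m] / 2)

  # inconsistent topologies are refused
  small <- hdxkin:::new_hdx_frame(fr$atoms[fr$atoms$resno <= 5, ])
  expect_error(hdx_ensemble(list(fr, small)), "topology")
})

test_that("profile CSV export has the documented columns", {
  fr <- build_amide_hydrogens(make_structure("ideal_helix", 6))
  prof <- average_protection(hdx_ensemble(list(fr)))
  tmp <- tempfile(fileext = ".csv")
  write_protection_csv(prof, tmp)
  d <- read.csv(tmp)
  expect_named(d, c("chain", "resseq", "aa", "mean_Nc", "mean_Nh",
                    "mean_lnP", "n_frames"))
  expect_equal(nrow(d), 6)
})
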