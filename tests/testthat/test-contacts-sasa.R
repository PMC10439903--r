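# insert numbering, contacts, solvent accessibility, paratope

test_that("insert numbering anchors at the residue before 101 and stops at 95", {
  g <- generate_vhh_structure("kinked", 12, seed = 1)$chain
  idx <- insert_index(g)
  expect_equal(names(idx)[1], "I1")
  lab <- function(i) paste0(g$residues[[i]]$number, g$residues[[i]]$ins)
  expect_equal(lab(idx[["I1"]]), "100D")
  expect_equal(lab(idx[["I2"]]), "100C")
  expect_equal(length(idx), 10)  # 12-residue loop minus 101, 102
  expect_equal(lab(idx[[length(idx)]]), "95")
  g8 <- generate_vhh_structure("extended", 8, seed = 1)$chain
  idx8 <- insert_index(g8)
  expect_equal(length(idx8), 6)
  expect_equal(lab8 <- paste0(g8$residues[[idx8[["I1"]]]]$number,
                              g8$residues[[idx8[["I1"]]]]$ins), "100")
})

test_that("contact cutoff is inclusive at 4.0 A over heavy atoms", {
  r0 <- mk_res(c(0, 0, 0))
  expect_true(residue_contact(r0, mk_res(c(3.9, 0, 0))))
  expect_true(residue_contact(r0, mk_res(c(4.0, 0, 0))))
  expect_false(residue_contact(r0, mk_res(c(4.1, 0, 0))))
  # minimum over all atom pairs
  rb <- mk_res(rbind(c(10, 0, 0), c(3.5, 0, 0)))
  expect_equal(min_heavy_atom_distance(r0, rb), 3.5)
  expect_equal(min_heavy_atom_distance(rb, r0), 3.5)  # symmetric
})

test_that("cohort contact map fractions and denominators follow the design", {
  k <- lapply(1:4, function(i) generate_vhh_structure("kinked", 12, seed = i)$chain)
  e <- lapply(1:4, function(i) generate_vhh_structure("extended", 9,
                                                      seed = 10 + i)$chain)
  mk <- cohort_contact_map(k)
  expect_equal(unname(mk$fraction["45", "I1"]), 1.0)
  expect_true(all(mk$fraction >= 0 & mk$fraction <= 1, na.rm = TRUE))
  # 12-residue loops define I1..I10 only: I11+ columns have denominator 0
  expect_equal(unname(mk$denominator["45", "I10"]), 4)
  expect_equal(unname(mk$denominator["45", "I11"]), 0)
  expect_true(is.na(mk$fraction["45", "I11"]))
  me <- cohort_contact_map(e)
  expect_equal(max(me$fraction, na.rm = TRUE), 0)
  # mixed cohort: 1 kinked + 1 extended at the designed cell -> 0.5
  mhalf <- cohort_contact_map(list(k[[1]], e[[1]]))
  expect_equal(unname(mhalf$fraction["45", "I1"]), 0.5)
  long <- contact_map_long(mk)
  expect_true(all(c("fwr2_pos", "insert_pos", "fraction", "n") %in% names(long)))
  expect_true(all(long$n > 0))
})

test_that("contact-map PFM columns sum to one over observed residues", {
  k <- lapply(1:3, function(i) generate_vhh_structure("kinked", 12, seed = i)$chain)
  mk <- cohort_contact_map(k)
  cs <- colSums(mk$pfm_fwr2)
  expect_true(all(abs(cs - 1) < 1e-12))
  obs_cols <- colSums(mk$pfm_cdr3) > 0
  expect_true(all(abs(colSums(mk$pfm_cdr3)[obs_cols] - 1) < 1e-12))
})

test_that("Shrake-Rupley matches closed forms and converges with sampling", {
  lone <- mk_ca_chain(matrix(c(0, 0, 0), 1))
  s <- shrake_rupley(lone, n_points = 960, radii = c(C = 1.7))
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01)
  # two-sphere spherical-cap oracle
  R <- 1.7 + 1.4
  for (d in c(2, 3, 4)) {
    two <- mk_ca_chain(rbind(c(0, 0, 0), c(d, 0, 0)))
    s2 <- shrake_rupley(two, n_points = 960, radii = c(C = 1.7))
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
    expect_equal(s2$total, exact, tolerance = 0.02)
  }
  # error against the oracle shrinks as point count grows
  errs <- vapply(c(96, 960, 9600), function(np) {
    two <- mk_ca_chain(rbind(c(0, 0, 0), c(3, 0, 0)))
    s2 <- shrake_rupley(two, n_points = np, radii = c(C = 1.7))
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - 1.5))
    abs(s2$total - exact) / exact
  }, 1)
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 5e-3)
})

test_that("SASA obeys occlusion monotonicity and enclosure", {
  # fully enclosed atom
  shell <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1),
                 cbind(c(1, 1, -1, -1) / sqrt(2), c(1, -1, 1, -1) / sqrt(2), 0),
                 cbind(0, c(1, 1, -1, -1) / sqrt(2), c(1, -1, 1, -1) / sqrt(2)))
  enc <- mk_ca_chain(rbind(c(0, 0, 0), 2 * shell))
  se <- shrake_rupley(enc)
  expect_equal(se$atoms$area[1], 0)
  # adding neighbours can only decrease each atom's area
  set.seed(33)
  pts <- matrix(rnorm(15, sd = 2.5), 5, 3)
  full <- shrake_rupley(mk_ca_chain(pts))
  part <- shrake_rupley(mk_ca_chain(pts[1:3, , drop = FALSE]))
  expect_true(all(full$atoms$area[1:3] <= part$atoms$area + 1e-9))
  iso <- sum(vapply(1:5, function(i)
    shrake_rupley(mk_ca_chain(pts[i, , drop = FALSE]))$total, 1))
  expect_lte(full$total, iso + 1e-9)
})

test_that("relative accessibility is ~1 for exposed Ala, 0 when buried, bounded", {
  gag <- build_peptide(rep(180, 3), rep(180, 3), sequence = "GAG")
  rsa <- relative_sasa(gag, 2)
  expect_equal(rsa$aa, "A")
  expect_equal(rsa$rsa, 1.0, tolerance = 0.1)
  # buried residue: surround a single-atom residue with an occluding shell
  shell <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1),
                 cbind(c(1, 1, -1, -1) / sqrt(2), c(1, -1, 1, -1) / sqrt(2), 0),
                 cbind(0, c(1, 1, -1, -1) / sqrt(2), c(1, -1, 1, -1) / sqrt(2)))
  buried <- mk_ca_chain(rbind(c(0, 0, 0), 2 * shell))
  rb <- relative_sasa(buried, 1)
  expect_equal(rb$rsa, 0)
  # random structures stay within the loose physical bound
  set.seed(44)
  ch <- build_peptide(runif(8, -180, 180), runif(8, -180, 180),
                      sequence = strrep("A", 8))
  rr <- relative_sasa(ch, 1:8)
  expect_true(all(rr$rsa >= 0 & rr$rsa <= 1.25))
})

test_that("paratope profile flags designed regions and conserves area", {
  g <- generate_vhh_structure("kinked", 12, seed = 3)
  cx <- generate_complex(g$chain, "CDR2", seed = 1)
  pp <- paratope_profile(cx, n_points = 240)
  expect_equal(pp$region[pp$contact], "CDR2")
  expect_gt(pp$buried_area[pp$region == "CDR2"], 0)
  expect_true(all(pp$buried_area[pp$region != "CDR2"] == 0))
  expect_equal(attr(pp, "total_area"), sum(pp$buried_area))
  # two-region design
  cx2 <- generate_complex(g$chain, c("CDR1", "CDR2"), seed = 2)
  pp2 <- paratope_profile(cx2, n_points = 240)
  expect_setequal(pp2$region[pp2$contact], c("CDR1", "CDR2"))
  expect_error(paratope_profile(
    structure(list(vhh = list(g$chain), antigen = list(), source_id = "x"),
              class = "vhh_complex")), "no antigen")
})

test_that("cohort paratope summary aggregates per conformation label", {
  g1 <- generate_vhh_structure("kinked", 12, seed = 3)$chain
  g2 <- generate_vhh_structure("extended", 9, seed = 4)$chain
  p1 <- paratope_profile(generate_complex(g1, "CDR2", seed = 1), n_points = 96)
  p2 <- paratope_profile(generate_complex(g2, "CDR1", seed = 1), n_points = 96)
  s <- cohort_paratope_summary(list(p1, p2), c("kinked", "extended"))
  u <- s$usage
  expect_equal(u$percent[u$label == "kinked" & u$region == "CDR2"], 100)
  expect_equal(u$percent[u$label == "extended" & u$region == "CDR2"], 0)
  expect_equal(u$percent[u$label == "extended" & u$region == "CDR1"], 100)
  a <- s$area
  expect_gt(a$mean_area[a$label == "kinked" & a$region == "CDR2"], 0)
})
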