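# stem angles, classification, superposition

test_that("pseudo-bond angle matches arccos oracle and handles degenerate input", {
  expect_equal(pseudo_bond_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(pseudo_bond_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  set.seed(101)
  for (i in 1:250) {
    p <- matrix(rnorm(9), 3, 3)
    expect_equal(pseudo_bond_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-11)
  }
  expect_error(pseudo_bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("pseudo-dihedral matches projection oracle, IUPAC sign, rigid invariance", {
  expect_equal(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                               c(0, 1, 0)), 0)
  expect_equal(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                               c(2, 1, 0)), 180)
  expect_equal(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                               c(1, 1, 1)), 90)
  set.seed(102)
  for (i in 1:250) {
    p <- matrix(rnorm(12), 4, 3)
    d0 <- pseudo_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(d0, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-11)
    # rigid motion invariance
    R <- random_rotation(); t <- rnorm(3)
    q <- sweep(p %*% t(R), 2, t, "+")
    expect_equal(pseudo_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), d0,
                 tolerance = 1e-9)
    # reflection antisymmetry
    m <- p; m[, 3] <- -m[, 3]
    expect_equal(pseudo_dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -d0,
                 tolerance = 1e-9)
  }
})

test_that("stem residues follow chain order ending at 102", {
  g <- generate_vhh_structure("kinked", 12, seed = 5)
  labs <- vapply(stem_residues(g$chain), function(r) paste0(r$number, r$ins), "")
  expect_equal(labs, c("100C", "100D", "101", "102"))
  g8 <- generate_vhh_structure("extended", 8, seed = 5)
  labs8 <- vapply(stem_residues(g8$chain), function(r) paste0(r$number, r$ins), "")
  expect_equal(labs8, c("99", "100", "101", "102"))
  # missing CA at a stem residue is a hard error
  broken <- g$chain
  i <- conformap:::residue_index(broken, 101L)
  broken$residues[[i]]$atoms <-
    broken$residues[[i]]$atoms[broken$residues[[i]]$atoms$name != "CA", ]
  expect_error(stem_residues(broken), "missing CA")
})

test_that("classification windows match the published definitions, strict boundaries", {
  expect_equal(classify_h3(60, 110), "kinked")
  expect_equal(classify_h3(-120, 120), "extended")
  expect_equal(classify_h3(150, 150), "other")
  expect_equal(classify_h3(0, 110), "other")     # strict lower alpha bound
  expect_equal(classify_h3(120, 110), "other")
  expect_equal(classify_h3(60, 85), "other")
  expect_equal(classify_h3(-100, 120), "other")  # strict extended bound
  expect_equal(classify_h3(-120, 145), "other")
})

test_that("compute_h3_angles is rigid-invariant and mirror-antisymmetric", {
  g <- generate_vhh_structure("kinked", 12, seed = 9)
  a0 <- compute_h3_angles(g$chain)
  set.seed(9)
  moved <- transform_chain(g$chain, random_rotation(), rnorm(3))
  a1 <- compute_h3_angles(moved)
  expect_equal(a1$alpha101, a0$alpha101, tolerance = 1e-9)
  expect_equal(a1$tau101, a0$tau101, tolerance = 1e-9)
  mirror <- g$chain
  mirror$residues <- lapply(mirror$residues, function(r) {
    r$atoms$z <- -r$atoms$z; r
  })
  a2 <- compute_h3_angles(mirror)
  expect_equal(a2$alpha101, -a0$alpha101, tolerance = 1e-9)
  expect_equal(a2$tau101, a0$tau101, tolerance = 1e-9)
})

test_that("superposition RMSD: zero on self/rotated copies, oracle on displaced CA", {
  g <- generate_vhh_structure("kinked", 12, seed = 4)
  pos <- 96:101
  expect_equal(superpose_and_rmsd(g$chain, g$chain, pos), 0, tolerance = 1e-12)
  set.seed(4)
  rot <- transform_chain(g$chain, random_rotation(), rnorm(3, sd = 10))
  expect_lt(superpose_and_rmsd(g$chain, rot, pos), 1e-9)
  # displace one CA by 1 A and compare with a numerical-optimisation oracle
  disp <- g$chain
  i <- conformap:::residue_index(disp, 97L)
  k <- match("CA", disp$residues[[i]]$atoms$name)
  disp$residues[[i]]$atoms$z[k] <- disp$residues[[i]]$atoms$z[k] + 1
  got <- superpose_and_rmsd(g$chain, disp, pos)
  A <- t(vapply(pos, function(p) residue_ca(find_residue(g$chain, p)),
                numeric(3)))
  B <- t(vapply(pos, function(p) residue_ca(find_residue(disp, p)),
                numeric(3)))
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  obj <- function(th) {
    cx <- cos(th[1]); sx <- sin(th[1]); cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    sqrt(mean(rowSums((Bc %*% t(Rx %*% Ry %*% Rz) - Ac)^2)))
  }
  best <- Inf
  set.seed(7)
  for (s in 1:12) {
    o <- optim(runif(3, -pi, pi), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-6)
  expect_error(superpose_and_rmsd(g$chain, disp, 96:97), "at least 3")
})

test_that("cohort classification table carries angles, labels and lengths", {
  coh <- generate_structure_cohort(3, 2, seed = 6)
  tab <- classify_cohort(coh$chains)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$label, coh$truth$label)
  expect_equal(tab$alpha101, coh$truth$alpha101, tolerance = 1e-6)
  expect_equal(tab$cdr3_len, coh$truth$cdr3_length)
})
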