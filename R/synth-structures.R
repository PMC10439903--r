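# Synthetic VHH structures with prescribed stem geometry.
#
# The scaffold is idealised, not a real immunoglobulin fold: framework
# residues sit on a serpentine C-alpha grid (3.8 A spacing, 12 A between
# rows), the CDR-H3 loop is routed either back over framework 2 (kinked)
# or out into solvent (extended), and the four stem C-alphas are built to
# exact target angles. All consumers of these structures measure distances
# and angles, never energetics, so geometric truth is what matters.

# NeRF placement: position d such that |d-c| = bond, angle(b,c,d) = theta,
# dihedral(a,b,c,d) = chi (degrees)
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) stop("collinear frame in place_atom")
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d_loc <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d_loc[1] * bc + d_loc[2] * m + d_loc[3] * n
}

#' Build four stem C-alpha points with prescribed angles
#'
#' Returns points p1..p4 (rows) with consecutive distances 3.8 A such that
#' `pseudo_bond_angle(p2, p3, p4) == tau_target` and
#' `pseudo_dihedral(p1, p2, p3, p4) == alpha_target` to high precision.
#'
#' @param alpha_target Dihedral target in degrees, (-180, 180].
#' @param tau_target Bond-angle target in degrees, (0, 180).
#' @param bond Consecutive CA distance, default 3.8 A.
#' @param theta2 Auxiliary bond angle at p2 (p1-p2-p3), default 110 degrees.
#' @return 4 x 3 numeric matrix.
#' @export
build_stem_coordinates <- function(alpha_target, tau_target, bond = 3.8,
                                   theta2 = 110) {
  if (tau_target <= 0 || tau_target >= 180) stop("tau_target outside (0, 180)")
  if (alpha_target <= -180 || alpha_target > 180)
    stop("alpha_target outside (-180, 180]")
  tau <- tau_target * pi / 180
  p2 <- c(0, 0, 0)
  p3 <- c(bond, 0, 0)
  p4 <- p3 + bond * c(-cos(tau), sin(tau), 0)
  p1 <- place_atom(p4, p3, p2, bond, theta2, alpha_target)
  rbind(p1, p2, p3, p4)
}

# ideal peptide backbone from phi/psi (omega = 180): N, CA, C, O, CB per
# residue with standard bond geometry; used for secondary-structure tests
# and reference tripeptides

#' Build an ideal-geometry peptide backbone from dihedral angles
#'
#' Constructs a chain with standard backbone bond lengths/angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A), trans peptide bonds,
#' and the requested phi/psi angles. Residues carry N, CA, C, O and (except
#' glycine) CB.
#'
#' @param phi,psi Numeric vectors of dihedrals in degrees (recycled to the
#'   longer length).
#' @param sequence One-letter amino-acid string; default poly-alanine.
#' @param chain_id,source_id Identifiers.
#' @return A numbered `vhh_chain` with residues numbered 1..n.
#' @export
build_peptide <- function(phi, psi, sequence = NULL, chain_id = "A",
                          source_id = "peptide") {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  # seed first residue
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      # N(i): C(i-1) with angle CA-C-N = 116.2, dihedral psi(i-1)
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi[i - 1])
      # CA(i): omega = 180
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      # C(i): phi(i)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
    # carbonyl O in the peptide plane: dihedral (N(i+1) or psi+180)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psi[i] + 180)
  }
  residues <- lapply(seq_len(n), function(i) {
    names <- c("N", "CA", "C", "O")
    coords <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (aa[i] != "G") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, phi[i] - 120)
      names <- c(names, "CB")
      coords <- rbind(coords, cb)
    }
    new_residue(i, "", aa[i],
                data.frame(name = names,
                           element = substr(names, 1, 1),
                           x = coords[, 1], y = coords[, 2], z = coords[, 3],
                           stringsAsFactors = FALSE))
  })
  new_chain(chain_id, residues, source_id)
}

# Chothia labels of a CDR-H3 of a given length: 95..100, inserts 100A..,
# then 101, 102 (minimum length 8)
cdr3_labels <- function(len) {
  stopifnot(len >= 8L, len <= 27L)
  n_ins <- len - 8L
  nums <- c(95:100, rep(100L, n_ins), 101L, 102L)
  ins <- c(rep("", 6), if (n_ins > 0) LETTERS[seq_len(n_ins)] else character(0),
           "", "")
  list(number = nums, ins = ins)
}

# satellite backbone atoms around a CA given a local tangent direction;
# offsets kept within 1.35 A of the CA so contact margins are controlled
satellite_atoms <- function(ca, tangent) {
  t_u <- tangent / vnorm(tangent)
  ref <- if (abs(t_u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  j_u <- vcross(t_u, ref); j_u <- j_u / vnorm(j_u)
  k_u <- vcross(t_u, j_u)
  data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    x = ca[1] + c(-1.2 * t_u[1], 0, 1.2 * t_u[1], 1.2 * t_u[1] + 0.6 * k_u[1],
                  1.0 * j_u[1]),
    y = ca[2] + c(-1.2 * t_u[2], 0, 1.2 * t_u[2], 1.2 * t_u[2] + 0.6 * k_u[2],
                  1.0 * j_u[2]),
    z = ca[3] + c(-1.2 * t_u[3], 0, 1.2 * t_u[3], 1.2 * t_u[3] + 0.6 * k_u[3],
                  1.0 * j_u[3]),
    stringsAsFactors = FALSE)
}

# serpentine framework CA layout: slots 1..105 cover Chothia 1..94 and
# 103..113; 20 slots per row, 12 A row spacing, 3.8 A along the row
framework_slot_xyz <- function(slot) {
  row <- (slot - 1) %/% 20
  col <- (slot - 1) %% 20
  x <- if (row %% 2 == 0) col * 3.8 else (19 - col) * 3.8
  c(x, row * 12, 0)
}

# default VHH-like amino acids: conserved Cys22/Cys92, hallmark FWR2 and the
# C-terminal YDYWGQ-style consensus; label-dependent hallmarks at 37/45/47
scaffold_sequence <- function(label) {
  aa <- rep("S", 113)
  aa[seq(2, 113, by = 3)] <- "G"
  aa[seq(3, 113, by = 3)] <- "V"
  aa[22] <- "C"; aa[92] <- "C"; aa[93] <- "A"; aa[94] <- "R"
  if (label == "kinked") {
    aa[37] <- "F"; aa[45] <- "R"; aa[47] <- "F"
  } else {
    aa[37] <- "Y"; aa[45] <- "Q"; aa[47] <- "L"
  }
  aa[103] <- "W"; aa[104] <- "G"; aa[105] <- "Q"; aa[106] <- "G"
  aa
}

#' Generate a synthetic VHH structure with a designed stem conformation
#'
#' Builds a full Chothia-numbered chain 1--113 (backbone N, CA, C, O, CB on
#' an idealised serpentine scaffold) whose CDR-H3 stem realises the target
#' `alpha101`/`tau101` angles. Kinked variants route the loop so that insert
#' position I1 stacks on framework-2 position 45 at the designed distance;
#' extended variants keep every CDR-H3 atom well clear (>= 6 A) of all FWR2
#' atoms. Deterministic per seed.
#'
#' @param label `"kinked"` or `"extended"`.
#' @param cdr3_length CDR-H3 residue count including insertions (>= 8);
#'   defaults: 12 for kinked, 9 for extended (the cohort means of the two
#'   conformation families).
#' @param seed Integer seed.
#' @param alpha,tau Optional explicit stem angle targets; by default drawn
#'   uniformly inside the classification window of `label`.
#' @param contact_distance Designed I1(CA)--45(CA) stacking distance for
#'   kinked loops, default 3.5 A.
#' @return List with `chain` (a `vhh_chain`) and `truth` (designed label,
#'   angles, CDR lengths, stem ids and contact pairs).
#' @export
generate_vhh_structure <- function(label = c("kinked", "extended"),
                                   cdr3_length = NULL, seed = 1,
                                   alpha = NULL, tau = NULL,
                                   contact_distance = 3.5) {
  label <- match.arg(label)
  set.seed(seed)
  if (is.null(cdr3_length))
    cdr3_length <- if (label == "kinked") 12L else 9L
  if (is.null(alpha))
    alpha <- if (label == "kinked") runif(1, 20, 100) else runif(1, -170, -110)
  if (is.null(tau))
    tau <- if (label == "kinked") runif(1, 90, 125) else runif(1, 105, 140)
  stopifnot(classify_h3(alpha, tau) == label)

  aa_all <- scaffold_sequence(label)
  lab <- cdr3_labels(cdr3_length)

  # framework CA positions
  fw_numbers <- c(1:94, 103:113)
  fw_ca <- lapply(seq_along(fw_numbers), framework_slot_xyz)
  names(fw_ca) <- fw_numbers

  # stem CA quadruple at exact angles, variant chosen so p1 stays above the
  # plane of its anchor
  S <- build_stem_coordinates(alpha, tau)
  if (S[1, 3] < 0) S[, 2:3] <- -S[, 2:3]  # proper rotation about x axis
  anchor <- if (label == "kinked") {
    fw_ca[["45"]] + c(0, 0, contact_distance)
  } else {
    (fw_ca[["94"]] + fw_ca[["103"]]) / 2 + c(0, 0, 10)
  }
  S <- sweep(S, 2, anchor - S[2, ], "+")  # translate so p2 -> anchor

  # CDR-H3 CA path: non-stem residues arc from 94 toward the stem entry
  n_loop <- cdr3_length - 4L
  start <- fw_ca[["94"]]
  p1 <- S[1, ]
  loop_ca <- lapply(seq_len(n_loop), function(j) {
    t <- j / (n_loop + 1)
    base <- (1 - t) * start + t * p1
    lift <- if (label == "kinked") 6 * sin(pi * t) else 4 * sin(pi * t)
    base + c(0, 0, lift + if (label == "extended") 0 else 0)
  })
  cdr3_ca <- c(loop_ca, list(S[1, ], S[2, ], S[3, ], S[4, ]))

  # assemble residues in Chothia order
  residues <- list()
  add_res <- function(number, ins, aa, ca, tangent) {
    at <- satellite_atoms(ca, tangent)
    if (aa == "G") at <- at[at$name != "CB", ]
    residues[[length(residues) + 1L]] <<- new_residue(number, ins, aa, at)
  }
  cdr3_aa <- c("A", sample(c("G", "S", "R", "D", "V", "A", "T"),
                           cdr3_length - 4, replace = TRUE),
               "Y", "D", "Y")[seq_len(cdr3_length)]
  # enforce the conserved-ish stem identities: I1 = Y, 101 = D, 102 = Y
  cdr3_aa[cdr3_length - 2L] <- "Y"
  cdr3_aa[cdr3_length - 1L] <- "D"
  cdr3_aa[cdr3_length] <- "Y"

  for (num in 1:94) {
    nxt <- if (num < 94) fw_ca[[as.character(num + 1)]] else cdr3_ca[[1]]
    prv <- if (num > 1) fw_ca[[as.character(num - 1)]] else NULL
    tangent <- if (is.null(prv)) nxt - fw_ca[[as.character(num)]] else
      nxt - prv
    if (vnorm(tangent) < 1e-6) tangent <- c(1, 0, 0)
    add_res(num, "", aa_all[num], fw_ca[[as.character(num)]], tangent)
  }
  for (k in seq_len(cdr3_length)) {
    ca <- cdr3_ca[[k]]
    prv <- if (k > 1) cdr3_ca[[k - 1]] else fw_ca[["94"]]
    nxt <- if (k < cdr3_length) cdr3_ca[[k + 1]] else fw_ca[["103"]]
    tangent <- nxt - prv
    if (vnorm(tangent) < 1e-6) tangent <- c(0, 1, 0)
    add_res(lab$number[k], lab$ins[k], cdr3_aa[k], ca, tangent)
  }
  for (num in 103:113) {
    nxt <- if (num < 113) fw_ca[[as.character(num + 1)]] else NULL
    prv <- if (num > 103) fw_ca[[as.character(num - 1)]] else
      cdr3_ca[[cdr3_length]]
    tangent <- if (is.null(nxt)) fw_ca[[as.character(num)]] - prv else
      nxt - prv
    if (vnorm(tangent) < 1e-6) tangent <- c(1, 0, 0)
    add_res(num, "", aa_all[num], fw_ca[[as.character(num)]], tangent)
  }
  source_id <- sprintf("synth_%s_%04d", label, seed)
  chain <- new_chain("A", residues, source_id)
  stem_lab <- vapply(stem_residues(chain), function(r) paste0(r$number, r$ins), "")
  truth <- list(source_id = source_id, label = label, alpha101 = alpha,
                tau101 = tau, cdr3_length = cdr3_length,
                cdr1_length = cdr_length(chain, "CDR1"),
                cdr2_length = cdr_length(chain, "CDR2"),
                stem_ids = stem_lab,
                contact_pairs = if (label == "kinked")
                  data.frame(fwr2_pos = "45", insert_pos = "I1") else
                    data.frame(fwr2_pos = character(0),
                               insert_pos = character(0)))
  list(chain = chain, truth = truth)
}

#' Generate a deterministic cohort of synthetic VHH structures
#'
#' @param n_kinked,n_extended Cohort sizes.
#' @param seed Base seed; structure i uses `seed * 1000 + i`.
#' @param cdr3_length_kinked,cdr3_length_extended Designed loop lengths.
#' @return List with `chains` and `truth` (data frame of designed values).
#' @export
generate_structure_cohort <- function(n_kinked = 30, n_extended = 20,
                                      seed = 1, cdr3_length_kinked = 12,
                                      cdr3_length_extended = 9) {
  specs <- data.frame(
    label = c(rep("kinked", n_kinked), rep("extended", n_extended)),
    len = c(rep(cdr3_length_kinked, n_kinked),
            rep(cdr3_length_extended, n_extended)),
    stringsAsFactors = FALSE)
  chains <- vector("list", nrow(specs))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    g <- generate_vhh_structure(specs$label[i], specs$len[i],
                                seed = seed * 1000 + i)
    g$chain$source_id <- sprintf("%s_%03d", g$truth$source_id, i)
    chains[[i]] <- g$chain
    rows[[i]] <- data.frame(source_id = g$chain$source_id,
                            label = g$truth$label,
                            alpha101 = g$truth$alpha101,
                            tau101 = g$truth$tau101,
                            cdr3_length = g$truth$cdr3_length,
                            stringsAsFactors = FALSE)
  }
  list(chains = chains, truth = do.call(rbind, rows))
}

#' Place a toy antigen next to selected regions of a VHH
#'
#' For each requested region a compact cluster of pseudo-atoms is placed so
#' its minimum heavy-atom distance to that region falls in
#' `[contact_min, contact_max]` while staying at least `clear` Angstrom from
#' every other region. Directions out of the scaffold plane are tried first;
#' placement failure is an error.
#'
#' @param chain A synthetic `vhh_chain` (from [generate_vhh_structure()]).
#' @param target_regions Character vector of region names, e.g. `"CDR2"`.
#' @param seed Integer seed (cluster jitter).
#' @param contact_min,contact_max Designed contact window, default 3.3--3.8.
#' @param clear Minimum distance to non-target regions, default 8 A.
#' @return A `vhh_complex` with the VHH chain and one antigen chain.
#' @export
generate_complex <- function(chain, target_regions, seed = 1,
                             contact_min = 3.3, contact_max = 3.8,
                             clear = 8) {
  set.seed(seed)
  rm <- region_map()
  stopifnot(all(target_regions %in% names(rm)))
  other <- setdiff(names(rm), target_regions)
  other_atoms <- do.call(rbind, lapply(other, function(reg) {
    res <- suppressWarnings(region_residues(chain, reg))
    do.call(rbind, lapply(res, function(r) as.matrix(r$atoms[, c("x", "y", "z")])))
  }))
  target_atoms <- function(reg) {
    res <- suppressWarnings(region_residues(chain, reg))
    do.call(rbind, lapply(res, function(r) as.matrix(r$atoms[, c("x", "y", "z")])))
  }
  mind <- function(P, Q) {
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
    sqrt(max(0, min(d2)))
  }
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0),
                c(1, 0, 0), c(-1, 0, 0))
  cluster_local <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0),
                         c(0, 0.5, 0), c(0, 0, 0.5))
  atoms <- list()
  for (reg in target_regions) {
    res <- suppressWarnings(region_residues(chain, reg))
    anchor_res <- res[[ceiling(length(res) / 2)]]
    anchor <- residue_ca(anchor_res)
    tatoms <- target_atoms(reg)
    placed <- FALSE
    for (di in seq_len(nrow(dirs))) {
      for (offset in seq(contact_min + 0.2, contact_max + 3, by = 0.1)) {
        center <- anchor + dirs[di, ] * offset
        cl <- sweep(cluster_local, 2, center, "+")
        dt <- mind(cl, tatoms)
        if (dt < contact_min || dt > contact_max) next
        if (!is.null(other_atoms) && mind(cl, other_atoms) < clear) next
        atoms[[length(atoms) + 1L]] <- cl
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed)
      stop("could not place antigen near region ", reg,
           " with the required clearances")
  }
  ag_residues <- lapply(seq_along(atoms), function(i) {
    cl <- atoms[[i]]
    new_residue(i, "", "X",
                data.frame(name = paste0("C", seq_len(nrow(cl))),
                           element = "C", x = cl[, 1], y = cl[, 2],
                           z = cl[, 3], stringsAsFactors = FALSE))
  })
  antigen <- new_chain("X", ag_residues,
                       paste0(chain$source_id, ".antigen"), numbered = FALSE)
  structure(list(vhh = list(chain), antigen = list(antigen),
                 source_id = paste0(chain$source_id, "_cx")),
            class = "vhh_complex")
}
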