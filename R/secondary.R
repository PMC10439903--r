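# Kabsch-Sander style secondary structure over backbone N, CA, C, O.
#
# Backbone amide hydrogens are reconstructed from peptide geometry (1.0 A
# from N, opposite the bisector of the C(i-1)->N and CA->N directions).
# The hydrogen-bond energy is the classic electrostatic model
#   E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol,
# a bond being assigned when E < -0.5 kcal/mol. Only the simplified
# alphabet {G, H, T, E, C} is produced: n->n+3 turn repeats give G (3-10
# helix), n->n+4 repeats give H (alpha helix), isolated turns give T, and
# beta-bridge ladders give E. Priority H > G > E > T.

backbone_coords <- function(chain) {
  n <- length(chain$residues)
  get <- function(r, name) {
    i <- match(name, r$atoms$name)
    if (is.na(i)) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  list(N = t(vapply(chain$residues, get, numeric(3), name = "N")),
       CA = t(vapply(chain$residues, get, numeric(3), name = "CA")),
       C = t(vapply(chain$residues, get, numeric(3), name = "C")),
       O = t(vapply(chain$residues, get, numeric(3), name = "O")))
}

# reconstructed amide H for residues 2..n (NA for residue 1 and prolines
# are not special-cased: the toy model has no side chains to distinguish)
amide_h <- function(bb) {
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (anyNA(bb$N[i, ]) || anyNA(bb$CA[i, ]) || anyNA(bb$C[i - 1, ])) next
    d1 <- bb$N[i, ] - bb$C[i - 1, ]
    d2 <- bb$N[i, ] - bb$CA[i, ]
    d1 <- d1 / vnorm(d1)
    d2 <- d2 / vnorm(d2)
    dir <- d1 + d2
    if (vnorm(dir) < 1e-8) next
    H[i, ] <- bb$N[i, ] + dir / vnorm(dir)
  }
  H
}

# n x n logical matrix: hb[i, j] TRUE if CO(i) accepts NH(j)
hbond_matrix <- function(bb) {
  n <- nrow(bb$N)
  H <- amide_h(bb)
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || anyNA(bb$N[j, ]) || anyNA(H[j, ])) next
      rON <- vnorm(bb$O[i, ] - bb$N[j, ])
      rCH <- vnorm(bb$C[i, ] - H[j, ])
      rOH <- vnorm(bb$O[i, ] - H[j, ])
      rCN <- vnorm(bb$C[i, ] - bb$N[j, ])
      if (rON < 0.5 || rOH < 0.5) next  # clash guard
      E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < -0.5
    }
  }
  hb
}

#' Assign simplified secondary structure to a chain
#'
#' @param chain A `vhh_chain` with backbone N, CA, C, O atoms. Residues with
#'   missing backbone atoms are labelled `C` with a warning.
#' @return Character vector of per-residue labels in
#'   `{"G", "H", "E", "T", "C"}`, same length as the chain.
#' @export
assign_secondary_structure <- function(chain) {
  n <- length(chain$residues)
  bb <- backbone_coords(chain)
  incomplete <- apply(cbind(bb$N, bb$CA, bb$C, bb$O), 1, anyNA)
  if (any(incomplete))
    warning(sum(incomplete), " residue(s) with missing backbone atoms in ",
            chain$source_id, "; labelled C")
  ss <- rep("C", n)
  if (n < 4L) return(ss)
  hb <- hbond_matrix(bb)
  turn3 <- vapply(seq_len(n), function(i) i + 3 <= n && hb[i, i + 3], TRUE)
  turn4 <- vapply(seq_len(n), function(i) i + 4 <= n && hb[i, i + 4], TRUE)
  # helices from consecutive turns
  gmask <- rep(FALSE, n); hmask <- rep(FALSE, n); tmask <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (turn4[i] && i > 1 && turn4[i - 1]) hmask[i:min(n, i + 3)] <- TRUE
    if (turn3[i] && i > 1 && turn3[i - 1]) gmask[i:min(n, i + 2)] <- TRUE
  }
  # beta bridges
  emask <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) emask[c(i, j)] <- TRUE
    }
  }
  # isolated turns
  for (i in seq_len(n)) {
    if (turn3[i]) tmask[seq(i + 1, i + 2)] <- TRUE
    if (turn4[i]) tmask[seq(i + 1, i + 3)] <- TRUE
  }
  ss[tmask] <- "T"
  ss[emask] <- "E"
  ss[gmask] <- "G"
  ss[hmask] <- "H"
  ss[incomplete] <- "C"
  ss
}

#' Detect the helix-or-turn motif at CDR-H3 insert positions I2--I4
#'
#' Kinked loops frequently carry a short 3-10 helix or turn immediately
#' before the stem. The motif is called when any of insert positions I2--I4
#' is labelled `G` or `T`.
#'
#' @param chain A numbered `vhh_chain`.
#' @param ss Secondary-structure labels from
#'   [assign_secondary_structure()] (computed if missing).
#' @return `"helix_or_turn"` or `"other"`.
#' @export
stem_motif <- function(chain, ss = NULL) {
  if (is.null(ss)) ss <- assign_secondary_structure(chain)
  idx <- insert_index(chain)
  want <- idx[names(idx) %in% c("I2", "I3", "I4")]
  if (length(want) == 0L) return("other")
  if (any(ss[want] %in% c("G", "T"))) "helix_or_turn" else "other"
}

#' Confidence filter on the CDR-H3 stem of a predicted model
#'
#' A predicted model is dropped when the confidence (pLDDT) of any of the
#' residues 100x, 101 or 102 falls below 70 (strictly; exactly 70 keeps).
#'
#' @param model A `predicted_model` from [read_predicted_model()], or a
#'   `vhh_chain` with a `plddt` field.
#' @param cutoff Confidence cutoff, default 70.
#' @return `"keep"` or `"drop"`.
#' @export
plddt_stem_filter <- function(model, cutoff = 70) {
  if (is.null(model$plddt)) stop("model carries no per-residue confidence")
  i101 <- residue_index(model, 101L)
  i102 <- residue_index(model, 102L)
  if (is.na(i101) || is.na(i102) || i101 < 2L)
    stop("stem unresolvable in ", model$source_id)
  conf <- model$plddt[c(i101 - 1L, i101, i102)]
  if (anyNA(conf)) stop("missing confidence at stem of ", model$source_id)
  if (min(conf) < cutoff) "drop" else "keep"
}
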