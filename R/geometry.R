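# Stem-angle geometry and kinked/extended classification.
#
# The CDR-H3 C-terminal stem conformation is captured by two angles over
# C-alpha atoms: tau101, the planar (pseudo-bond) angle at position 101 over
# the triple (100x, 101, 102), and alpha101, the pseudo-dihedral over the
# four chain-order stem residues ending at 102. tau101 is sometimes loosely
# called a pseudo dihedral, but three atoms define a bond angle; the observed
# 85--145 degree range only makes sense for the planar reading, which is the
# one implemented here.

vnorm <- function(v) sqrt(sum(v * v))
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pseudo-bond angle over three points
#'
#' Planar angle at `p2`, in degrees, computed via `atan2` of the cross and
#' dot products (numerically stable near 0 and 180 degrees).
#'
#' @param p1,p2,p3 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, in (0, 180].
#' @export
pseudo_bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  if (vnorm(u) == 0 || vnorm(v) == 0)
    stop("coincident points in pseudo_bond_angle")
  atan2(vnorm(vcross(u, v)), sum(u * v)) * 180 / pi
}

#' Pseudo-dihedral angle over four points
#'
#' Signed torsion p1-p2-p3-p4 in degrees, IUPAC convention (cis = 0,
#' right-handed positive), in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Dihedral in degrees.
#' @export
pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) == 0 || vnorm(n2) == 0)
    stop("degenerate (collinear) geometry in pseudo_dihedral")
  ang <- atan2(sum(vcross(n1, n2) * (b2 / vnorm(b2))),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Locate the four CDR-H3 stem residues
#'
#' Returns, in chain order, the two residues immediately preceding Chothia
#' 101 (the second of which is "100x", whatever its insertion code), then
#' 101, then 102. In loops without insertions this is (99, 100, 101, 102).
#'
#' @param chain A numbered `vhh_chain`.
#' @return List of four residues; errors if 101/102 are absent, fewer than
#'   two residues precede 101, or any stem residue lacks a CA atom.
#' @export
stem_residues <- function(chain) {
  i101 <- residue_index(chain, 101L)
  i102 <- residue_index(chain, 102L)
  if (is.na(i101) || is.na(i102) || i102 != i101 + 1L)
    stop("chain ", chain$source_id,
         ": residues 101/102 missing or out of order; not classifiable")
  if (i101 < 3L)
    stop("chain ", chain$source_id, ": fewer than 2 residues precede 101")
  stem <- chain$residues[c(i101 - 2L, i101 - 1L, i101, i102)]
  if (any(vapply(stem, function(r) is.null(residue_ca(r)), TRUE)))
    stop("chain ", chain$source_id,
         ": missing CA at a stem residue; not classifiable")
  stem
}

#' Classify a CDR-H3 stem conformation from its angles
#'
#' Kinked if `0 < alpha101 < 120` and `85 < tau101 < 130`; extended if
#' `alpha101 < -100` and `100 < tau101 < 145`; otherwise `"other"`.
#' All inequalities are strict; the two windows are disjoint.
#'
#' @param alpha101 Pseudo-dihedral in degrees, (-180, 180].
#' @param tau101 Pseudo-bond angle in degrees, (0, 180).
#' @return `"kinked"`, `"extended"` or `"other"` (vectorised).
#' @export
classify_h3 <- function(alpha101, tau101) {
  kinked <- alpha101 > 0 & alpha101 < 120 & tau101 > 85 & tau101 < 130
  extended <- alpha101 < -100 & tau101 > 100 & tau101 < 145
  ifelse(kinked, "kinked", ifelse(extended, "extended", "other"))
}

#' Compute CDR-H3 stem angles and conformation label for one chain
#'
#' @param chain A numbered `vhh_chain` containing the CDR-H3 stem.
#' @return An `h3_geometry` list: `alpha101`, `tau101`, `label`, `stem_ids`
#'   (labels of the four stem residues, e.g. `"100B"`), `source_id`.
#' @export
compute_h3_angles <- function(chain) {
  stem <- stem_residues(chain)
  ca <- lapply(stem, residue_ca)
  tau <- pseudo_bond_angle(ca[[2]], ca[[3]], ca[[4]])
  alpha <- pseudo_dihedral(ca[[1]], ca[[2]], ca[[3]], ca[[4]])
  structure(list(
    alpha101 = alpha, tau101 = tau,
    label = classify_h3(alpha, tau),
    stem_ids = vapply(stem, function(r) paste0(r$number, r$ins), ""),
    source_id = chain$source_id), class = "h3_geometry")
}

#' @export
print.h3_geometry <- function(x, ...) {
  cat(sprintf("<h3_geometry %s> alpha101 = %.2f, tau101 = %.2f -> %s\n",
              x$source_id, x$alpha101, x$tau101, x$label))
  invisible(x)
}

#' Stem-angle table for a cohort of chains
#'
#' @param chains List of numbered `vhh_chain` objects. Chains whose stem
#'   cannot be resolved are skipped with a warning.
#' @return Data frame: `source_id`, `alpha101`, `tau101`, `label`,
#'   `cdr3_len`.
#' @export
classify_cohort <- function(chains) {
  rows <- lapply(chains, function(ch) {
    g <- tryCatch(compute_h3_angles(ch), error = function(e) {
      warning("skipping ", ch$source_id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(g)) return(NULL)
    data.frame(source_id = ch$source_id, alpha101 = g$alpha101,
               tau101 = g$tau101, label = g$label,
               cdr3_len = cdr_length(ch, "CDR3"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Least-squares superposition RMSD over selected positions
#'
#' Optimal rigid-body (Kabsch, SVD) superposition of the CA atoms of
#' `position_set` in `chainB` onto `chainA`, returning the post-fit RMSD.
#'
#' @param chainA,chainB Numbered `vhh_chain` objects.
#' @param position_set Chothia positions as integers, or labels such as
#'   `"100A"` for insertion-coded residues.
#' @return RMSD in Angstrom.
#' @export
superpose_and_rmsd <- function(chainA, chainB, position_set) {
  split_label <- function(p) {
    p <- as.character(p)
    num <- as.integer(sub("([0-9]+).*", "\\1", p))
    ins <- sub("[0-9]+", "", p)
    list(num = num, ins = ins)
  }
  get_ca <- function(chain, p) {
    lb <- split_label(p)
    r <- find_residue(chain, lb$num, lb$ins)
    if (is.null(r)) stop("position ", p, " absent from ", chain$source_id)
    ca <- residue_ca(r)
    if (is.null(ca)) stop("position ", p, " lacks CA in ", chain$source_id)
    ca
  }
  A <- t(vapply(position_set, function(p) get_ca(chainA, p), numeric(3)))
  B <- t(vapply(position_set, function(p) get_ca(chainB, p), numeric(3)))
  if (nrow(A) < 3L) stop("need at least 3 common positions")
  kabsch_rmsd(A, B)
}

# Kabsch: optimal rotation of B onto A after centering; returns RMSD
kabsch_rmsd <- function(A, B) {
  Ac <- scale(A, center = TRUE, scale = FALSE)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- Bc %*% t(R)
  sqrt(mean(rowSums((Bfit - Ac)^2)))
}
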