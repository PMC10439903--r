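# Residue contacts and the C-terminally anchored CDR-H3 insert numbering.

#' C-terminally anchored insert numbering of the CDR-H3 loop
#'
#' I1 is the residue immediately preceding Chothia 101 in chain order
#' ("100x"); Ik walks backward through the CDR-H3 toward position 95, for at
#' most 21 positions. Only residues whose base number lies in 95--102 are
#' indexed.
#'
#' @param chain A numbered `vhh_chain`.
#' @return Named integer vector mapping `"I1"`, `"I2"`, ... to positional
#'   residue indices within the chain.
#' @export
insert_index <- function(chain) {
  i101 <- residue_index(chain, 101L)
  if (is.na(i101) || i101 < 2L) stop("position 101 absent or first in chain")
  out <- integer(0)
  k <- 1L
  i <- i101 - 1L
  while (i >= 1L && k <= 21L) {
    r <- chain$residues[[i]]
    if (r$number < 95L || r$number > 102L) break
    out[paste0("I", k)] <- i
    k <- k + 1L
    i <- i - 1L
  }
  out
}

#' Minimum heavy-atom distance between two residues
#'
#' @param resA,resB `vhh_residue` objects (atom tables are heavy atoms).
#' @return Minimum pairwise atom distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(resA, resB) {
  A <- as.matrix(resA$atoms[, c("x", "y", "z")])
  B <- as.matrix(resB$atoms[, c("x", "y", "z")])
  if (nrow(A) == 0L || nrow(B) == 0L) stop("residue with no heavy atoms")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Residue contact predicate
#'
#' Two residues are in contact when any heavy-atom pair is 4 Angstrom or
#' less apart (inclusive cutoff).
#'
#' @param resA,resB `vhh_residue` objects.
#' @param cutoff Distance cutoff in Angstrom, default 4.0.
#' @return Logical.
#' @export
residue_contact <- function(resA, resB, cutoff = 4.0) {
  min_heavy_atom_distance(resA, resB) <= cutoff
}

# column labels of the contact map: I21..I1 then fixed positions 101-105
contact_map_columns <- function() {
  c(paste0("I", 21:1), as.character(101:105))
}

#' Cohort contact map between FWR2 and the C-anchored CDR-H3
#'
#' For every structure, contacts (minimum heavy-atom distance <= `cutoff`)
#' are computed between each FWR2 residue (Chothia 33--51) and each CDR-H3
#' column: insert positions I21..I1 plus the fixed positions 101--105. The
#' summary is the fraction of structures showing each contact; a structure
#' lacking a column position (short loop) is excluded from that column's
#' denominator. Position frequency matrices are built from the same
#' sequences.
#'
#' @param chains List of numbered `vhh_chain` objects (typically one
#'   conformation subset).
#' @param cutoff Contact cutoff in Angstrom, default 4.0 (inclusive).
#' @return A `contact_map_summary`: `fraction` (rows FWR2 positions 33--51,
#'   columns I21..I1, 101--105), `counts`, `denominator`, `n_structures`,
#'   `pfm_fwr2`, `pfm_cdr3`.
#' @export
cohort_contact_map <- function(chains, cutoff = 4.0) {
  fw_pos <- as.character(33:51)
  cols <- contact_map_columns()
  counts <- matrix(0L, length(fw_pos), length(cols),
                   dimnames = list(fw_pos, cols))
  denom <- matrix(0L, length(fw_pos), length(cols),
                  dimnames = list(fw_pos, cols))
  aa_fw <- matrix(NA_character_, length(chains), length(fw_pos),
                  dimnames = list(NULL, fw_pos))
  aa_h3 <- matrix(NA_character_, length(chains), length(cols),
                  dimnames = list(NULL, cols))
  for (si in seq_along(chains)) {
    ch <- chains[[si]]
    idx <- insert_index(ch)
    col_res <- setNames(vector("list", length(cols)), cols)
    for (nm in names(idx)) col_res[[nm]] <- ch$residues[[idx[[nm]]]]
    for (p in 101:105) {
      r <- find_residue(ch, p)
      if (!is.null(r)) col_res[[as.character(p)]] <- r
    }
    fw_res <- setNames(vector("list", length(fw_pos)), fw_pos)
    for (p in 33:51) fw_res[[as.character(p)]] <- find_residue(ch, p)
    for (ci in seq_along(cols)) {
      rc <- col_res[[ci]]
      if (is.null(rc)) next
      aa_h3[si, ci] <- rc$aa
      for (fi in seq_along(fw_pos)) {
        rf <- fw_res[[fi]]
        if (is.null(rf)) next
        denom[fi, ci] <- denom[fi, ci] + 1L
        if (residue_contact(rf, rc, cutoff))
          counts[fi, ci] <- counts[fi, ci] + 1L
      }
    }
    for (fi in seq_along(fw_pos))
      if (!is.null(fw_res[[fi]])) aa_fw[si, fi] <- fw_res[[fi]]$aa
  }
  frac <- counts / denom
  frac[denom == 0L] <- NA_real_
  structure(list(fraction = frac, counts = counts, denominator = denom,
                 n_structures = length(chains),
                 pfm_fwr2 = position_frequency_matrix(aa_fw),
                 pfm_cdr3 = position_frequency_matrix(aa_h3)),
            class = "contact_map_summary")
}

#' @export
print.contact_map_summary <- function(x, ...) {
  nz <- which(!is.na(x$fraction) & x$fraction > 0, arr.ind = TRUE)
  cat(sprintf("<contact_map_summary> %d structures, %d contacting pairs\n",
              x$n_structures, nrow(nz)))
  invisible(x)
}

#' Contact map in long format
#'
#' @param map A `contact_map_summary`.
#' @return Data frame `fwr2_pos`, `insert_pos`, `fraction`, `n`.
#' @export
contact_map_long <- function(map) {
  df <- expand.grid(fwr2_pos = rownames(map$fraction),
                    insert_pos = colnames(map$fraction),
                    stringsAsFactors = FALSE)
  df$fraction <- as.vector(map$fraction)
  df$n <- as.vector(map$denominator)
  df[df$n > 0, , drop = FALSE]
}
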