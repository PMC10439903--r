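# Data model for Chothia-numbered VHH chains.
#
# A `vhh_chain` is an ordered list of residues; each residue carries its
# Chothia number, insertion code, one-letter amino acid and a heavy-atom
# table. Chothia numbers are labels, never indices: all internal indexing is
# positional (1-based into the residue list).

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- setNames(names(AA_321), unname(AA_321))

#' Construct a residue of a numbered chain
#'
#' @param number Chothia number (integer label).
#' @param ins Insertion code, single character or `""`.
#' @param aa One-letter amino-acid code (`"X"` for unknown).
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (heavy atoms only, coordinates in Angstrom).
#' @return A `vhh_residue` list.
#' @export
new_residue <- function(number, ins = "", aa = "X", atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in residue ", number, ins)
  structure(list(number = as.integer(number), ins = as.character(ins),
                 aa = aa, atoms = atoms),
            class = "vhh_residue")
}

#' Construct a numbered chain
#'
#' @param chain_id Chain identifier (e.g. `"A"`).
#' @param residues List of [new_residue()] objects in chain order.
#' @param source_id Structure identifier, e.g. PDB code plus chain.
#' @param numbered Logical; `TRUE` for Chothia-numbered VHH chains, `FALSE`
#'   for antigen chains whose numbers are plain author numbering.
#' @return A `vhh_chain` object.
#' @export
new_chain <- function(chain_id, residues, source_id = chain_id, numbered = TRUE) {
  keys <- vapply(residues, function(r) paste0(r$number, r$ins), "")
  if (anyDuplicated(keys))
    stop("duplicate (number, insertion code) in chain ", source_id)
  structure(list(chain_id = chain_id, residues = residues,
                 source_id = source_id, numbered = numbered),
            class = "vhh_chain")
}

#' @export
print.vhh_chain <- function(x, ...) {
  cat(sprintf("<vhh_chain %s> %d residues, %s\n", x$source_id,
              length(x$residues),
              if (x$numbered) "Chothia-numbered" else "unnumbered"))
  invisible(x)
}

#' Amino-acid sequence of a chain
#'
#' @param chain A `vhh_chain`.
#' @return One-letter amino-acid string in residue order.
#' @export
chain_sequence <- function(chain) {
  paste(vapply(chain$residues, function(r) r$aa, ""), collapse = "")
}

#' C-alpha coordinate of one residue
#'
#' @param res A `vhh_residue`.
#' @return Numeric length-3 vector, or `NULL` when the residue has no CA atom.
#' @export
residue_ca <- function(res) {
  i <- match("CA", res$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

#' Find a residue by Chothia number and insertion code
#'
#' @param chain A numbered `vhh_chain`.
#' @param number Chothia number.
#' @param ins Insertion code (`""` for none).
#' @return The residue, or `NULL` if absent.
#' @export
find_residue <- function(chain, number, ins = "") {
  for (r in chain$residues)
    if (r$number == number && r$ins == ins) return(r)
  NULL
}

# positional index of the residue labelled (number, ins); NA if absent
residue_index <- function(chain, number, ins = "") {
  for (i in seq_along(chain$residues)) {
    r <- chain$residues[[i]]
    if (r$number == number && r$ins == ins) return(i)
  }
  NA_integer_
}

#' Chothia region definitions for the VHH variable domain
#'
#' Inclusive Chothia intervals partitioning positions 1--113:
#' FWR1 1--25, CDR1 26--32, FWR2 33--51, CDR2 52--56, FWR3 57--94,
#' CDR3 95--102, FWR4 103--113. Insertion-coded residues belong to the
#' region of their base number.
#'
#' @return Named list of `c(from, to)` integer pairs.
#' @export
region_map <- function() {
  list(FWR1 = c(1L, 25L),  CDR1 = c(26L, 32L), FWR2 = c(33L, 51L),
       CDR2 = c(52L, 56L), FWR3 = c(57L, 94L), CDR3 = c(95L, 102L),
       FWR4 = c(103L, 113L))
}

#' Region of a Chothia position
#'
#' @param number Chothia base number (insertion codes are ignored: an
#'   insertion-coded residue belongs to the region of its base number).
#' @return Region name, or `NA` outside 1--113.
#' @export
region_of <- function(number) {
  rm <- region_map()
  for (nm in names(rm))
    if (number >= rm[[nm]][1] && number <= rm[[nm]][2]) return(nm)
  NA_character_
}

#' Residues of a chain falling in one region
#'
#' @param chain A numbered `vhh_chain`.
#' @param region One of `"FWR1"`, `"CDR1"`, `"FWR2"`, `"CDR2"`, `"FWR3"`,
#'   `"CDR3"`, `"FWR4"`.
#' @return List of residues in chain order (insertion-coded residues
#'   included with their base number's region).
#' @export
region_residues <- function(chain, region) {
  iv <- region_map()[[region]]
  if (is.null(iv)) stop("unknown region: ", region)
  res <- Filter(function(r) r$number >= iv[1] && r$number <= iv[2],
                chain$residues)
  if (length(res) == 0L)
    warning("region ", region, " absent from chain ", chain$source_id)
  res
}

#' CDR loop length
#'
#' Residue count of a CDR including insertion-coded residues.
#'
#' @param chain A numbered `vhh_chain`.
#' @param cdr `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @return Integer length.
#' @export
cdr_length <- function(chain, cdr = "CDR3") {
  stopifnot(cdr %in% c("CDR1", "CDR2", "CDR3"))
  length(suppressWarnings(region_residues(chain, cdr)))
}

#' Deduplicate VHH chains by exact sequence identity
#'
#' Keeps one representative per exact amino-acid sequence; the representative
#' is the first chain in input order (100% identity cut-off).
#'
#' @param chains List of `vhh_chain` objects.
#' @return List of unique chains, input order preserved.
#' @export
split_and_dedupe <- function(chains) {
  seqs <- vapply(chains, chain_sequence, "")
  chains[!duplicated(seqs)]
}

#' Remove structures by source identifier
#'
#' Supports manual exclusion of mis-classified outliers via an explicit list.
#'
#' @param chains List of `vhh_chain` objects.
#' @param exclusion_ids Character vector of `source_id`s to drop.
#' @return Remaining chains; ids not present trigger a warning, removals are
#'   reported via `message()`.
#' @export
apply_exclusion_list <- function(chains, exclusion_ids) {
  if (length(exclusion_ids) == 0L) return(chains)
  ids <- vapply(chains, function(ch) ch$source_id, "")
  missing <- setdiff(exclusion_ids, ids)
  if (length(missing) > 0L)
    warning("exclusion ids not present: ", paste(missing, collapse = ", "))
  drop <- ids %in% exclusion_ids
  if (any(drop))
    message("excluded ", sum(drop), " structure(s): ",
            paste(ids[drop], collapse = ", "))
  out <- chains[!drop]
  if (length(out) == 0L) warning("exclusion list removed every structure")
  out
}

# flat heavy-atom table of a chain: residue positional index + atom rows
chain_atom_table <- function(chain) {
  rows <- lapply(seq_along(chain$residues), function(i) {
    a <- chain$residues[[i]]$atoms
    if (nrow(a) == 0L) return(NULL)
    cbind(res_idx = i, a)
  })
  do.call(rbind, rows)
}
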