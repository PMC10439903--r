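# PDB reading/writing. Parsing is delegated to bio3d; this layer resolves
# alternate locations, drops hydrogens, and builds the numbered-chain model.

#' Read a Chothia-numbered antibody structure from a PDB file
#'
#' Residue numbers of the named VHH chains are taken as Chothia numbers with
#' insertion codes (SAbDab dialect). Hydrogens are dropped; alternate
#' locations are resolved to the highest occupancy (ties: first listed).
#' All remaining chains are returned as unnumbered antigen chains.
#'
#' @param path Path to a PDB file.
#' @param vhh_chain_ids Character vector of chain ids holding VHH domains.
#' @param source_id Identifier recorded on the chains; defaults to the file
#'   base name.
#' @return A `vhh_complex`: list with `vhh` (list of numbered `vhh_chain`),
#'   `antigen` (list of unnumbered chains) and `source_id`.
#' @export
read_numbered_pdb <- function(path, vhh_chain_ids, source_id = NULL) {
  if (is.null(source_id))
    source_id <- sub("\\.pdb$", "", basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # drop hydrogens/deuterium
  elem <- bio3d::atom2ele(at$elety)
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  missing_chains <- setdiff(vhh_chain_ids, unique(at$chain))
  if (length(missing_chains) > 0L)
    stop("chain id(s) not found in ", path, ": ",
         paste(missing_chains, collapse = ", "))
  build_chain <- function(cid, numbered) {
    sub <- at[at$chain == cid, , drop = FALSE]
    key <- paste(sub$resno, sub$insert, sep = "|")
    residues <- lapply(unique(key), function(k) {
      ra <- sub[key == k, , drop = FALSE]
      # altloc: per atom name keep highest occupancy, ties -> first listed
      keep <- unlist(lapply(split(seq_len(nrow(ra)), ra$elety), function(ix) {
        ix[which.max(ra$o[ix])]
      }))
      ra <- ra[sort(keep), , drop = FALSE]
      aa <- AA_321[ra$resid[1]]
      if (is.na(aa)) aa <- "X"
      new_residue(ra$resno[1], ra$insert[1], unname(aa),
                  data.frame(name = ra$elety,
                             element = bio3d::atom2ele(ra$elety),
                             x = ra$x, y = ra$y, z = ra$z,
                             stringsAsFactors = FALSE))
    })
    if (numbered) {
      # stable sort by number; insertion codes stay in file order
      ord <- order(vapply(residues, function(r) r$number, 1L))
      residues <- residues[ord]
      ch <- new_chain(cid, residues, paste0(source_id, ".", cid), TRUE)
      # flag CDR-H3 residues lacking CA (needed by all geometry downstream)
      h3 <- Filter(function(r) r$number >= 95 && r$number <= 102, ch$residues)
      no_ca <- Filter(function(r) is.null(residue_ca(r)), h3)
      if (length(no_ca) > 0L)
        warning("chain ", ch$source_id, ": ", length(no_ca),
                " CDR-H3 residue(s) without CA atom")
      ch
    } else {
      new_chain(cid, residues, paste0(source_id, ".", cid), FALSE)
    }
  }
  vhh <- lapply(vhh_chain_ids, build_chain, numbered = TRUE)
  other_ids <- setdiff(unique(at$chain), vhh_chain_ids)
  antigen <- lapply(other_ids, build_chain, numbered = FALSE)
  structure(list(vhh = vhh, antigen = antigen, source_id = source_id),
            class = "vhh_complex")
}

#' @export
print.vhh_complex <- function(x, ...) {
  cat(sprintf("<vhh_complex %s> %d VHH chain(s), %d antigen chain(s)\n",
              x$source_id, length(x$vhh), length(x$antigen)))
  invisible(x)
}

#' Write chains to a PDB file
#'
#' @param chains A `vhh_chain`, a list of chains, or a `vhh_complex`.
#' @param path Output file path.
#' @param b Optional per-residue values for the B-factor column (list parallel
#'   to `chains`, each a numeric vector per residue; used to store pLDDT in
#'   predicted-model files). Defaults to 0.
#' @return `path`, invisibly.
#' @export
write_numbered_pdb <- function(chains, path, b = NULL) {
  if (inherits(chains, "vhh_complex")) chains <- c(chains$vhh, chains$antigen)
  if (inherits(chains, "vhh_chain")) chains <- list(chains)
  rows <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    for (ri in seq_along(ch$residues)) {
      r <- ch$residues[[ri]]
      a <- r$atoms
      resid3 <- AA_123[r$aa]
      if (is.na(resid3)) resid3 <- "UNK"
      bv <- if (is.null(b)) 0 else b[[ci]][ri]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch$chain_id, resno = r$number, insert = r$ins,
        resid = unname(resid3), elety = a$name,
        x = a$x, y = a$y, z = a$z, b = bv, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(tab[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = tab$resno,
                   resid = tab$resid, eleno = seq_len(nrow(tab)),
                   elety = tab$elety, chain = tab$chain,
                   insert = ifelse(tab$insert == "", NA, tab$insert),
                   o = rep(1, nrow(tab)), b = tab$b)
  invisible(path)
}

#' Read a predicted-model PDB with per-residue confidence
#'
#' Predicted structure models store the per-residue confidence estimate
#' (pLDDT, 0--100) in the B-factor column; the CA B-factor of each residue
#' is taken as its confidence.
#'
#' @param path Path to a predicted-model PDB file.
#' @param chain_id Chain id of the VHH model.
#' @param source_id Optional identifier.
#' @return A `predicted_model`: `vhh_chain` plus `$plddt`, a numeric vector
#'   parallel to the residues.
#' @export
read_predicted_model <- function(path, chain_id = "A", source_id = NULL) {
  cx <- read_numbered_pdb(path, chain_id, source_id)
  ch <- cx$vhh[[1]]
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$chain == chain_id, ]
  at$insert[is.na(at$insert)] <- ""
  plddt <- vapply(ch$residues, function(r) {
    sel <- at$resno == r$number & at$insert == r$ins & at$elety == "CA"
    if (!any(sel)) return(NA_real_)
    at$b[which(sel)[1]]
  }, 1)
  if (anyNA(plddt))
    warning("residues without CA confidence in ", path)
  ch$plddt <- plddt
  class(ch) <- c("predicted_model", class(ch))
  ch
}
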