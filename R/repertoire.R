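# UMI-consensus BCR repertoire pipeline: paired FASTQ -> annotated
# V(D)J records.
#
# Library layout (5' RACE with a UMI-bearing template-switch adapter):
# reads start with a short random primer overhang, the adapter anchor, a
# 12-nt UMI split into three N-quadruplets separated by fixed T bases
# (deoxy-U in the adapter, read as T), the riboG tail, then leader + V(D)J +
# hinge + constant primer site. Read 2 comes from the constant side.

UMI_PATTERN <- "CAACGCAGAGT([ACGT]{4})T([ACGT]{4})T([ACGT]{4})TCTTGGGG"

#' Llama hinge signatures used for isotype assignment
#'
#' @return Named character vector of the four hinge-derived nucleotide
#'   signatures (IGHG1A, IGHG1B, IGHG2B, IGHG2C).
#' @export
hinge_signatures <- function() {
  c(IGHG1A = "gaactcaagacaccccaacctcaatcccaa",
    IGHG1B = "gaaccacatggaggatgcacgtgtccccaa",
    IGHG2B = "gaacccaagacaccaaaaccacaaccacaa",
    IGHG2C = "gcgcaccacagcgaagaccccagctccaag")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

translate_dna <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  s <- substr(s, 1, n)
  s <- gsub("[^ACGT]", "N", toupper(s))
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "solve"))
}

#' Extract the UMI from a read-1 sequence
#'
#' The adapter pattern (anchor, three N-quadruplets separated by fixed T
#' bases, riboG tail) is matched exactly, with no mismatch allowance. Reads
#' with zero or more than one pattern occurrence are rejected; rejects are
#' data, not errors.
#'
#' @param read1 Character vector of read-1 sequences.
#' @return Data frame with `umi` (12-nt string or `NA`), `reject_reason`
#'   (`NA`, `"no UMI"` or `"multiple UMIs"`), and `template_start` (1-based
#'   position just after the adapter; `NA` on reject).
#' @export
extract_umi <- function(read1) {
  res <- lapply(toupper(read1), function(s) {
    m <- gregexpr(UMI_PATTERN, s, perl = TRUE)[[1]]
    nhit <- if (m[1] == -1L) 0L else length(m)
    if (nhit == 0L)
      return(list(umi = NA_character_, reason = "no UMI",
                  tstart = NA_integer_))
    if (nhit > 1L)
      return(list(umi = NA_character_, reason = "multiple UMIs",
                  tstart = NA_integer_))
    frag <- regmatches(s, m)[[1]]
    g <- regmatches(frag, regexec(UMI_PATTERN, frag, perl = TRUE))[[1]]
    list(umi = paste0(g[2], g[3], g[4]), reason = NA_character_,
         tstart = as.integer(m[1] + attr(m, "match.length")[1]))
  })
  data.frame(umi = vapply(res, `[[`, "", "umi"),
             reject_reason = vapply(res, `[[`, "", "reason"),
             template_start = vapply(res, `[[`, 1L, "tstart"),
             stringsAsFactors = FALSE)
}

#' Group read pairs by UMI and apply the frequency filter
#'
#' @param umi_tab Output of [extract_umi()] (rows parallel to read pairs).
#' @param min_count Minimum reads per UMI for a group to be kept,
#'   default 10.
#' @return List with `kept` and `dropped`, each a named list of integer row
#'   index vectors keyed by UMI.
#' @export
group_and_filter <- function(umi_tab, min_count = 10) {
  ok <- which(!is.na(umi_tab$umi))
  groups <- split(ok, umi_tab$umi[ok])
  sizes <- lengths(groups)
  list(kept = groups[sizes >= min_count],
       dropped = groups[sizes < min_count])
}

# column-plurality consensus over anchored equal-start sequences;
# ties -> N; returns seq plus per-column agreement fraction
plurality_consensus <- function(seqs) {
  if (length(seqs) == 0L) stop("empty group")
  mlen <- max(nchar(seqs))
  mat <- matrix(NA_character_, length(seqs), mlen)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    mat[i, seq_along(ch)] <- ch
  }
  cons <- character(mlen)
  supp <- numeric(mlen)
  for (j in seq_len(mlen)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    tb <- table(col)
    mx <- max(tb)
    winners <- names(tb)[tb == mx]
    cons[j] <- if (length(winners) == 1L) winners else "N"
    supp[j] <- mx / length(col)
  }
  list(seq = paste(cons, collapse = ""), support = supp)
}

#' Consensus sequences of one UMI group
#'
#' Read-1 members are anchored at the end of the UMI adapter pattern before
#' the per-column plurality vote (ties give `N`); read-2 members are
#' position-anchored at their start. Consensus is computed separately for
#' the two mates.
#'
#' @param r1,r2 Character vectors of the group's read sequences.
#' @param template_start Integer vector: per-read position just after the
#'   adapter in read 1 (from [extract_umi()]).
#' @return List with `r1`, `r2`, each `list(seq, support)`.
#' @export
consensus <- function(r1, r2, template_start) {
  if (length(r1) == 0L) stop("empty group")
  anchored <- substr(r1, template_start, nchar(r1))
  list(r1 = plurality_consensus(toupper(anchored)),
       r2 = plurality_consensus(toupper(r2)))
}

#' Merge a consensus read pair by best ungapped overlap
#'
#' Read 2 is reverse-complemented and slid along read 1; admissible
#' overlaps are at least `min_overlap` long with a mismatch fraction of at
#' most `max_mismatch_frac`. The overlap maximising (matches - mismatches)
#' wins (ties: longer overlap); disagreeing overlap columns are resolved by
#' the higher per-column support.
#'
#' @param cons1,cons2 `list(seq, support)` from [consensus()], or plain
#'   strings (support then defaults to 1).
#' @param min_overlap Minimum overlap length, default 10.
#' @param max_mismatch_frac Maximum overlap mismatch fraction, default 0.25.
#' @return Merged sequence string, or `NA_character_` when no admissible
#'   overlap exists.
#' @export
merge_pair <- function(cons1, cons2, min_overlap = 10,
                       max_mismatch_frac = 0.25) {
  as_cons <- function(x) {
    if (is.character(x)) list(seq = toupper(x), support = rep(1, nchar(x)))
    else x
  }
  c1 <- as_cons(cons1)
  c2 <- as_cons(cons2)
  s1 <- strsplit(c1$seq, "")[[1]]
  rc2seq <- revcomp(c2$seq)
  s2 <- strsplit(rc2seq, "")[[1]]
  sup2 <- rev(c2$support)
  n1 <- length(s1); n2 <- length(s2)
  best <- NULL
  for (o in seq_len(n1)) {  # rc2[1] aligned to R1 position o
    L <- min(n1 - o + 1L, n2)
    if (L < min_overlap) next
    a <- s1[o:(o + L - 1L)]
    b <- s2[seq_len(L)]
    cmp <- a == b & a != "N" & b != "N"
    mm <- sum(!cmp & a != "N" & b != "N")
    if (mm / L > max_mismatch_frac) next
    score <- sum(cmp) - mm
    if (is.null(best) || score > best$score ||
        (score == best$score && L > best$L))
      best <- list(o = o, L = L, score = score)
  }
  if (is.null(best)) return(NA_character_)
  o <- best$o; L <- best$L
  ov <- character(L)
  for (k in seq_len(L)) {
    a <- s1[o + k - 1L]; b <- s2[k]
    ov[k] <- if (a == b) a
    else if (a == "N") b
    else if (b == "N") a
    else if (c1$support[o + k - 1L] >= sup2[k]) a else b
  }
  paste0(paste(s1[seq_len(o - 1L)], collapse = ""),
         paste(ov, collapse = ""),
         if (n2 > L) paste(s2[(L + 1L):n2], collapse = "") else "")
}

local_align <- function(seq, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(aln),
       read_start = Biostrings::start(Biostrings::pattern(aln)),
       read_end = Biostrings::end(Biostrings::pattern(aln)),
       ref_start = Biostrings::start(Biostrings::subject(aln)),
       ref_end = Biostrings::end(Biostrings::subject(aln)))
}

#' Assign a germline segment to a sequence
#'
#' V and J segments are assigned by best local alignment (match +1,
#' mismatch -2, gap open -5, gap extend -2); the winner is the maximum
#' score, ties resolved by reference order. For V the trim position is the
#' last (most 3') reference position covered by the alignment; for J it is
#' the first (most 5') covered position. D segments are assigned inside the
#' V--J junction window only, requiring a contiguous exact match of at
#' least `min_d_match` nucleotides; ties prefer the longer match, then the
#' 5'-most.
#'
#' @param seq Nucleotide sequence (merged consensus).
#' @param refs Named character vector of reference sequences.
#' @param side `"V"`, `"J"` or `"D"`.
#' @param window For `side = "D"`: the junction subsequence to search.
#' @param min_d_match Minimum exact D match length, default 5.
#' @param score_floor Minimum admissible alignment score (V/J); below it the
#'   segment is unassigned (`id = NA`).
#' @return List `id`, `score`, `trim_pos`, `read_start`, `read_end`
#'   (for D: `id`, `match_length`, `window_start`).
#' @export
assign_segment <- function(seq, refs, side = c("V", "J", "D"),
                           window = NULL, min_d_match = 5,
                           score_floor = 0) {
  side <- match.arg(side)
  if (length(refs) == 0L) stop("empty reference set")
  if (side == "D") {
    stopifnot(!is.null(window))
    best <- list(id = NA_character_, match_length = 0L,
                 window_start = NA_integer_)
    if (nchar(window) >= min_d_match) {
      for (id in names(refs)) {
        hit <- longest_common_substring(window, toupper(refs[[id]]))
        if (hit$length >= min_d_match &&
            (hit$length > best$match_length ||
             (hit$length == best$match_length &&
              !is.na(best$window_start) && hit$start < best$window_start)))
          best <- list(id = id, match_length = hit$length,
                       window_start = hit$start)
      }
    }
    return(best)
  }
  best <- NULL
  for (id in names(refs)) {
    al <- local_align(toupper(seq), toupper(refs[[id]]))
    if (is.null(best) || al$score > best$al$score)
      best <- list(id = id, al = al)
  }
  if (best$al$score < score_floor)
    return(list(id = NA_character_, score = best$al$score,
                trim_pos = NA_integer_, read_start = NA_integer_,
                read_end = NA_integer_))
  list(id = best$id, score = best$al$score,
       trim_pos = if (side == "V") best$al$ref_end else best$al$ref_start,
       ref_start = best$al$ref_start, ref_end = best$al$ref_end,
       read_start = best$al$read_start, read_end = best$al$read_end)
}

# longest common substring (exact); returns length and 1-based start in `a`
longest_common_substring <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best_len <- 0L; best_start <- NA_integer_
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (A[i] == B[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best_len) {
          best_len <- cur[j]
          best_start <- i - cur[j] + 1L
        }
      }
    }
    prev <- cur
  }
  list(length = best_len, start = best_start)
}

#' Junction metrics of one annotated sequence
#'
#' `np_d_length` counts the nucleotides strictly between the trimmed V end
#' and the trimmed J start (N/P additions plus the retained D segment).
#' The CDR-H3 is the translated region from 3 codons after the conserved
#' framework-3 cysteine through the residue before the conserved Trp-Gly
#' of framework 4 (encoded in J). A sequence is in frame when the V-start
#' to J-end stretch has length divisible by 3 and translates without
#' internal stops.
#'
#' @param seq Merged nucleotide sequence.
#' @param v,j Results of [assign_segment()] for V and J.
#' @return List `np_d_length`, `cdr3_aa`, `cdr3_length`, `in_frame`,
#'   `anchors_found`.
#' @export
junction_metrics <- function(seq, v, j) {
  seq <- toupper(seq)
  out <- list(np_d_length = NA_integer_, cdr3_aa = NA_character_,
              cdr3_length = NA_integer_, in_frame = FALSE,
              anchors_found = FALSE)
  if (is.na(v$id) || is.na(j$id)) return(out)
  out$np_d_length <- j$read_start - v$read_end - 1L
  # read position of V reference position 1 (extrapolated if clipped)
  p0 <- v$read_start - (v$ref_start - 1L)
  p1 <- j$read_end
  if (p0 < 1L || p1 <= p0) return(out)
  region <- substr(seq, p0, p1)
  out$in_frame <- nchar(region) %% 3 == 0
  aa <- translate_dna(region)
  if (out$in_frame && grepl("\\*", sub("\\*$", "", aa)))
    out$in_frame <- FALSE
  aa_v <- strsplit(aa, "")[[1]]
  if (length(aa_v) == 0L) return(out)
  # conserved Cys: last C at or before the codon containing the V trim
  v_end_codon <- ceiling((v$read_end - p0 + 1L) / 3)
  cys_candidates <- which(aa_v == "C" &
                            seq_along(aa_v) <= min(v_end_codon, length(aa_v)))
  if (length(cys_candidates) == 0L) return(out)
  cys <- max(cys_candidates)
  w <- NA_integer_
  if (cys + 4L > length(aa_v) - 1L) return(out)
  for (k in seq(cys + 4L, length(aa_v) - 1L)) {
    if (aa_v[k] == "W" && aa_v[k + 1L] == "G" &&
        (k + 3L > length(aa_v) || aa_v[k + 3L] == "G")) { w <- k; break }
  }
  if (is.na(w) || w - 1L < cys + 3L) return(out)
  out$anchors_found <- TRUE
  out$cdr3_aa <- paste(aa_v[(cys + 3L):(w - 1L)], collapse = "")
  out$cdr3_length <- w - 1L - (cys + 3L) + 1L
  out
}

#' Assign the heavy-chain isotype from hinge signatures
#'
#' Exact, case-insensitive substring match against the four llama hinge
#' sequences. Exactly one hit assigns the isotype; zero hits or hits to
#' more than one distinct isotype give `"unassigned"`.
#'
#' @param merged_seq Character vector of merged sequences.
#' @return Character vector of `"IGHG1A"`, `"IGHG1B"`, `"IGHG2B"`,
#'   `"IGHG2C"` or `"unassigned"`.
#' @export
assign_isotype <- function(merged_seq) {
  sigs <- toupper(hinge_signatures())
  vapply(toupper(merged_seq), function(s) {
    hits <- names(sigs)[vapply(sigs, function(p) grepl(p, s, fixed = TRUE),
                               TRUE)]
    if (length(hits) == 1L) hits else "unassigned"
  }, "", USE.NAMES = FALSE)
}

#' Run the repertoire pipeline on paired reads
#'
#' UMI extraction, frequency filtering, per-UMI consensus, pair merging,
#' V/D/J assignment, junction metrics and isotype assignment.
#'
#' @param r1,r2 Character vectors of read sequences (pairs row-parallel), or
#'   paths to FASTQ files.
#' @param germlines List with named character vectors `V`, `D`, `J`.
#' @param min_umi_count UMI frequency threshold, default 10.
#' @param min_overlap,max_mismatch_frac Passed to [merge_pair()].
#' @param v_score_floor Minimum V alignment score, default 50.
#' @return List with `records` (data frame: one row per kept UMI group) and
#'   `funnel` (read-accounting counts).
#' @export
run_repertoire <- function(r1, r2, germlines, min_umi_count = 10,
                           min_overlap = 10, max_mismatch_frac = 0.25,
                           v_score_floor = 50) {
  if (length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
  if (length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
  stopifnot(length(r1) == length(r2))
  umi_tab <- extract_umi(r1)
  groups <- group_and_filter(umi_tab, min_umi_count)
  funnel <- list(
    raw_pairs = length(r1),
    with_single_umi = sum(!is.na(umi_tab$umi)),
    rejected_no_umi = sum(umi_tab$reject_reason %in% "no UMI"),
    rejected_multiple_umi = sum(umi_tab$reject_reason %in% "multiple UMIs"),
    umi_groups = length(groups$kept) + length(groups$dropped),
    umi_groups_kept = length(groups$kept),
    umi_groups_dropped = length(groups$dropped))
  rows <- list()
  n_unmerged <- 0L
  for (umi in names(groups$kept)) {
    ix <- groups$kept[[umi]]
    cons <- consensus(r1[ix], r2[ix], umi_tab$template_start[ix])
    merged <- merge_pair(cons$r1, cons$r2, min_overlap, max_mismatch_frac)
    if (is.na(merged)) { n_unmerged <- n_unmerged + 1L; next }
    v <- assign_segment(merged, germlines$V, "V", score_floor = v_score_floor)
    j <- assign_segment(merged, germlines$J, "J")
    d <- list(id = NA_character_)
    jm <- list(np_d_length = NA_integer_, cdr3_aa = NA_character_,
               cdr3_length = NA_integer_, in_frame = FALSE)
    if (!is.na(v$id) && !is.na(j$id) && j$read_start > v$read_end + 1L) {
      window <- substr(merged, v$read_end + 1L, j$read_start - 1L)
      d <- assign_segment(merged, germlines$D, "D", window = window)
    }
    if (!is.na(v$id) && !is.na(j$id)) jm <- junction_metrics(merged, v, j)
    rows[[length(rows) + 1L]] <- data.frame(
      umi = umi, count = length(ix), sequence = merged,
      v_call = v$id, d_call = d$id, j_call = j$id,
      v_trim = if (is.na(v$id)) NA_integer_ else v$trim_pos,
      j_trim = if (is.na(j$id)) NA_integer_ else j$trim_pos,
      np_d_len = jm$np_d_length, cdr3_aa = jm$cdr3_aa,
      cdr3_len = jm$cdr3_length, in_frame = jm$in_frame,
      isotype = assign_isotype(merged),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  funnel$unmerged <- n_unmerged
  funnel$records <- if (is.null(records)) 0L else nrow(records)
  funnel$in_frame <- if (is.null(records)) 0L else sum(records$in_frame)
  list(records = records, funnel = funnel)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Cohort usage tables and junction distributions
#'
#' @param records Record data frame from [run_repertoire()].
#' @param d_classes Optional named character vector mapping D ids to
#'   `"long"` / `"short"` length classes.
#' @return List of data frames: `v_usage`, `d_usage`, `d_class_by_v`,
#'   `j_usage_by_v`, `isotype_by_v`, `v_trim_hist`, `j_trim_hist`,
#'   `np_d_by_v`, `cdr3_len_by_v`.
#' @export
cohort_summaries <- function(records, d_classes = NULL) {
  stopifnot(is.data.frame(records))
  tab <- function(x) {
    t <- table(x, useNA = "no")
    data.frame(value = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  }
  by_v <- function(col) {
    sub <- records[!is.na(records$v_call) & !is.na(records[[col]]), ]
    out <- as.data.frame(table(v_call = sub$v_call, value = sub[[col]]),
                         stringsAsFactors = FALSE)
    names(out)[3] <- "count"
    out[out$count > 0, , drop = FALSE]
  }
  out <- list(
    v_usage = tab(records$v_call),
    d_usage = tab(records$d_call),
    j_usage_by_v = by_v("j_call"),
    isotype_by_v = by_v("isotype"),
    v_trim_hist = by_v("v_trim"),
    j_trim_hist = by_v("j_trim"),
    np_d_by_v = by_v("np_d_len"),
    cdr3_len_by_v = by_v("cdr3_len"))
  if (!is.null(d_classes)) {
    sub <- records[!is.na(records$d_call) & !is.na(records$v_call), ]
    sub$d_class <- d_classes[sub$d_call]
    cls <- as.data.frame(table(v_call = sub$v_call, d_class = sub$d_class),
                         stringsAsFactors = FALSE)
    names(cls)[3] <- "count"
    totals <- tapply(cls$count, cls$v_call, sum)
    cls$fraction <- cls$count / as.numeric(totals[cls$v_call])
    out$d_class_by_v <- cls
  }
  out
}
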