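# V(D)J / UMI read simulator with ground-truth tables.
#
# Each molecule is assembled as
#   adapter(UMI) + leader + V[1..v_trim] + NP1 + D[d5+1..len-d3] + NP2 +
#   J[j_trim..len] + hinge(isotype) + constant primer site,
# emulating a 5' RACE UMI library read as asymmetric pairs (long read 1
# from the adapter side, short read 2 from the constant side). Junction N
# bases are resampled whenever they would extend a germline match, so the
# designed trim positions remain identifiable by alignment.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# codons excluding stops and cysteines (the conserved Cys is placed
# explicitly so the CDR-H3 anchor is unique)
codon_pool <- function() {
  all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                         paste0))
  setdiff(all, c("TAA", "TAG", "TGA", "TGT", "TGC", "TGG"))
}

#' Synthetic germline reference set
#'
#' Builds a deterministic toy alpaca-like germline set: four V segments
#' (300 nt, conserved Cys codons at 22 and 96, ~12 nt differences between
#' alleles), eight D segments in the two natural length classes (long
#' IGHD1--IGHD3, 29--34 nt; short IGHD4--IGHD8, 16--19 nt; pairwise longest
#' common substring capped at 5 nt), and two J segments (48 nt, conserved
#' Trp-Gly-Gln-Gly starting at nucleotide 19).
#'
#' @param seed Integer seed.
#' @return List `V`, `D`, `J` (named character vectors), `d_class`
#'   (`"long"`/`"short"` per D id), `cys_codon` (96), `j_w_start` (19).
#' @export
synthetic_germlines <- function(seed = 7) {
  set.seed(seed)
  pool <- codon_pool()
  base_v <- sample(pool, 100, replace = TRUE)
  base_v[22] <- "TGT"
  base_v[96] <- "TGT"
  v_names <- c("IGHV3-3", "IGHV3S53", "IGHV3S61", "IGHV3S66")
  V <- setNames(character(4), v_names)
  for (k in seq_along(v_names)) {
    v <- base_v
    if (k > 1) {
      pos <- sample(setdiff(5:90, c(22, 96)), 12)
      v[pos] <- sample(pool, 12, replace = TRUE)
    }
    V[k] <- paste(v, collapse = "")
  }
  d_lens <- c(IGHD1 = 29, IGHD2 = 31, IGHD3 = 34, IGHD4 = 16, IGHD5 = 17,
              IGHD6 = 18, IGHD7 = 19, IGHD8 = 16)
  repeat {
    D <- vapply(d_lens, rand_dna, "")
    lcs_ok <- TRUE
    for (i in seq_along(D)) for (j in seq_along(D)) {
      if (i < j &&
          longest_common_substring(D[[i]], D[[j]])$length > 5)
        lcs_ok <- FALSE
    }
    if (lcs_ok) break
  }
  make_j <- function() {
    head6 <- sample(setdiff(codon_pool(), "TGG"), 6, replace = TRUE)
    tail10 <- c("TGG", "GGC", "CAA", "GGA", "ACC", "CAG", "GTC", "ACC",
                "GTC", "TCC")
    paste(c(head6, tail10), collapse = "")
  }
  J <- c(IGHJ4 = make_j(), IGHJ6 = make_j())
  list(V = V, D = D, J = J,
       d_class = setNames(ifelse(d_lens >= 29, "long", "short"),
                          names(d_lens)),
       cys_codon = 96L, j_w_start = 19L)
}

#' Reconstruct a molecule template from its truth fields
#'
#' @param row One row of the truth data frame from [simulate_repertoire()].
#' @param germlines The germline set the simulation used.
#' @return The full molecule template string.
#' @export
reconstruct_molecule <- function(row, germlines) {
  umi <- row$umi
  adapter <- paste0("AAGCAGTGGTATCAACGCAGAGT",
                    substr(umi, 1, 4), "T", substr(umi, 5, 8), "T",
                    substr(umi, 9, 12), "TCTTGGGG")
  v <- germlines$V[[row$v_id]]
  j <- germlines$J[[row$j_id]]
  d <- germlines$D[[row$d_id]]
  d_kept <- substr(d, row$d5_trim + 1L, nchar(d) - row$d3_trim)
  paste0(adapter, row$leader, substr(v, 1, row$v_trim), row$np1_seq,
         d_kept, row$np2_seq, substr(j, row$j_trim, nchar(j)),
         hinge_signatures()[[row$isotype]] |> toupper(),
         "AATCAGGGCTGCCCAAT")
}

# truncated geometric helper
rgeom_trunc <- function(n, p, max) pmin(rgeom(n, p), max)

default_repertoire_config <- function() {
  list(
    n_molecules = 100L,
    v_usage = c("IGHV3-3" = 0.35, "IGHV3S53" = 0.40, "IGHV3S61" = 0.15,
                "IGHV3S66" = 0.10),
    d_usage = NULL,                      # uniform over the D set
    j_usage = c(IGHJ4 = 0.9, IGHJ6 = 0.1),
    isotype_probs = c(IGHG1A = 0.05, IGHG1B = 0.05, IGHG2B = 0.45,
                      IGHG2C = 0.45),
    np_lambda = 4,                       # Poisson mean of each N region
    np_lambda_by_v = NULL,               # optional named overrides
    v_trim_geom_p = 0.5,                 # V trimmed in codon steps
    j_trim_min = 5, j_trim_geom_p = 0.4, j_trim_max = 12,
    j_trim_by_v = NULL,                  # optional list of j_trim pools
    d_trim_geom_p = 0.35, d_min_keep = 8L,
    reads_per_umi = 12L,
    substitution_error_rate = 0,
    read_lengths = c(400L, 100L),
    leader_length = 18L,
    max_template_length = 490L,          # gel size-selection window
    in_frame_only = TRUE)
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate a UMI-tagged V(D)J repertoire as paired reads with truth
#'
#' Deterministic per seed. Junction N regions are resampled when their
#' first/last three bases would elementwise extend the flanking germline
#' match, and junctions whose translation would contain a premature
#' CDR-H3 Trp-Gly anchor or (with `in_frame_only`) a stop codon are
#' redrawn, keeping the designed truth identifiable from the reads.
#'
#' @param germlines Germline set from [synthetic_germlines()].
#' @param config Named list overriding the defaults (sample sizes, usage
#'   probabilities, trim/N-addition distributions, reads per UMI, error
#'   rate, read lengths); see `conformap:::default_repertoire_config`.
#' @param seed Integer seed.
#' @return List `r1`, `r2` (character read vectors, row-parallel pairs),
#'   `truth` (data frame with per-molecule design), `templates`, `config`.
#' @export
simulate_repertoire <- function(germlines, config = list(), seed = 1) {
  cfg <- utils::modifyList(default_repertoire_config(), config)
  set.seed(seed)
  nm <- cfg$n_molecules
  d_usage <- cfg$d_usage %||%
    setNames(rep(1 / length(germlines$D), length(germlines$D)),
             names(germlines$D))
  v_len <- nchar(germlines$V[1])
  umis <- character(0)
  while (length(umis) < nm)
    umis <- unique(c(umis, vapply(seq_len(nm), function(i) rand_dna(12), "")))
  umis <- umis[seq_len(nm)]
  rows <- list()
  templates <- character(nm)
  r1 <- character(0); r2 <- character(0); truth_idx <- integer(0)
  for (m in seq_len(nm)) {
    v_id <- sample(names(cfg$v_usage), 1, prob = cfg$v_usage)
    j_id <- sample(names(cfg$j_usage), 1, prob = cfg$j_usage)
    d_id <- sample(names(d_usage), 1, prob = d_usage)
    isotype <- sample(names(cfg$isotype_probs), 1, prob = cfg$isotype_probs)
    vseq <- toupper(germlines$V[[v_id]])
    jseq <- toupper(germlines$J[[j_id]])
    dseq <- toupper(germlines$D[[d_id]])
    lam <- cfg$np_lambda
    if (!is.null(cfg$np_lambda_by_v) && v_id %in% names(cfg$np_lambda_by_v))
      lam <- cfg$np_lambda_by_v[[v_id]]
    ok <- FALSE
    for (attempt in 1:400) {
      v_trim <- v_len - 3L * rgeom_trunc(1, cfg$v_trim_geom_p, 3)
      j_pool <- if (!is.null(cfg$j_trim_by_v) &&
                    v_id %in% names(cfg$j_trim_by_v))
        cfg$j_trim_by_v[[v_id]]
      else seq(cfg$j_trim_min,
               min(cfg$j_trim_max, germlines$j_w_start - 1L))
      j_trim <- if (length(j_pool) == 1L) j_pool else sample(j_pool, 1)
      repeat {
        d5 <- rgeom_trunc(1, cfg$d_trim_geom_p, nchar(dseq))
        d3 <- rgeom_trunc(1, cfg$d_trim_geom_p, nchar(dseq))
        if (nchar(dseq) - d5 - d3 >= cfg$d_min_keep) break
      }
      d_kept <- substr(dseq, d5 + 1L, nchar(dseq) - d3)
      np1 <- rpois(1, lam)
      np2 <- rpois(1, lam)
      if (cfg$in_frame_only) {
        pre <- v_trim + np1 + nchar(d_kept) + np2 +
          (germlines$j_w_start - j_trim)
        np2 <- np2 + (3L - pre %% 3L) %% 3L
      }
      np1_seq <- rand_dna(np1)
      np2_seq <- rand_dna(np2)
      junction <- paste0(np1_seq, d_kept, np2_seq)
      j_kept <- substr(jseq, j_trim, nchar(jseq))
      # amplicon size selection: keep the molecule within the window the
      # paired-read design can span
      tpl_len <- 45L + cfg$leader_length + v_trim + nchar(junction) +
        nchar(j_kept) + 30L + 17L
      if (tpl_len > cfg$max_template_length) next
      # identifiability guards: junction must not extend the V or J match
      ext_v <- FALSE
      for (b in 1:3) {
        if (v_trim + b > v_len) break
        jb <- substr(paste0(junction, j_kept), b, b)
        if (jb == substr(vseq, v_trim + b, v_trim + b)) { ext_v <- TRUE; break }
      }
      ext_j <- FALSE
      full_left <- paste0(substr(vseq, 1, v_trim), junction)
      for (b in 1:3) {
        if (j_trim - b < 1L) break
        lb <- substr(full_left, nchar(full_left) - b + 1L,
                     nchar(full_left) - b + 1L)
        if (lb == substr(jseq, j_trim - b, j_trim - b)) { ext_j <- TRUE; break }
      }
      if (ext_v || ext_j) next
      coding <- paste0(full_left, j_kept)
      aa <- translate_dna(coding)
      aa_v <- strsplit(aa, "")[[1]]
      if (cfg$in_frame_only && any(aa_v == "*")) next
      # premature CDR-H3 anchor guard (only meaningful in frame)
      if (cfg$in_frame_only) {
        w_true <- (v_trim + nchar(junction) +
                     (germlines$j_w_start - j_trim)) / 3 + 1
        premature <- FALSE
        ks <- seq(germlines$cys_codon + 4L, w_true - 1L)
        if (length(ks) > 0 && ks[1] <= w_true - 1L) for (k in ks) {
          if (k + 1L <= length(aa_v) && aa_v[k] == "W" &&
              aa_v[k + 1L] == "G" &&
              (k + 3L > length(aa_v) || aa_v[k + 3L] == "G")) {
            premature <- TRUE; break
          }
        }
        if (premature) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("failed to build an identifiable junction for molecule ", m)
    leader <- rand_dna(cfg$leader_length)
    umi <- umis[m]
    cdr3_len <- if (cfg$in_frame_only) {
      w_true <- (v_trim + nchar(junction) +
                   (germlines$j_w_start - j_trim)) / 3 + 1
      as.integer(w_true - (germlines$cys_codon + 3L))
    } else NA_integer_
    row <- data.frame(
      molecule_id = m, umi = umi, leader = leader,
      v_id = v_id, v_trim = v_trim,
      d_id = d_id, d5_trim = d5, d3_trim = d3,
      np1 = np1, np2 = np2, np1_seq = np1_seq, np2_seq = np2_seq,
      np_d_length = nchar(junction),
      j_id = j_id, j_trim = j_trim,
      cdr3_length = cdr3_len, isotype = isotype,
      in_frame = cfg$in_frame_only, n_reads = cfg$reads_per_umi,
      stringsAsFactors = FALSE)
    template <- reconstruct_molecule(row, germlines)
    templates[m] <- template
    rows[[m]] <- row
    for (rd in seq_len(cfg$reads_per_umi)) {
      prefix <- rand_dna(sample(1:4, 1))
      full <- paste0(prefix, substr(template, 4, nchar(template)))
      read1 <- substr(full, 1, cfg$read_lengths[1])
      read2 <- substr(revcomp(template), 1, cfg$read_lengths[2])
      r1 <- c(r1, mutate_seq(read1, cfg$substitution_error_rate))
      r2 <- c(r2, mutate_seq(read2, cfg$substitution_error_rate))
      truth_idx <- c(truth_idx, m)
    }
  }
  ord <- sample(length(r1))  # shuffle pairs, keeping mates together
  list(r1 = r1[ord], r2 = r2[ord], read_molecule = truth_idx[ord],
       truth = do.call(rbind, rows), templates = templates, config = cfg)
}

#' Write paired reads to FASTQ files
#'
#' @param sim Output of [simulate_repertoire()].
#' @param r1_path,r2_path Output FASTQ paths (uncompressed).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(sim, r1_path, r2_path) {
  wr <- function(seqs, path, mate) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs))
      writeLines(c(sprintf("@read%06d/%d", i, mate), seqs[i], "+",
                   strrep("I", nchar(seqs[i]))), con)
  }
  wr(sim$r1, r1_path, 1)
  wr(sim$r2, r2_path, 2)
  invisible(c(r1_path, r2_path))
}
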