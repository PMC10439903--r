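# UMI extraction, consensus, merging, germline assignment, isotypes

test_that("UMI extraction follows the adapter pattern exactly", {
  mk <- function(umi) paste0("GGTATCAACGCAGAGT", substr(umi, 1, 4), "T",
                             substr(umi, 5, 8), "T", substr(umi, 9, 12),
                             "TCTTGGGG", "ACGTACGTACGT")
  got <- extract_umi(mk("ACGTGGCCTTAA"))
  expect_equal(got$umi, "ACGTGGCCTTAA")
  expect_true(is.na(got$reject_reason))
  # template_start points just past the adapter
  read <- mk("ACGTGGCCTTAA")
  expect_equal(substr(read, got$template_start, nchar(read)), "ACGTACGTACGT")
  # two occurrences -> rejected as multiple
  double <- paste0(mk("AAAACCCCGGGG"), mk("TTTTAAAACCCC"))
  got2 <- extract_umi(double)
  expect_equal(got2$reject_reason, "multiple UMIs")
  expect_true(is.na(got2$umi))
  # no anchor -> rejected
  got3 <- extract_umi("ACGTACGTACGTACGT")
  expect_equal(got3$reject_reason, "no UMI")
  # one mismatch in the fixed block kills the match (exact matching)
  broken <- sub("TCTTGGGG", "TCTTGGCG", mk("ACGTGGCCTTAA"), fixed = TRUE)
  expect_equal(extract_umi(broken)$reject_reason, "no UMI")
})

test_that("UMI grouping applies the frequency threshold", {
  umis <- c(rep("AAAACCCCGGGG", 12), rep("TTTTCCCCGGGG", 9),
            rep("AAAATTTTGGGG", 10))
  tab <- data.frame(umi = umis, reject_reason = NA_character_,
                    template_start = 1L, stringsAsFactors = FALSE)
  g <- group_and_filter(tab, 10)
  expect_setequal(names(g$kept), c("AAAACCCCGGGG", "AAAATTTTGGGG"))
  expect_equal(names(g$dropped), "TTTTCCCCGGGG")
  g9 <- group_and_filter(tab, 9)
  expect_equal(length(g9$kept), 3)
})

test_that("consensus is plurality per column with N on ties", {
  expect_equal(conformap:::plurality_consensus(rep("ACGT", 10))$seq, "ACGT")
  reads <- c(rep("AAAA", 9), "ACAA")
  expect_equal(conformap:::plurality_consensus(reads)$seq, "AAAA")
  tied <- c("AAAA", "ACAA")
  expect_equal(conformap:::plurality_consensus(tied)$seq, "ANAA")
  # anchored consensus strips variable-length prefixes
  r1 <- c(paste0("NN", "GGTATCAACGCAGAGTAAAATCCCCTGGGGTCTTGGGG", "ACGTAC"),
          paste0("N", "GGTATCAACGCAGAGTAAAATCCCCTGGGGTCTTGGGG", "ACGTAC"))
  tab <- extract_umi(r1)
  cons <- consensus(r1, c("TTTT", "TTTT"), tab$template_start)
  expect_equal(cons$r1$seq, "ACGTAC")
  expect_equal(cons$r2$seq, "TTTT")
})

test_that("pair merging finds the designed overlap and respects limits", {
  set.seed(55)
  template <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  r1 <- substr(template, 1, 100)
  r2 <- conformap:::revcomp(substr(template, 61, 160))
  merged <- merge_pair(r1, r2)
  expect_equal(merged, template)
  expect_equal(nchar(merged), nchar(r1) + 60)
  # disjoint sequences do not merge
  expect_true(is.na(merge_pair(strrep("A", 50), strrep("C", 50))))
  # overlap below the minimum is rejected
  r2short <- conformap:::revcomp(substr(template, 96, 160))
  expect_true(is.na(merge_pair(r1, r2short, min_overlap = 10)))
  # disagreements resolve toward the higher-support column
  c1 <- list(seq = "AAAAAAAAAAGG", support = rep(0.6, 12))
  c2 <- list(seq = conformap:::revcomp("AAAAAAAAAATT"),
             support = rep(0.9, 12))
  m2 <- merge_pair(c1, c2, min_overlap = 10, max_mismatch_frac = 0.25)
  expect_equal(m2, "AAAAAAAAAATT")
})

test_that("segment assignment recovers trims on clean constructs", {
  gl <- synthetic_germlines()
  v <- assign_segment(gl$V[["IGHV3-3"]], gl$V, "V")
  expect_equal(v$id, "IGHV3-3")
  expect_equal(v$trim_pos, nchar(gl$V[["IGHV3-3"]]))
  # junction with no 5-mer from any D
  d <- assign_segment("X", gl$D, "D", window = "ACG")
  expect_true(is.na(d$id))
  # designed D inside a junction window
  dk <- substr(gl$D[["IGHD2"]], 3, 20)
  d2 <- assign_segment("X", gl$D, "D", window = paste0("AC", dk, "GT"))
  expect_equal(d2$id, "IGHD2")
  expect_gte(d2$match_length, nchar(dk))
  # V score floor marks unassignable sequences
  poor <- assign_segment(strrep("AT", 30), gl$V, "V", score_floor = 50)
  expect_true(is.na(poor$id))
})

test_that("junction metrics handle a V directly abutting J (np length 0)", {
  gl <- synthetic_germlines()
  vseq <- gl$V[["IGHV3S53"]]
  jseq <- gl$J[["IGHJ4"]]
  j_trim <- 7L
  # choose a codon-aligned V trim and pad J so the frame holds
  v_trim <- nchar(vseq) - 3L
  pre <- v_trim + (gl$j_w_start - j_trim)
  pad <- (3L - pre %% 3L) %% 3L
  v_trim <- v_trim - pad  # stay codon-friendly for this construct
  seq <- paste0(substr(vseq, 1, v_trim), substr(jseq, j_trim, nchar(jseq)))
  v <- assign_segment(seq, gl$V, "V")
  j <- assign_segment(seq, gl$J, "J")
  jm <- junction_metrics(seq, v, j)
  expect_equal(jm$np_d_length, 0L)
  expect_true(jm$anchors_found)
})

test_that("isotype assignment is exact, case-insensitive and order-independent", {
  sigs <- hinge_signatures()
  for (iso in names(sigs)) {
    s <- paste0("acgt", sigs[[iso]], "ACGT")
    expect_equal(assign_isotype(s), iso)
    expect_equal(assign_isotype(toupper(s)), iso)
  }
  expect_equal(assign_isotype("ACGTACGTACGT"), "unassigned")
  both <- paste0(sigs[["IGHG2B"]], sigs[["IGHG2C"]])
  expect_equal(assign_isotype(both), "unassigned")
  # one mismatch breaks the exact match
  near <- sub("aagacacc", "aagacgcc", sigs[["IGHG2B"]], fixed = TRUE)
  expect_equal(assign_isotype(near), "unassigned")
})

test_that("funnel accounting conserves reads through the pipeline", {
  gl <- synthetic_germlines()
  sim <- simulate_repertoire(gl, list(n_molecules = 12, reads_per_umi = 11),
                             seed = 3)
  # spike in reads that must be rejected / dropped
  bad <- c("ACGTACGTACGTACGTACGTACGT",
           paste0("GGTATCAACGCAGAGTAAAATCCCCTGGGGTCTTGGGGAC",
                  "GGTATCAACGCAGAGTAAAATCCCCTGGGGTCTTGGGGAC"))
  r1 <- c(sim$r1, bad)
  r2 <- c(sim$r2, c("ACGT", "ACGT"))
  res <- run_repertoire(r1, r2, gl, min_umi_count = 10)
  f <- res$funnel
  expect_equal(f$raw_pairs,
               f$with_single_umi + f$rejected_no_umi + f$rejected_multiple_umi)
  expect_equal(f$umi_groups, f$umi_groups_kept + f$umi_groups_dropped)
  expect_equal(f$umi_groups_kept, f$records + f$unmerged)
  expect_equal(f$rejected_no_umi, 1L)
  expect_equal(f$rejected_multiple_umi, 1L)
  expect_equal(f$records, 12L)
})

test_that("cohort summaries tabulate usage and junction distributions", {
  gl <- synthetic_germlines()
  sim <- simulate_repertoire(gl, list(n_molecules = 25), seed = 9)
  res <- run_repertoire(sim$r1, sim$r2, gl)
  s <- cohort_summaries(res$records, d_classes = gl$d_class)
  expect_equal(sum(s$v_usage$count), 25)
  expect_true(all(s$d_class_by_v$d_class %in% c("long", "short")))
  agg <- tapply(s$d_class_by_v$fraction, s$d_class_by_v$v_call, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  # single-germline corner
  one <- res$records[res$records$v_call == res$records$v_call[1], ]
  s1 <- cohort_summaries(one)
  expect_equal(nrow(s1$v_usage), 1)
})
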