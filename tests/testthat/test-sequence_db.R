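tx <- function(id, seq) data.frame(accession = id, description = "",
                                   sequence = seq, stringsAsFactors = FALSE)

test_that("stop-to-stop translation emits the expected ORFs with coordinates", {
  # 24 nt encoding MKMKMKMK, then a stop and a trailing start
  seq <- paste0(strrep("ATGAAA", 4), "TAAATG")
  got <- translate_three_frames(tx("t1", seq), min_len = 8)
  f0 <- got[got$frame == 0, ]
  expect_equal(f0$peptide, "MKMKMKMK")
  expect_equal(f0$start_nt, 0)
  expect_equal(f0$end_nt, 24)
  expect_equal(f0$orf_id, "orf|t1|F0|0-24")
  # the coordinates recover the emitting nucleotides exactly
  expect_equal(substr(seq, f0$start_nt + 1, f0$end_nt), strrep("ATGAAA", 4))

  # short transcript: longest segment MK (2 aa) < 8 -> nothing
  expect_equal(nrow(translate_three_frames(tx("t2", "ATGAAATAA"))), 0)

  # N-containing codon translates to X and splits the segment
  seq_n <- paste0(strrep("GCT", 8), "ANA", strrep("GCT", 8))
  got_n <- translate_three_frames(tx("t3", seq_n), min_len = 8)
  f0n <- got_n[got_n$frame == 0, ]
  expect_equal(f0n$peptide, c(strrep("A", 8), strrep("A", 8)))
  expect_false(any(grepl("X", got_n$peptide)))

  # include_terminal = FALSE keeps only stop-flanked segments
  seq_t <- paste0(strrep("GCT", 10), "TAA", strrep("GGT", 10), "TGA",
                  strrep("CCT", 10))
  all_seg <- translate_three_frames(tx("t4", seq_t), min_len = 8)
  expect_equal(sum(all_seg$frame == 0), 3)
  inner <- translate_three_frames(tx("t4", seq_t), min_len = 8,
                                  include_terminal = FALSE)
  expect_equal(inner$peptide[inner$frame == 0], strrep("G", 10))
})

test_that("translation matches the brute-force oracle on random transcripts", {
  set.seed(42)
  for (i in 1:50) {
    len <- sample(60:600, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- translate_three_frames(tx("r", seq), min_len = 8)
    want <- oracle_orfs("r", seq, min_len = 8)
    ord <- function(d) {
      d <- d[order(d$frame, d$start_nt), c("frame", "start_nt", "end_nt",
                                           "peptide")]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(got[, -1]), ord(want[, -1]))
  }
})

test_that("expression cutoff filters strictly and databases are nested", {
  txs <- rbind(tx("T1", strrep("GCT", 20)), tx("T2", strrep("GGT", 20)),
               tx("T3", strrep("CCT", 20)))
  expr <- data.frame(transcript_id = c("T1", "T2", "T3"),
                     gene_id = c("G1", "G2", "G3"),
                     value = c(0, 1.5, 7), unit = "FPKM",
                     stringsAsFactors = FALSE)
  db0 <- build_noncanonical_db(txs, expr, cutoff = 0)
  expect_setequal(unique(db0$transcript_id), c("T2", "T3"))
  db5 <- build_noncanonical_db(txs, expr, cutoff = 5)
  expect_setequal(unique(db5$transcript_id), "T3")
  expect_equal(nrow(build_noncanonical_db(txs, expr, cutoff = 10)), 0)
  expect_true(all(db5$orf_id %in% db0$orf_id))
  expect_error(build_noncanonical_db(txs, expr, cutoff = -1), ">= 0")
  # transcript missing from the table is treated as unexpressed + warning
  expect_warning(
    db_m <- build_noncanonical_db(rbind(txs, tx("T9", strrep("GCT", 20))),
                                  expr, cutoff = 0),
    "missing")
  expect_false("T9" %in% db_m$transcript_id)
})

test_that("peptide classification applies I/L equivalence and TE exceptions", {
  prot <- rbind(tx("UP1", "AAAPEPTIDEKKK"), tx("TE1", "GGGQWERTYAMMM"))
  idx <- build_proteome_index(prot)
  cls <- classify_peptides(c("PEPTLDE", "QQQQQQQQ", "QWERTYA"), idx,
                           te_whitelist = "TE1")
  expect_equal(cls$status, c("proteome", "noncanonical", "noncanonical"))
  expect_equal(cls$canonical_accessions[1], "UP1")
  expect_equal(cls$te_exception, c(FALSE, FALSE, TRUE))
  expect_equal(cls$canonical_accessions[3], "TE1")

  # invariance under I <-> L substitution anywhere in the peptide
  set.seed(9)
  base <- "PEPTIDLIK"
  variants <- vapply(1:10, function(i) {
    s <- strsplit(base, "")[[1]]
    il <- which(s %in% c("I", "L"))
    s[il] <- sample(c("I", "L"), length(il), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  prot2 <- tx("UPX", paste0("MMM", base, "WWW"))
  idx2 <- build_proteome_index(prot2)
  got <- classify_peptides(variants, idx2)
  expect_true(all(got$status == "proteome"))
  expect_error(classify_peptides("", idx2), "empty")
})

test_that("relative peptide position uses the C-terminal convention", {
  protein <- paste(rep("A", 90), collapse = "")
  protein <- paste0(substr(protein, 1, 81), "WWWWWWWWW")
  expect_equal(peptide_position_stats("WWWWWWWWW", protein), 1.0)
  protein2 <- paste0("WWWWWWWWW", strrep("A", 81))
  expect_equal(peptide_position_stats("WWWWWWWWW", protein2), 0.1)
  protein3 <- paste0(strrep("A", 10), "QWERTYKMFP", strrep("C", 80))
  expect_equal(peptide_position_stats("QWERTYKMFP", protein3), 0.2)
  expect_equal(peptide_position_stats("QWERTYKMFP", protein3,
                                      terminus = "N"), 0.1)
  expect_error(peptide_position_stats("YYYYY", protein3), "occur")
})

test_that("ORF FASTA output round-trips through read_fasta", {
  t1 <- tx("T1", paste0(strrep("GCT", 12), "TAA", strrep("GGT", 12)))
  orfs <- translate_three_frames(t1, min_len = 8)
  f <- tempfile(fileext = ".fa")
  write_orf_fasta(orfs, f)
  back <- read_fasta(f, "aa")
  expect_equal(back$accession, orfs$orf_id)
  expect_equal(back$sequence, orfs$peptide)
})
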