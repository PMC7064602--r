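# codon -> amino acid lookup from the standard genetic code; codons with
# ambiguous bases (N) translate to X
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- setNames(as.character(gc), names(gc))
  tab
})

translate_frame <- function(seq, frame) {
  n <- nchar(seq)
  n_codons <- (n - frame) %/% 3L
  if (n_codons < 1L) return(character(0))
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Translate a transcript in all three forward frames into stop-to-stop ORFs
#'
#' Each forward frame is translated with the standard genetic code and
#' split at stop codons. Segments of at least `min_len` residues are
#' emitted as ORF records whose nucleotide coordinates recover the
#' emitting codons exactly. Codons containing an ambiguous base (N)
#' translate to X and segments are additionally split at X, so no
#' fabricated residue enters the search space. Segments bounded by the
#' sequence ends (no flanking stop) are included by default.
#'
#' @param transcript one-row data frame with `accession` and `sequence`
#'   (nucleotide), e.g. a row of [read_fasta()] output.
#' @param min_len minimum ORF length in amino acids (default 8).
#' @param include_terminal keep segments that touch a sequence end rather
#'   than being flanked by stop codons on both sides.
#' @return data frame with columns `orf_id`, `transcript_id`, `frame`
#'   (0/1/2), `start_nt` (0-based inclusive), `end_nt` (0-based
#'   exclusive), `peptide`.
#' @export
translate_three_frames <- function(transcript, min_len = 8L,
                                   include_terminal = TRUE) {
  if (min_len < 1L) stop_validation("min_len must be >= 1")
  seq <- toupper(transcript$sequence[1])
  id <- transcript$accession[1]
  out <- vector("list", 3L)
  for (frame in 0:2) {
    aa <- translate_frame(seq, frame)
    if (!length(aa)) next
    keep <- !(aa %in% c("*", "X"))
    r <- rle(keep)
    ends_aa <- cumsum(r$lengths)
    starts_aa <- ends_aa - r$lengths + 1L
    segs <- which(r$values & r$lengths >= min_len)
    if (!length(segs)) next
    rows <- lapply(segs, function(s) {
      a0 <- starts_aa[s]; a1 <- ends_aa[s]
      if (!include_terminal) {
        # require a genuine stop codon on both sides
        left_ok <- a0 > 1L && aa[a0 - 1L] == "*"
        right_ok <- a1 < length(aa) && aa[a1 + 1L] == "*"
        if (!(left_ok && right_ok)) return(NULL)
      }
      start_nt <- frame + 3L * (a0 - 1L)
      end_nt <- frame + 3L * a1
      data.frame(
        orf_id = sprintf("orf|%s|F%d|%d-%d", id, frame, start_nt, end_nt),
        transcript_id = id, frame = frame,
        start_nt = start_nt, end_nt = end_nt,
        peptide = paste(aa[a0:a1], collapse = ""),
        stringsAsFactors = FALSE)
    })
    out[[frame + 1L]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(orf_id = character(0), transcript_id = character(0),
                      frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Build the non-canonical ORF database from expressed transcripts
#'
#' Translates every transcript whose expression is strictly greater than
#' `cutoff` (FPKM/TPM) in all three forward frames and keeps stop-to-stop
#' segments of at least `min_len` residues. Transcripts missing from the
#' expression table are treated as unexpressed, with a warning. Output is
#' deterministically ordered by (transcript id, frame, start).
#'
#' @param transcripts data frame of nucleotide entries ([read_fasta()]).
#' @param expr expression table ([read_expression_table()]).
#' @param cutoff strict expression cutoff; `0` keeps every transcript with
#'   any expression.
#' @inheritParams translate_three_frames
#' @export
build_noncanonical_db <- function(transcripts, expr, cutoff = 0,
                                  min_len = 8L, include_terminal = TRUE) {
  if (cutoff < 0) stop_validation("expression cutoff must be >= 0")
  value <- expr$value[match(transcripts$accession, expr$transcript_id)]
  if (anyNA(value)) {
    warning(sum(is.na(value)),
            " transcript(s) missing from the expression table; treated as",
            " expression 0")
    value[is.na(value)] <- 0
  }
  keep <- transcripts[value > cutoff, , drop = FALSE]
  keep <- keep[order(keep$accession, method = "radix"), , drop = FALSE]
  orfs <- lapply(seq_len(nrow(keep)), function(i)
    translate_three_frames(keep[i, , drop = FALSE], min_len = min_len,
                           include_terminal = include_terminal))
  res <- do.call(rbind, orfs)
  if (is.null(res))
    return(translate_three_frames(
      data.frame(accession = "x", sequence = "AAA"), min_len = 100L)[0, ])
  res <- res[order(res$transcript_id, res$frame, res$start_nt,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an ORF database as amino-acid FASTA
#' @param orfs data frame from [build_noncanonical_db()].
#' @param path output path.
#' @export
write_orf_fasta <- function(orfs, path) {
  write_fasta(data.frame(accession = orfs$orf_id, description = "",
                         sequence = orfs$peptide, stringsAsFactors = FALSE),
              path)
}

#' Build an I/L-collapsed substring index over a protein set
#'
#' Isoleucine and leucine are indistinguishable by mass spectrometry, so
#' both the proteins and query peptides are collapsed (I -> L) before
#' substring matching.
#'
#' @param proteins data frame with `accession` and `sequence` (amino acid).
#' @return a `proteome_index` holding the collapsed sequences as an
#'   `AAStringSet` plus the original lengths.
#' @export
build_proteome_index <- function(proteins) {
  collapsed <- chartr("I", "L", toupper(proteins$sequence))
  set <- Biostrings::AAStringSet(collapsed)
  names(set) <- proteins$accession
  structure(list(accessions = proteins$accession,
                 set = set,
                 lengths = nchar(proteins$sequence)),
            class = "proteome_index")
}

#' Classify peptides as proteome-derived or non-canonical
#'
#' A peptide is proteome-derived when it occurs as an exact substring
#' (under I/L equivalence) of any canonical protein — unless all of its
#' canonical matches are accessions on the transposable-element (TE)
#' whitelist, in which case it is retained as non-canonical with
#' `te_exception = TRUE`. Peptides with no canonical match are
#' non-canonical; when a non-canonical index is supplied their matching
#' ORF ids are recorded.
#'
#' @param peptides character vector of peptide sequences (modifications
#'   are stripped before matching).
#' @param canonical_index [build_proteome_index()] over the canonical
#'   proteome.
#' @param te_whitelist accessions of TE proteins integrated in the
#'   canonical set whose matches do not count as proteome evidence.
#' @param noncanonical_index optional [build_proteome_index()] over the
#'   ORF database.
#' @return data frame with columns `peptide`, `status`
#'   (`proteome`/`noncanonical`), `canonical_accessions`,
#'   `noncanonical_ids` (semicolon-separated), `te_exception`.
#' @export
classify_peptides <- function(peptides, canonical_index,
                              te_whitelist = character(0),
                              noncanonical_index = NULL) {
  if (any(nchar(peptides) == 0)) stop_validation("empty peptide")
  bare <- strip_mods(peptides)
  uq <- unique(bare)
  res <- lapply(uq, function(p) {
    q <- chartr("I", "L", p)
    hits <- Biostrings::vcountPattern(q, canonical_index$set) > 0
    acc <- canonical_index$accessions[hits]
    te <- length(acc) > 0 && all(acc %in% te_whitelist)
    status <- if (length(acc) > 0 && !te) "proteome" else "noncanonical"
    nc <- character(0)
    if (!is.null(noncanonical_index) && status == "noncanonical") {
      nh <- Biostrings::vcountPattern(q, noncanonical_index$set) > 0
      nc <- noncanonical_index$accessions[nh]
    }
    data.frame(peptide = p, status = status,
               canonical_accessions = paste(acc, collapse = ";"),
               noncanonical_ids = paste(nc, collapse = ";"),
               te_exception = te, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[match(bare, out$peptide), , drop = FALSE] -> out
  out$peptide <- bare
  rownames(out) <- NULL
  out
}

strip_mods <- function(peptide) gsub("\\[[^]]*\\]", "", peptide)

#' Relative position of a peptide within its source protein
#'
#' Returns the position of the peptide relative to the full protein
#' length, using the first occurrence under I/L equivalence. With
#' `terminus = "C"` (default) the statistic is the 0-based start plus the
#' peptide length divided by the protein length, i.e. 1.0 for a peptide
#' ending at the C-terminus; with `terminus = "N"` it is the 0-based start
#' divided by the protein length.
#'
#' @param peptide peptide sequence.
#' @param source_seq full protein sequence containing the peptide.
#' @param terminus `"C"` or `"N"` coordinate convention.
#' @return a number in `[0, 1]`.
#' @export
peptide_position_stats <- function(peptide, source_seq,
                                   terminus = c("C", "N")) {
  terminus <- match.arg(terminus)
  if (nchar(peptide) == 0) stop_validation("empty peptide")
  p <- chartr("I", "L", strip_mods(toupper(peptide)))
  s <- chartr("I", "L", toupper(source_seq))
  at <- regexpr(p, s, fixed = TRUE)
  if (at < 0) stop_validation("peptide does not occur in source sequence")
  start0 <- as.integer(at) - 1L
  if (terminus == "C") (start0 + nchar(p)) / nchar(s) else start0 / nchar(s)
}
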