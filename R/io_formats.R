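#' Read a PSM table in the native TSV dialect
#'
#' The native interchange format is a tab-separated table with a versioned
#' comment header (lines starting with `#` are ignored). One row is one
#' peptide-spectrum match. Mandatory columns: `spectrum_key`, `peptide`,
#' `charge`, `proteins` (semicolon-separated accessions). Engine A rows
#' additionally require the three search scores `xcorr`, `delta_cn`,
#' `sp_score`; engine B rows require the single `engine_score` (engine B
#' tables are accepted as pre-filtered at the FDR recorded in
#' `claimed_fdr`). Optional columns: `is_decoy` (true/false), `group`
#' (`proteome`/`noncanonical`/`unassigned`).
#'
#' When no `is_decoy` column is present the flag is derived from the
#' protein accessions: a row is a decoy when all of its accessions start
#' with `decoy_prefix`. Rows with non-finite mandatory scores are dropped,
#' counted in the `n_malformed` attribute and reported in a warning with
#' their line numbers.
#'
#' @param path path to a TSV file.
#' @param engine `"engineA"` or `"engineB"`.
#' @param decoy_prefix accession prefix marking decoy (reversed) sequences.
#' @param claimed_fdr optional FDR at which an engine B table was
#'   pre-filtered upstream; stored as metadata only.
#' @return A `psm_table`: a `data.frame` with the dialect columns plus
#'   attributes `engine`, `source_path`, `n_malformed`, `claimed_fdr`.
#' @export
read_psm_table <- function(path, engine = c("engineA", "engineB"),
                           decoy_prefix = "DECOY_", claimed_fdr = NA_real_) {
  engine <- match.arg(engine)
  if (!file.exists(path)) stop_validation("PSM table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  mandatory <- c("spectrum_key", "peptide", "charge", "proteins")
  score_cols <- if (engine == "engineA") c("xcorr", "delta_cn", "sp_score")
                else "engine_score"
  for (col in c(mandatory, score_cols)) {
    if (!col %in% names(df))
      stop_validation("PSM table ", path, " is missing mandatory column '",
                      col, "'")
  }
  optional <- c("xcorr", "delta_cn", "sp_score", "engine_score")
  for (col in setdiff(optional, names(df)))
    df[[col]] <- rep(NA_real_, nrow(df))
  for (col in optional) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$charge <- suppressWarnings(as.integer(df$charge))

  bad <- !is.finite(df$charge) | df$charge < 1 |
    nchar(df$spectrum_key) == 0 | nchar(df$peptide) == 0
  for (col in score_cols) bad <- bad | !is.finite(df[[col]])
  if (any(bad)) {
    # +1 header line, and read.delim line counting starts after it
    warning(sprintf("dropped %d malformed row(s) in %s (data line(s) %s)",
                    sum(bad), path,
                    paste(which(bad), collapse = ", ")))
  }
  n_malformed <- sum(bad)
  df <- df[!bad, , drop = FALSE]

  prot_list <- strsplit(as.character(df$proteins), ";", fixed = TRUE)
  prefix_decoy <- vapply(prot_list, function(p) {
    length(p) > 0 && all(startsWith(p, decoy_prefix))
  }, logical(1))
  if ("is_decoy" %in% names(df)) {
    df$is_decoy <- as.logical(df$is_decoy)
    if (nrow(df) && any(df$is_decoy != prefix_decoy))
      warning("is_decoy column disagrees with accession prefix '",
              decoy_prefix, "' for ", sum(df$is_decoy != prefix_decoy),
              " row(s); keeping the explicit column")
  } else {
    df$is_decoy <- prefix_decoy
  }
  if (!"group" %in% names(df)) df$group <- rep("unassigned", nrow(df))
  if (nrow(df) && any(!is.na(df$delta_cn) &
                      (df$delta_cn < 0 | df$delta_cn > 1)))
    stop_validation("delta_cn outside [0, 1] in ", path)

  new_psm_table(df, engine = engine, source_path = path,
                n_malformed = n_malformed, claimed_fdr = claimed_fdr)
}

#' @rdname read_psm_table
#' @param df a data frame with the dialect columns.
#' @export
new_psm_table <- function(df, engine = "engineA", source_path = NA_character_,
                          n_malformed = 0L, claimed_fdr = NA_real_) {
  cols <- c("spectrum_key", "peptide", "charge", "xcorr", "delta_cn",
            "sp_score", "engine_score", "proteins", "is_decoy", "group")
  for (col in setdiff(cols, names(df))) {
    df[[col]] <- switch(col,
      engine_score = , xcorr = , delta_cn = ,
      sp_score = rep(NA_real_, nrow(df)),
      group = rep("unassigned", nrow(df)),
      stop_validation("psm_table is missing column '", col, "'"))
  }
  df <- df[, cols]
  structure(df, class = c("psm_table", "data.frame"),
            engine = engine, source_path = source_path,
            n_malformed = n_malformed, claimed_fdr = claimed_fdr)
}

#' Fraction of decoy rows in a PSM table
#' @param psms a `psm_table`.
#' @export
decoy_fraction <- function(psms) {
  if (nrow(psms) == 0) return(0)
  mean(psms$is_decoy)
}

#' Read a FASTA file with alphabet validation
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' sequences, removes line wrapping, rejects duplicate accessions and
#' validates the declared alphabet. The accession is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description.
#'
#' @param path FASTA file path.
#' @param alphabet `"aa"` (20 standard residues plus X/U/B/Z and `*`) or
#'   `"nt"` (ACGTN, case-insensitive on input).
#' @return data frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_validation("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    stop_validation("duplicate FASTA accession(s): ",
                    paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  legal <- if (alphabet == "aa") "ACDEFGHIKLMNPQRSTVWYXUBZ*" else "ACGTN"
  pat <- paste0("[^", gsub("\\*", "\\\\*", legal), "]")
  bad <- regexpr(pat, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_validation("illegal ", alphabet, " character '",
                    substr(seqs[i], bad[i], bad[i]), "' at position ",
                    bad[i], " in sequence '", accession[i], "'")
  }
  if (any(nchar(seqs) == 0))
    stop_validation("empty sequence for accession '",
                    accession[which(nchar(seqs) == 0)[1]], "'")
  data.frame(accession = accession, description = description,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write amino-acid or nucleotide sequences as FASTA
#'
#' @param entries data frame with `accession`, `description`, `sequence`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(entries))) {
    hdr <- entries$accession[i]
    if (nzchar(entries$description[i]))
      hdr <- paste(hdr, entries$description[i])
    writeLines(paste0(">", hdr), con)
    s <- entries$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a transcript expression table
#'
#' TSV with columns `transcript_id`, `gene_id`, `value`, `unit`
#' (`FPKM` or `TPM`). Transcript ids must be unique and values
#' non-negative.
#'
#' @param path TSV path.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_validation("expression table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("transcript_id", "gene_id", "value", "unit"))
    if (!col %in% names(df))
      stop_validation("expression table is missing column '", col, "'")
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value) | df$value < 0))
    stop_validation("expression values must be finite and >= 0")
  if (anyDuplicated(df$transcript_id))
    stop_validation("duplicate transcript_id in expression table")
  if (!all(df$unit %in% c("FPKM", "TPM")))
    stop_validation("expression unit must be FPKM or TPM")
  df
}

#' Write final PSM results with peptide classifications
#'
#' One row per retained PSM with its classification, stably sorted by
#' `(spectrum_key, peptide)` so repeated writes of the same input are
#' byte-identical.
#'
#' @param psms a `psm_table` (or data frame) of retained PSMs; an optional
#'   `lfdr` column is carried through.
#' @param classifications data frame from [classify_peptides()]; every PSM
#'   peptide must be present.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(psms, classifications, path) {
  missing <- setdiff(unique(psms$peptide), classifications$peptide)
  if (length(missing))
    stop_validation("no classification for peptide(s): ",
                    paste(utils::head(missing, 5), collapse = ", "))
  status <- classifications$status[match(psms$peptide,
                                         classifications$peptide)]
  out <- data.frame(
    spectrum_key = psms$spectrum_key,
    peptide = psms$peptide,
    charge = psms$charge,
    group = status,
    xcorr = psms$xcorr,
    delta_cn = psms$delta_cn,
    sp_score = psms$sp_score,
    lfdr = if ("lfdr" %in% names(psms)) psms$lfdr
           else rep(NA_real_, nrow(psms)),
    accepted = if ("accepted" %in% names(psms)) psms$accepted
               else rep(TRUE, nrow(psms)),
    proteins = psms$proteins,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$spectrum_key, out$peptide, method = "radix"), ,
             drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# peplfdr results_tsv v1", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a psm_table in the native TSV dialect
#' @param psms a `psm_table`.
#' @param path output path.
#' @export
write_psm_table <- function(psms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# peplfdr psm_tsv v1", con)
  utils::write.table(as.data.frame(psms), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize bracketed modification masses in a peptide string
#'
#' Rounds bracketed mass deltas (`"PEPT[+79.96633]IDE"`) to 4 decimals so
#' peptide strings from different engines compare equal.
#'
#' @param peptide character vector of modified peptide strings.
#' @export
normalize_peptide_mods <- function(peptide) {
  has_mod <- grepl("[", peptide, fixed = TRUE)
  if (!any(has_mod)) return(peptide)
  peptide[has_mod] <- vapply(peptide[has_mod], function(p) {
    m <- gregexpr("\\[[+-]?[0-9.]+\\]", p)[[1]]
    if (m[1] == -1) return(p)
    lens <- attr(m, "match.length")
    parts <- character(0)
    last <- 1L
    for (i in seq_along(m)) {
      parts <- c(parts, substr(p, last, m[i] - 1L))
      val <- as.numeric(substr(p, m[i] + 1L, m[i] + lens[i] - 2L))
      parts <- c(parts, sprintf("[%+.4f]", val))
      last <- m[i] + lens[i]
    }
    paste0(paste(parts, collapse = ""), substr(p, last, nchar(p)))
  }, character(1), USE.NAMES = FALSE)
  peptide
}
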