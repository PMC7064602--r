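#' Intersect the accepted PSMs of two search engines
#'
#' Only PSMs for which both engines report the identical match — same
#' spectrum, same modified peptide string (modification masses normalized
#' to 4 decimals; I and L kept distinct, since both engines searched the
#' same database), same charge — are retained. PSMs present in exactly
#' one engine are dropped and counted per engine in the attached report.
#'
#' @param acceptedA engine A's accepted target PSMs (e.g.
#'   [accepted_psms()] output); must carry `lfdr` when available.
#' @param acceptedB engine B's accepted target PSMs with `engine_score`.
#' @return data frame of combined PSMs (`spectrum_key`, `peptide`,
#'   `charge`, `group`, `lfdr_engineA`, `engineB_score`, `proteins` =
#'   union of both engines' accessions), with attribute `report` listing
#'   per-engine accepted and dropped counts.
#' @export
intersect_psms <- function(acceptedA, acceptedB) {
  if (any(acceptedA$is_decoy) || any(acceptedB$is_decoy))
    stop_validation("intersect_psms expects decoy-free accepted lists")
  keyA <- psm_key(acceptedA)
  keyB <- psm_key(acceptedB)
  if (anyDuplicated(keyA)) acceptedA <- acceptedA[!duplicated(keyA), ]
  if (anyDuplicated(keyB)) acceptedB <- acceptedB[!duplicated(keyB), ]
  keyA <- psm_key(acceptedA)
  keyB <- psm_key(acceptedB)
  iA <- match(intersect(keyA, keyB), keyA)
  iB <- match(keyA[iA], keyB)
  a <- acceptedA[iA, , drop = FALSE]
  b <- acceptedB[iB, , drop = FALSE]
  gb <- b$group
  known <- !is.na(gb) & gb != "unassigned"
  if (any(known & gb != a$group)) {
    bad <- which(known & gb != a$group)[1]
    stop_validation("conflicting group labels between engines for key ",
                    keyA[iA][bad])
  }
  proteins <- mapply(function(pa, pb) {
    paste(sort(unique(c(
      strsplit(pa, ";", fixed = TRUE)[[1]],
      if (!is.na(pb)) strsplit(pb, ";", fixed = TRUE)[[1]]))),
      collapse = ";")
  }, a$proteins, b$proteins, USE.NAMES = FALSE)
  out <- data.frame(
    spectrum_key = a$spectrum_key,
    peptide = normalize_peptide_mods(a$peptide),
    charge = a$charge,
    group = a$group,
    lfdr_engineA = if ("lfdr" %in% names(a)) a$lfdr else NA_real_,
    engineB_score = b$engine_score,
    proteins = proteins,
    stringsAsFactors = FALSE)
  out <- out[order(out$spectrum_key, out$peptide, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- data.frame(
    engine = c("engineA", "engineB"),
    accepted = c(nrow(acceptedA), nrow(acceptedB)),
    intersected = nrow(out),
    dropped = c(nrow(acceptedA), nrow(acceptedB)) - nrow(out))
  out
}

psm_key <- function(psms) {
  paste(psms$spectrum_key, normalize_peptide_mods(psms$peptide),
        psms$charge, sep = "\r")
}

#' Collapse combined PSMs to unique peptides
#'
#' @param combined output of [intersect_psms()] (or any PSM data frame
#'   with `peptide`, `group` and optionally `lfdr_engineA`).
#' @return data frame with one row per peptide: `peptide`, `group`,
#'   `n_psms`, `best_lfdr` (minimum engine A lFDR over its PSMs),
#'   deterministically ordered by peptide.
#' @export
psms_to_peptides <- function(combined) {
  if (nrow(combined) == 0)
    return(data.frame(peptide = character(0), group = character(0),
                      n_psms = integer(0), best_lfdr = numeric(0),
                      stringsAsFactors = FALSE))
  lf <- if ("lfdr_engineA" %in% names(combined)) combined$lfdr_engineA
        else if ("lfdr" %in% names(combined)) combined$lfdr
        else rep(NA_real_, nrow(combined))
  sp <- split(seq_len(nrow(combined)), combined$peptide)
  out <- data.frame(
    peptide = names(sp),
    group = vapply(sp, function(i) combined$group[i[1]], character(1)),
    n_psms = vapply(sp, length, integer(1)),
    best_lfdr = vapply(sp, function(i) {
      v <- lf[i]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$peptide, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
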