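# draw n correlated (xcorr, delta_cn, sp_score) score triples;
# delta_cn is clamped to [0, 1], xcorr and sp_score floored at 0.
# XCorr and spScore carry a rare exponential tail (as in real search
# output, where the observed score range is many times the bulk spread)
draw_scores <- function(n, model) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  z3 <- stats::rnorm(n)
  rho <- model$rho_xd
  xc <- model$mean[1] + model$sd[1] * z1
  dc <- model$mean[2] + model$sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  sp <- model$mean[3] + model$sd[3] * z3
  if (!is.null(model$tail_prob) && model$tail_prob > 0) {
    tl <- stats::runif(n) < model$tail_prob
    nt <- sum(tl)
    if (nt > 0) {
      xc[tl] <- xc[tl] + stats::rexp(nt, 1 / model$tail_xcorr)
      sp[tl] <- sp[tl] + stats::rexp(nt, 1 / model$tail_sp)
    }
  }
  data.frame(xcorr = pmax(xc, 0),
             delta_cn = pmin(pmax(dc, 0), 1),
             sp_score = pmax(sp, 0))
}

random_peptides <- function(n, len = 9L) {
  aa <- c("A", "D", "E", "F", "G", "H", "K", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")  # unambiguous under I/L
  m <- matrix(sample(aa, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Default score model of the PSM simulator
#'
#' True PSMs score higher on all three axes and show a positive
#' XCorr-deltaCn correlation; false PSMs sit lower with nearly
#' independent scores, so the 3D histogram separates the classes better
#' than any 1D projection. Both classes carry a rare exponential tail on
#' XCorr and spScore, reproducing the long right tails of real search
#' scores (the observed range spans many bulk standard deviations, so
#' the bulk of an equal-width min/max histogram is densely populated).
#' Decoy PSM scores are drawn from the false distribution (target-decoy
#' symmetry).
#'
#' @return list with `true` and `false` components, each holding `mean`
#'   (xcorr, delta_cn, sp_score), `sd`, `rho_xd` (XCorr-deltaCn
#'   correlation), and tail parameters `tail_prob`, `tail_xcorr`,
#'   `tail_sp`.
#' @export
default_score_model <- function() {
  tails <- list(tail_prob = 0.004, tail_xcorr = 2.0, tail_sp = 600)
  list(true = c(list(mean = c(2.9, 0.32, 520), sd = c(0.85, 0.16, 190),
                     rho_xd = 0.5), tails),
       false = c(list(mean = c(1.5, 0.08, 220), sd = c(0.5, 0.06, 110),
                      rho_xd = 0.05), tails))
}

#' Simulate labeled two-engine PSM datasets
#'
#' Emulates the target/decoy structure of a combined canonical +
#' non-canonical search. Target PSMs are a mixture of true and false
#' matches with group-specific true fractions (the non-canonical search
#' space is large and mostly wrong, so its true fraction is low). Decoy
#' PSMs are drawn from the false-score distribution, one decoy per false
#' target on average (`decoy_ratio`), and carry the group of the database
#' section they derive from. Engine B reproduces each true engine A match
#' with probability `engineB_agreement`; for a false engine A match it
#' reports the same wrong peptide with probability
#' `engineB_false_overlap`, a different wrong peptide with probability
#' `engineB_false_other`, and otherwise nothing.
#'
#' @param n_per_stratum named integer vector of target PSM counts per
#'   charge stratum.
#' @param frac_noncanonical fraction of target PSMs hitting the
#'   non-canonical database section.
#' @param true_fraction named vector: probability that a target PSM in
#'   each group is a correct match.
#' @param decoy_ratio expected decoys per false target PSM.
#' @param engineB_agreement,engineB_false_overlap,engineB_false_other
#'   engine B generation probabilities (see above).
#' @param score_model see [default_score_model()].
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with `psms_engineA` (a `psm_table` of targets and
#'   decoys), `psms_engineB` (a `psm_table` of engine B's pre-filtered
#'   target matches), and `truth` (data frame `spectrum_key`, `engine`,
#'   `is_correct` covering every PSM; decoys are always incorrect).
#' @export
simulate_psms <- function(n_per_stratum = c(Z1 = 20000, Z2 = 120000,
                                            Z3plus = 60000),
                          frac_noncanonical = 0.1,
                          true_fraction = c(proteome = 0.9,
                                            noncanonical = 0.3),
                          decoy_ratio = 1,
                          engineB_agreement = 0.9,
                          engineB_false_overlap = 0.1,
                          engineB_false_other = 0.5,
                          score_model = default_score_model(),
                          seed = 1L) {
  stopifnot(all(true_fraction >= 0 & true_fraction <= 1),
            frac_noncanonical >= 0, frac_noncanonical <= 1,
            decoy_ratio >= 0)
  if (!all(c("proteome", "noncanonical") %in% names(true_fraction)))
    stop_validation("true_fraction needs 'proteome' and 'noncanonical'")
  set.seed(seed)
  charges <- c(Z1 = 1L, Z2 = 2L, Z3plus = 3L)
  blocks <- list()
  b_blocks <- list()
  spec_counter <- 0L
  for (s in names(n_per_stratum)) {
    n <- n_per_stratum[[s]]
    if (n == 0) next
    grp <- ifelse(stats::runif(n) < frac_noncanonical,
                  "noncanonical", "proteome")
    is_true <- stats::runif(n) < true_fraction[grp]
    sc <- draw_scores(n, score_model$false)
    n_true <- sum(is_true)
    if (n_true > 0) sc[is_true, ] <- draw_scores(n_true, score_model$true)
    spec <- sprintf("sp%08d", spec_counter + seq_len(n))
    spec_counter <- spec_counter + n
    pep <- random_peptides(n)
    prot <- ifelse(grp == "proteome",
                   sprintf("PROT_%06d", seq_len(n)),
                   sprintf("NC_%06d", seq_len(n)))
    targets <- data.frame(
      spectrum_key = spec, peptide = pep,
      charge = if (s == "Z3plus") sample(3:4, n, replace = TRUE)
               else rep(charges[[s]], n),
      sc, engine_score = NA_real_, proteins = prot,
      is_decoy = FALSE, group = grp, is_correct = is_true,
      stringsAsFactors = FALSE)

    n_false_by_grp <- table(factor(grp[!is_true],
                                   levels = c("proteome", "noncanonical")))
    decs <- list()
    for (g in c("proteome", "noncanonical")) {
      nd <- stats::rpois(1, decoy_ratio * n_false_by_grp[[g]])
      if (nd == 0) next
      dsc <- draw_scores(nd, score_model$false)
      decs[[g]] <- data.frame(
        spectrum_key = sprintf("sp%08d", spec_counter + seq_len(nd)),
        peptide = random_peptides(nd),
        charge = if (s == "Z3plus") sample(3:4, nd, replace = TRUE)
                 else rep(charges[[s]], nd),
        dsc, engine_score = NA_real_,
        proteins = sprintf("DECOY_%s_%06d",
                           if (g == "proteome") "PROT" else "NC",
                           seq_len(nd)),
        is_decoy = TRUE, group = g, is_correct = FALSE,
        stringsAsFactors = FALSE)
      spec_counter <- spec_counter + nd
    }
    blocks[[s]] <- rbind(targets, do.call(rbind, decs))

    # engine B: subset of engine A target matches plus independent wrong
    # matches, emulating a pre-filtered second-engine result list
    u <- stats::runif(n)
    keep_true <- is_true & u < engineB_agreement
    keep_false_same <- !is_true & u < engineB_false_overlap
    keep_false_other <- !is_true & !keep_false_same &
      u < engineB_false_overlap + engineB_false_other
    b <- targets[keep_true | keep_false_same | keep_false_other, ,
                 drop = FALSE]
    other <- keep_false_other[keep_true | keep_false_same |
                                keep_false_other]
    if (any(other)) b$peptide[other] <- random_peptides(sum(other))
    b$engine_score <- 30 + 15 * b$xcorr + stats::rnorm(nrow(b), sd = 2)
    b$xcorr <- b$delta_cn <- b$sp_score <- NA_real_
    b_blocks[[s]] <- b
  }
  a <- do.call(rbind, blocks)
  b <- do.call(rbind, b_blocks)
  rownames(a) <- rownames(b) <- NULL
  truth <- rbind(
    data.frame(spectrum_key = a$spectrum_key, engine = "engineA",
               is_correct = a$is_correct, stringsAsFactors = FALSE),
    data.frame(spectrum_key = b$spectrum_key, engine = "engineB",
               is_correct = b$is_correct, stringsAsFactors = FALSE))
  a_tab <- new_psm_table(a[, setdiff(names(a), "is_correct")],
                         engine = "engineA")
  a_tab$is_correct <- a$is_correct
  b_tab <- new_psm_table(b[, setdiff(names(b), "is_correct")],
                         engine = "engineB")
  b_tab$is_correct <- b$is_correct
  list(psms_engineA = a_tab, psms_engineB = b_tab, truth = truth)
}

#' Simulate a non-coding transcriptome with expression values
#'
#' Uniform random nucleotide sequences with log-normally distributed
#' expression; a fraction of transcripts is unexpressed (value 0), as for
#' non-coding genes absent from a sample.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range min/max transcript length (nt, >= 30).
#' @param seed integer seed.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param frac_zero fraction of unexpressed transcripts.
#' @param unit expression unit label.
#' @return list with `transcripts` (FASTA data frame) and `expression`
#'   (expression table data frame).
#' @export
simulate_transcriptome <- function(n_transcripts, length_range = c(150, 900),
                                   seed = 1L, expr_meanlog = 1,
                                   expr_sdlog = 1.2, frac_zero = 0.2,
                                   unit = "FPKM") {
  if (length_range[1] < 30) stop_validation("transcript lengths must be >= 30")
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_transcripts,
                 replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  ids <- sprintf("TX%05d", seq_len(n_transcripts))
  expr <- stats::rlnorm(n_transcripts, expr_meanlog, expr_sdlog)
  expr[stats::runif(n_transcripts) < frac_zero] <- 0
  list(
    transcripts = data.frame(accession = ids, description = "",
                             sequence = seqs, stringsAsFactors = FALSE),
    expression = data.frame(transcript_id = ids,
                            gene_id = sprintf("G%05d",
                                              seq_len(n_transcripts)),
                            value = expr, unit = unit,
                            stringsAsFactors = FALSE))
}

#' Simulate a proteome with a planted peptide-sharing structure
#'
#' Generates random protein sequences and inserts planted peptides
#' according to a sharing plan, for protein-grouping tests with a known
#' peptide -> protein map.
#'
#' @param plan named list: protein accession -> character vector of
#'   peptide *names*; peptides appearing under several accessions are
#'   shared.
#' @param seed integer seed.
#' @param peptide_len length of planted peptides.
#' @param flank_len random residues between planted peptides.
#' @return list with `proteins` (FASTA data frame),
#'   `peptide_to_proteins` (named list keyed by planted peptide
#'   sequence), and `peptides` (name -> sequence map).
#' @export
simulate_proteome_with_peptides <- function(plan, seed = 1L,
                                            peptide_len = 9L,
                                            flank_len = 12L) {
  set.seed(seed)
  pep_names <- sort(unique(unlist(plan, use.names = FALSE)))
  pep_seq <- setNames(random_peptides(length(pep_names), peptide_len),
                      pep_names)
  while (anyDuplicated(pep_seq))
    pep_seq[duplicated(pep_seq)] <-
      random_peptides(sum(duplicated(pep_seq)), peptide_len)
  prots <- lapply(names(plan), function(acc) {
    peps <- pep_seq[plan[[acc]]]
    flanks <- random_peptides(length(peps) + 1L, flank_len)
    paste0(paste0(flanks[seq_along(peps)], peps, collapse = ""),
           flanks[length(flanks)])
  })
  p2p <- lapply(setNames(pep_names, pep_seq[pep_names]), function(nm)
    sort(names(plan)[vapply(plan, function(v) nm %in% v, logical(1))]))
  list(
    proteins = data.frame(accession = names(plan), description = "",
                          sequence = unlist(prots),
                          stringsAsFactors = FALSE),
    peptide_to_proteins = p2p,
    peptides = pep_seq)
}
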