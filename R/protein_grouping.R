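#' Greedy parsimony grouping of proteins by shared peptides
#'
#' Greedy set cover over the peptide-protein bipartite graph: the protein
#' explaining the most not-yet-explained peptides is selected as a group
#' lead (ties broken by lexicographically smallest accession), and every
#' protein sharing a peptide with the lead joins its group (a protein
#' sharing with several leads joins the first). Within a group, members
#' are sorted by decreasing total peptide count (ties by accession) and
#' the *adjusted* count of each member is the number of its peptides not
#' already credited to a member higher in the list, so that adjusted
#' counts over a group sum exactly to the distinct peptides assigned to
#' it. Peptides falling into more than one group are assigned (for the
#' adjusted counts) to the first group in lead order.
#'
#' @param peptide_to_proteins named list: peptide sequence -> character
#'   vector of protein accessions (each peptide maps to >= 1 accession).
#' @param protein_lengths optional named vector of protein lengths
#'   (residues), used by [hla_sampling()].
#' @return data frame with one row per (group, member): `group_id` (lead
#'   accession), `accession`, `protein_length`, `total_peptides`,
#'   `unique_peptides`, `adjusted_peptides`. The greedy cover itself
#'   (the selected proteins in selection order) is attached as the
#'   `cover` attribute.
#' @export
group_proteins <- function(peptide_to_proteins,
                           protein_lengths = NULL) {
  if (length(peptide_to_proteins) == 0)
    return(data.frame(group_id = character(0), accession = character(0),
                      protein_length = integer(0),
                      total_peptides = integer(0),
                      unique_peptides = integer(0),
                      adjusted_peptides = integer(0),
                      stringsAsFactors = FALSE))
  if (any(lengths(peptide_to_proteins) == 0))
    stop_validation("every peptide must map to at least one accession")
  peptides <- names(peptide_to_proteins)
  # protein -> peptide set
  prot_peps <- split(
    rep(peptides, lengths(peptide_to_proteins)),
    unlist(peptide_to_proteins, use.names = FALSE))
  prot_peps <- lapply(prot_peps, unique)
  accs <- sort(names(prot_peps))

  unexplained <- peptides
  leads <- character(0)
  while (length(unexplained)) {
    gain <- vapply(accs, function(a)
      sum(prot_peps[[a]] %in% unexplained), integer(1))
    lead <- accs[which.max(gain)]  # which.max takes the first (lexicographic)
    leads <- c(leads, lead)
    unexplained <- setdiff(unexplained, prot_peps[[lead]])
  }

  # a lead that already joined an earlier lead's group (it shares a
  # peptide with it) does not open a group of its own
  assigned_group <- setNames(rep(NA_character_, length(accs)), accs)
  group_leads <- character(0)
  for (lead in leads) {
    if (!is.na(assigned_group[lead])) next
    group_leads <- c(group_leads, lead)
    share <- vapply(accs, function(a)
      length(intersect(prot_peps[[a]], prot_peps[[lead]])) > 0, logical(1))
    free <- is.na(assigned_group) & share
    assigned_group[free] <- lead
  }
  # proteins sharing no peptide with any lead cannot occur (every peptide
  # is covered), but guard anyway
  orphan <- is.na(assigned_group)
  assigned_group[orphan] <- names(assigned_group)[orphan]
  group_leads <- c(group_leads, names(assigned_group)[orphan])

  total <- vapply(accs, function(a) length(prot_peps[[a]]), integer(1))
  pep_nprot <- lengths(lapply(peptide_to_proteins, unique))
  uniq <- vapply(accs, function(a)
    sum(pep_nprot[prot_peps[[a]]] == 1L), integer(1))

  # assign each peptide to its first group in lead order
  pep_group <- setNames(rep(NA_character_, length(peptides)), peptides)
  for (lead in group_leads) {
    members <- accs[assigned_group == lead]
    peps <- unique(unlist(prot_peps[members], use.names = FALSE))
    free <- is.na(pep_group[peps])
    pep_group[peps[free]] <- lead
  }

  rows <- lapply(group_leads, function(lead) {
    members <- accs[assigned_group == lead]
    members <- members[order(-total[members], members, method = "radix")]
    credited <- character(0)
    adj <- integer(length(members))
    for (k in seq_along(members)) {
      mine <- prot_peps[[members[k]]]
      mine <- mine[pep_group[mine] == lead]
      adj[k] <- length(setdiff(mine, credited))
      credited <- union(credited, mine)
    }
    data.frame(group_id = lead, accession = members,
               protein_length = if (is.null(protein_lengths)) NA_integer_
                                else unname(protein_lengths[members]),
               total_peptides = unname(total[members]),
               unique_peptides = unname(uniq[members]),
               adjusted_peptides = adj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # the greedy cover itself (selection order), before peptide-sharing
  # proteins were merged into groups
  attr(out, "cover") <- leads
  out
}

#' Length-normalized HLA sampling per protein
#'
#' Sampling = adjusted peptide count / protein length, a per-protein
#' presentation-efficiency proxy.
#'
#' @param groups data frame from [group_proteins()] with
#'   `protein_length` filled in.
#' @return named numeric vector (accession -> sampling).
#' @export
hla_sampling <- function(groups) {
  if (any(is.na(groups$protein_length) | groups$protein_length <= 0))
    stop_validation("hla_sampling requires positive protein lengths")
  setNames(groups$adjusted_peptides / groups$protein_length,
           groups$accession)
}

#' Cubic fit of HLA sampling against expression
#'
#' Fits a degree-3 polynomial of sampling on log-transformed expression
#' (log10(value + 1)) by least squares and reports the Pearson
#' correlation between the fitted curve and the observed sampling.
#'
#' @param sampling named numeric vector, gene -> sampling value.
#' @param expression named numeric vector, gene -> expression (raw scale;
#'   log-transformed internally unless `log_transform = FALSE`).
#' @param log_transform apply log10(x + 1) to expression first.
#' @return list with `coefficients` (intercept, x, x^2, x^3),
#'   `pearson_r`, `n`. `pearson_r` is `NA` (with a warning) when sampling
#'   has zero variance.
#' @export
expression_sampling_correlation <- function(sampling, expression,
                                            log_transform = TRUE) {
  shared <- intersect(names(sampling), names(expression))
  if (length(shared) < 5)
    stop_validation("need at least 5 genes shared between sampling and ",
                    "expression (got ", length(shared), ")")
  y <- as.numeric(sampling[shared])
  x <- as.numeric(expression[shared])
  if (log_transform) x <- log10(x + 1)
  fit <- stats::lm(y ~ stats::poly(x, 3, raw = TRUE))
  r <- if (stats::var(y) == 0 || stats::var(fitted(fit)) == 0) {
    warning("zero variance; Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(fitted(fit), y)
  }
  list(coefficients = unname(stats::coef(fit)), pearson_r = r,
       n = length(shared))
}
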