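# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately use naive loops (or a
# different library path) rather than the package's vectorized code.

# random PSM data frame with known structure for grid/pipeline tests
make_psm_df <- function(n, seed = 1, charges = c(1, 2, 3),
                        frac_decoy = 0.3, frac_nc = 0.2) {
  set.seed(seed)
  is_decoy <- runif(n) < frac_decoy
  grp <- ifelse(runif(n) < frac_nc, "noncanonical", "proteome")
  # decoys score lower on average so grids carry signal
  shift <- ifelse(is_decoy, 0, runif(n) < 0.7)
  data.frame(
    spectrum_key = sprintf("s%05d", seq_len(n)),
    peptide = peplfdr:::random_peptides(n),
    charge = sample(charges, n, replace = TRUE),
    xcorr = rnorm(n, 2 + 1.5 * shift, 0.7),
    delta_cn = pmin(pmax(rnorm(n, 0.1 + 0.25 * shift, 0.08), 0), 1),
    sp_score = pmax(rnorm(n, 300 + 250 * shift, 120), 0),
    engine_score = NA_real_,
    proteins = ifelse(is_decoy, "DECOY_P1", "P1"),
    is_decoy = is_decoy,
    group = grp,
    stringsAsFactors = FALSE)
}

# triple-loop recomputation of the whole per-PSM lFDR pipeline: counting,
# smoothing, pseudocounts, normalization, gamma, Eq. lfdr = 1/(1+pi*gamma)
oracle_lfdr_pipeline <- function(psms, mode = "2g3d", bins = 5,
                                 smooth = TRUE, smooth_window = 1,
                                 eps0 = 0.5, eps1 = 0.5) {
  two_group <- startsWith(mode, "2")
  dims <- if (endsWith(mode, "3d")) c("xcorr", "delta_cn", "sp_score")
          else "xcorr"
  nd <- length(dims)
  stratum <- ifelse(psms$charge == 1, "Z1",
                    ifelse(psms$charge == 2, "Z2", "Z3plus"))
  gamma <- numeric(nrow(psms))
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    sub <- psms[rows, , drop = FALSE]
    edges <- lapply(dims, function(d)
      seq(min(sub[[d]]), max(sub[[d]]), length.out = bins + 1))
    names(edges) <- dims
    # per-PSM bin by linear scan over the edge values
    bin_of <- matrix(0L, nrow(sub), nd)
    for (i in seq_len(nrow(sub))) {
      for (k in seq_len(nd)) {
        x <- sub[[dims[k]]][i]
        e <- edges[[k]]
        j <- 1L
        for (b in seq_len(bins)) if (x >= e[b]) j <- b
        bin_of[i, k] <- j
      }
    }
    dims_len <- rep(bins, nd)
    ncell <- prod(dims_len)
    n0 <- n1 <- array(0, dims_len)
    for (i in seq_len(nrow(sub))) {
      ix <- matrix(bin_of[i, ], 1)
      if (sub$is_decoy[i]) n0[ix] <- n0[ix] + 1
      else n1[ix] <- n1[ix] + 1
    }
    n1 <- pmax(n1 - n0, 0)
    box <- 1
    if (smooth) {
      box <- (2 * smooth_window + 1)^nd
      sm <- function(a) {
        out <- array(0, dims_len)
        idx <- as.matrix(do.call(expand.grid, lapply(dims_len, seq_len)))
        for (r in seq_len(nrow(idx))) {
          tot <- 0; cnt <- 0
          offs <- as.matrix(do.call(expand.grid,
                                    rep(list(-smooth_window:smooth_window),
                                        nd)))
          for (q in seq_len(nrow(offs))) {
            nb <- idx[r, ] + offs[q, ]
            if (all(nb >= 1) && all(nb <= dims_len)) {
              tot <- tot + a[matrix(nb, 1)]
              cnt <- cnt + 1
            }
          }
          out[matrix(idx[r, ], 1)] <- tot / cnt
        }
        out
      }
      n0 <- sm(n0)
      n1 <- sm(n1)
    }
    p0 <- (n0 + eps0 / box) / sum(n0 + eps0 / box)
    p1 <- (n1 + eps1 / box) / sum(n1 + eps1 / box)
    g <- p1 / p0
    for (i in seq_len(nrow(sub)))
      gamma[rows[i]] <- g[matrix(bin_of[i, ], 1)]
  }
  pi_of <- function(rows) {
    T_ <- sum(!psms$is_decoy[rows]); D_ <- sum(psms$is_decoy[rows])
    min(max(T_ - D_, 0) / max(D_, 1), 1e6)
  }
  lf <- numeric(nrow(psms))
  if (two_group) {
    for (g in c("proteome", "noncanonical")) {
      rows <- psms$group == g
      lf[rows] <- 1 / (1 + pi_of(rows) * gamma[rows])
    }
  } else {
    lf <- 1 / (1 + pi_of(rep(TRUE, nrow(psms))) * gamma)
  }
  list(gamma = gamma, lfdr = lf)
}

# per-frame translate-and-split ORF oracle using Biostrings::translate
# (codon handling through an independent code path)
oracle_orfs <- function(id, seq, min_len = 8) {
  out <- list()
  for (frame in 0:2) {
    ncod <- (nchar(seq) - frame) %/% 3
    if (ncod < 1) next
    sub <- substr(seq, frame + 1, frame + 3 * ncod)
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X",
      no.init.codon = TRUE)))
    # split at stops and at X
    pos <- gregexpr("[*X]", aa)[[1]]
    breaks <- if (pos[1] == -1) integer(0) else as.integer(pos)
    bounds <- c(0, breaks, nchar(aa) + 1)
    for (b in seq_len(length(bounds) - 1)) {
      a0 <- bounds[b] + 1
      a1 <- bounds[b + 1] - 1
      if (a1 - a0 + 1 >= min_len) {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = id, frame = frame,
          start_nt = frame + 3 * (a0 - 1), end_nt = frame + 3 * a1,
          peptide = substr(aa, a0, a1), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start_nt = integer(0), end_nt = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# exhaustive minimal set cover size over a peptide -> proteins map
oracle_min_cover_size <- function(peptide_to_proteins) {
  prots <- sort(unique(unlist(peptide_to_proteins)))
  peps <- names(peptide_to_proteins)
  for (k in seq_along(prots)) {
    combs <- utils::combn(prots, k, simplify = FALSE)
    for (cc in combs) {
      covered <- vapply(peps, function(p)
        any(peptide_to_proteins[[p]] %in% cc), logical(1))
      if (all(covered)) return(k)
    }
  }
  length(prots)
}

# random peptide-sharing plan on <= max_prot proteins / <= max_pep peptides
random_plan <- function(max_prot = 4, max_pep = 8) {
  np <- sample(1:max_prot, 1)
  prots <- LETTERS[seq_len(np)]
  m <- sample(1:max_pep, 1)
  plan <- setNames(vector("list", np), prots)
  for (j in seq_len(m)) {
    owners <- sample(prots, sample(seq_len(np), 1))
    for (o in owners)
      plan[[o]] <- c(plan[[o]], paste0("pep", j))
  }
  plan[lengths(plan) > 0]
}

plan_to_map <- function(plan) {
  peps <- sort(unique(unlist(plan)))
  setNames(lapply(peps, function(p)
    sort(names(plan)[vapply(plan, function(v) p %in% v, logical(1))])),
    peps)
}
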