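#' Split PSMs into charge strata
#'
#' Charge 1 (singly protonated, HLA class I only), charge 2, and charge 3
#' or higher form the three strata within which score histograms are
#' built.
#'
#' @param psms a `psm_table` or data frame with a `charge` column.
#' @return named list of data frames `Z1`, `Z2`, `Z3plus` (exhaustive,
#'   disjoint).
#' @export
stratify_by_charge <- function(psms) {
  stratum <- charge_stratum(psms$charge)
  list(Z1 = psms[stratum == "Z1", , drop = FALSE],
       Z2 = psms[stratum == "Z2", , drop = FALSE],
       Z3plus = psms[stratum == "Z3plus", , drop = FALSE])
}

charge_stratum <- function(charge) {
  if (any(charge < 1)) stop_validation("charge must be >= 1")
  ifelse(charge == 1, "Z1", ifelse(charge == 2, "Z2", "Z3plus"))
}

# box mean over the (2w+1)^d neighborhood, clipped at the grid borders:
# each cell is replaced by the mean of the valid cells in its box
box_smooth <- function(a, w = 1L) {
  dims <- dim(a)
  if (is.null(dims)) dims <- length(a)
  nd <- length(dims)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-w:w), nd)))
  acc <- array(0, dims)
  cnt <- array(0, dims)
  idx_full <- lapply(dims, seq_len)
  for (r in seq_len(nrow(offsets))) {
    src <- vector("list", nd)
    dst <- vector("list", nd)
    ok <- TRUE
    for (d in seq_len(nd)) {
      o <- offsets[r, d]
      dst[[d]] <- idx_full[[d]][idx_full[[d]] + o >= 1L &
                                idx_full[[d]] + o <= dims[d]]
      if (!length(dst[[d]])) { ok <- FALSE; break }
      src[[d]] <- dst[[d]] + o
    }
    if (!ok) next
    di <- as.matrix(do.call(expand.grid, dst))
    si <- as.matrix(do.call(expand.grid, src))
    acc[di] <- acc[di] + a[si]
    cnt[di] <- cnt[di] + 1
  }
  acc / cnt
}

#' Build a target/decoy score histogram for one charge stratum
#'
#' Partitions the score space into `bins` equal-width intervals per
#' dimension (right-open; the last bin is closed) spanning the observed
#' range. Per cell, the wrong-hit count `n0` is the number of decoy PSMs
#' and the true-hit count `n1` is the number of target PSMs minus `n0`,
#' floored at zero. Both count arrays are optionally smoothed by a
#' border-clipped box mean over the `(2*smooth_window + 1)^d`
#' neighborhood, then converted to probability distributions
#' `p(x | H = 0)` and `p(x | H = 1)` after adding pseudocounts of `eps0`
#' and `eps1` counts per smoothing neighborhood (i.e. `eps / (2w+1)^d`
#' per smoothed cell, or `eps` per cell when unsmoothed), so decoy-free
#' cells keep a finite density ratio without the pseudocount mass
#' swamping the real counts on a fine grid. The per-cell density ratio
#' is `gamma = p1 / p0`.
#'
#' @param psms data frame of PSMs in one stratum (targets and decoys).
#' @param dims score columns spanning the space; the default is the 3D
#'   Comet space, `"xcorr"` alone gives the 1D comparison mode.
#' @param bins intervals per dimension.
#' @param smooth apply the neighborhood box mean.
#' @param smooth_window half-width of the smoothing box.
#' @param eps0,eps1 pseudocounts (in counts per smoothing neighborhood)
#'   for wrong/true counts.
#' @return a `score_grid`: list with `dims`, `bins`, `edges`, raw and
#'   smoothed `n0`/`n1` arrays, normalized `p0`/`p1`, and `gamma`.
#' @export
build_score_grid <- function(psms,
                             dims = c("xcorr", "delta_cn", "sp_score"),
                             bins = 40L, smooth = TRUE, smooth_window = 1L,
                             eps0 = 0.5, eps1 = 0.5) {
  if (nrow(psms) < 1) stop_validation("cannot build a score grid from 0 PSMs")
  edges <- vector("list", length(dims))
  names(edges) <- dims
  for (d in dims) {
    x <- psms[[d]]
    if (any(!is.finite(x))) stop_validation("non-finite ", d, " score")
    lo <- min(x); hi <- max(x)
    if (hi <= lo)
      stop_validation("degenerate bins: all '", d, "' scores identical; ",
                      "consider the 1D (xcorr-only) mode")
    edges[[d]] <- seq(lo, hi, length.out = bins + 1L)
  }
  cell <- grid_cell(psms, edges)
  nbins <- rep(as.integer(bins), length(dims))
  ncell <- prod(nbins)
  n_decoy <- tabulate(cell[psms$is_decoy], nbins = ncell)
  n_target <- tabulate(cell[!psms$is_decoy], nbins = ncell)
  n0_raw <- array(n_decoy, nbins)
  n1_raw <- array(pmax(n_target - n_decoy, 0), nbins)
  if (smooth) {
    n0 <- box_smooth(n0_raw, smooth_window)
    n1 <- box_smooth(n1_raw, smooth_window)
    box <- (2 * smooth_window + 1)^length(dims)
  } else {
    n0 <- n0_raw
    n1 <- n1_raw
    box <- 1
  }
  p0 <- (n0 + eps0 / box) / sum(n0 + eps0 / box)
  p1 <- (n1 + eps1 / box) / sum(n1 + eps1 / box)
  structure(list(dims = dims, bins = nbins, edges = edges,
                 n0_raw = n0_raw, n1_raw = n1_raw, n0 = n0, n1 = n1,
                 p0 = p0, p1 = p1, gamma = p1 / p0,
                 n_psms = nrow(psms)),
            class = "score_grid")
}

# linear cell index of each PSM on a grid defined by `edges`;
# left-closed/right-open bins, values at the global max fall in the last bin
grid_cell <- function(psms, edges) {
  idx <- 0L
  mult <- 1L
  for (d in names(edges)) {
    e <- edges[[d]]
    i <- findInterval(psms[[d]], e, rightmost.closed = TRUE,
                      all.inside = TRUE)
    idx <- idx + (i - 1L) * mult
    mult <- mult * (length(e) - 1L)
  }
  idx + 1L
}

#' Per-cell local FDR from the density ratio and the prior odds
#'
#' `lfdr = (1 + pi_ratio * gamma)^(-1)`, the probability that a PSM whose
#' score vector falls in a cell with true/wrong density ratio `gamma` is
#' wrong, given prior odds `pi_ratio` = pi1/pi0 of true to wrong PSMs in
#' its group.
#'
#' @param gamma_value density ratio(s) `p(x|H=1)/p(x|H=0)`, >= 0.
#' @param pi_ratio prior odds pi1/pi0, >= 0.
#' @return value(s) in (0, 1].
#' @export
lfdr <- function(gamma_value, pi_ratio) {
  if (any(gamma_value < 0) || any(pi_ratio < 0))
    stop_validation("gamma and pi_ratio must be >= 0")
  1 / (1 + pi_ratio * gamma_value)
}

#' Estimate the prior odds pi1/pi0 for a PSM group
#'
#' The total number of wrong target PSMs in a group is estimated by its
#' decoy count D, so the prior odds of true to wrong PSMs is
#' `max(T - D, 0) / max(D, eps)` for T target PSMs. The odds differ
#' sharply between proteome-derived and non-canonical groups because the
#' non-canonical search space is large and mostly wrong.
#'
#' @param psms data frame of PSMs (targets and decoys) in one group.
#' @param group group label, recorded in the result.
#' @param eps minimum decoy count used in the denominator.
#' @param cap upper bound on the returned odds (guards decoy-free groups).
#' @return list with `group`, `n_targets`, `n_decoys`, `pi_ratio`.
#' @export
estimate_group_priors <- function(psms, group = "all", eps = 1, cap = 1e6) {
  n_t <- sum(!psms$is_decoy)
  n_d <- sum(psms$is_decoy)
  if (n_t == 0)
    stop_validation("no target PSMs in group '", group,
                    "'; consider one_group mode")
  pi_ratio <- max(n_t - n_d, 0) / max(n_d, eps)
  if (pi_ratio > cap) {
    warning("pi_ratio capped at ", cap, " for group '", group,
            "' (", n_d, " decoys)")
    pi_ratio <- cap
  }
  list(group = group, n_targets = n_t, n_decoys = n_d, pi_ratio = pi_ratio)
}

#' Select the local-FDR threshold achieving a global FDR
#'
#' Target PSMs are sorted by ascending lFDR; the running mean of the
#' sorted lFDR values estimates the global FDR of the list accepted so
#' far, and the threshold is the largest lFDR value whose running mean
#' stays at or below `alpha`.
#'
#' @param lfdr_values per-target-PSM lFDR values.
#' @param alpha requested global FDR (default 0.03).
#' @return list with `threshold`, logical `accepted` (aligned with
#'   `lfdr_values`), and `achieved_fdr_estimate` (mean lFDR of the
#'   accepted set; `NA` when nothing is accepted).
#' @export
select_threshold <- function(lfdr_values, alpha = 0.03) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  o <- order(lfdr_values)
  run_mean <- cumsum(lfdr_values[o]) / seq_along(o)
  ok <- which(run_mean <= alpha)
  if (!length(ok)) {
    warning("no PSM satisfies the global FDR bound ", alpha)
    return(list(threshold = -Inf,
                accepted = rep(FALSE, length(lfdr_values)),
                achieved_fdr_estimate = NA_real_))
  }
  k <- max(ok)
  threshold <- lfdr_values[o][k]
  accepted <- lfdr_values <= threshold
  list(threshold = threshold, accepted = accepted,
       achieved_fdr_estimate = mean(lfdr_values[accepted]))
}

#' Select the local-FDR threshold by decoy counting
#'
#' The global FDR of the list accepted at a candidate lFDR threshold is
#' estimated the standard target-decoy way, as the number of decoy PSMs
#' at or below the threshold divided by the number of target PSMs at or
#' below it; the selected threshold is the largest lFDR value keeping
#' this estimate at or below `alpha`. Unlike the running mean of lFDR
#' values ([select_threshold()]), the decoy count is insensitive to
#' bias in the lFDR estimates themselves, because decoys sample the
#' wrong-match score distribution directly.
#'
#' @param target_lfdr lFDR values of the target PSMs.
#' @param decoy_lfdr lFDR values of the decoy PSMs of the same group
#'   (computed with the same grid and priors).
#' @param alpha requested global FDR.
#' @return list with `threshold`, logical `accepted` (aligned with
#'   `target_lfdr`), and `achieved_fdr_estimate` (decoy/target ratio at
#'   the threshold).
#' @export
select_threshold_decoy <- function(target_lfdr, decoy_lfdr, alpha = 0.03) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  x <- c(target_lfdr, decoy_lfdr)
  is_d <- rep(c(FALSE, TRUE), c(length(target_lfdr), length(decoy_lfdr)))
  o <- order(x)
  xs <- x[o]
  cum_d <- cumsum(is_d[o])
  cum_t <- seq_along(xs) - cum_d
  # evaluate only at the last position of each tied lFDR value
  last_of_value <- c(xs[-1] > xs[-length(xs)], TRUE)
  est <- cum_d / pmax(cum_t, 1)
  ok <- which(last_of_value & cum_t > 0 & est <= alpha)
  if (!length(ok)) {
    warning("no PSM satisfies the global FDR bound ", alpha)
    return(list(threshold = -Inf,
                accepted = rep(FALSE, length(target_lfdr)),
                achieved_fdr_estimate = NA_real_))
  }
  k <- max(ok)
  list(threshold = xs[k],
       accepted = target_lfdr <= xs[k],
       achieved_fdr_estimate = est[k])
}

#' Run the composite group-specific local-FDR pipeline
#'
#' PSMs are split into charge strata (Z = 1, 2, >= 3). Per stratum a
#' target/decoy score histogram is built — 3D over (XCorr, deltaCn,
#' spScore) or 1D over XCorr — using *all* PSMs, so the density ratio
#' gamma is shared across groups. In `two_group` mode the prior odds
#' pi1/pi0 are estimated separately for the proteome-derived and
#' non-canonical groups (pooled over strata; decoys carry the group of
#' the database section they derive from) and each PSM's lFDR combines
#' its cell's gamma with its group's odds; thresholds are then selected
#' independently per group, each at `alpha`. In `one_group` mode a single
#' prior and a single threshold are used. The threshold achieving the
#' requested global FDR is found by decoy counting by default
#' ([select_threshold_decoy()]); `threshold_rule = "mean_lfdr"` uses the
#' running mean of sorted lFDR values instead ([select_threshold()]).
#'
#' @param psms a `psm_table` with `group` labels assigned (targets and
#'   decoys).
#' @param mode `"2g3d"` (default), `"1g3d"`, `"2g1d"` or `"1g1d"` —
#'   one/two groups crossed with 3D/1D score space.
#' @param alpha requested global FDR.
#' @param bins intervals per histogram dimension.
#' @param smooth,smooth_window,eps0,eps1 passed to [build_score_grid()].
#' @param pi_eps,pi_cap passed to [estimate_group_priors()].
#' @param min_psm_warning warn when a non-empty stratum has fewer PSMs
#'   than this (the histogram needs large datasets to be well estimated).
#' @return an `lfdr_result`: list with `psms` (target rows plus `gamma`,
#'   `lfdr`, `accepted`), `thresholds` and `achieved` per group,
#'   `priors`, `grids` per stratum, `decoy_fdr_estimate` per group (a
#'   decoy-counting cross-check: decoys under the group threshold over
#'   accepted targets), `mode`, `alpha`.
#' @export
run_composite_fdr <- function(psms, mode = c("2g3d", "1g3d", "2g1d", "1g1d"),
                              alpha = 0.03, bins = 40L, smooth = TRUE,
                              smooth_window = 1L, eps0 = 0.5, eps1 = 0.5,
                              pi_eps = 1, pi_cap = 1e6,
                              threshold_rule = c("decoy", "mean_lfdr"),
                              min_psm_warning = 1e5) {
  mode <- match.arg(mode)
  threshold_rule <- match.arg(threshold_rule)
  two_group <- startsWith(mode, "2")
  dims <- if (endsWith(mode, "3d")) c("xcorr", "delta_cn", "sp_score")
          else "xcorr"
  psms <- as.data.frame(psms)
  if (two_group && any(psms$group == "unassigned"))
    stop_validation("two-group mode requires every PSM to carry a group ",
                    "label (classify peptides first)")

  strata <- stratify_by_charge(psms)
  strata <- strata[vapply(strata, nrow, integer(1)) > 0]
  small <- names(strata)[vapply(strata, nrow, integer(1)) < min_psm_warning]
  if (length(small))
    warning("stratum/strata ", paste(small, collapse = ", "),
            " below ", min_psm_warning,
            " PSMs; histogram densities may be noisy")

  grids <- list()
  gamma_all <- numeric(nrow(psms))
  stratum_of <- charge_stratum(psms$charge)
  for (s in names(strata)) {
    g <- build_score_grid(strata[[s]], dims = dims, bins = bins,
                          smooth = smooth, smooth_window = smooth_window,
                          eps0 = eps0, eps1 = eps1)
    grids[[s]] <- g
    rows <- stratum_of == s
    gamma_all[rows] <- g$gamma[grid_cell(psms[rows, , drop = FALSE],
                                         g$edges)]
  }

  groups <- if (two_group) c("proteome", "noncanonical") else "all"
  priors <- list()
  lfdr_all <- numeric(nrow(psms))
  for (grp in groups) {
    rows <- if (two_group) psms$group == grp else rep(TRUE, nrow(psms))
    priors[[grp]] <- estimate_group_priors(psms[rows, , drop = FALSE],
                                           group = grp, eps = pi_eps,
                                           cap = pi_cap)
    lfdr_all[rows] <- lfdr(gamma_all[rows], priors[[grp]]$pi_ratio)
  }

  targets <- !psms$is_decoy
  res_psms <- psms[targets, , drop = FALSE]
  res_psms$gamma <- gamma_all[targets]
  res_psms$lfdr <- lfdr_all[targets]
  res_psms$accepted <- FALSE
  thresholds <- achieved <- decoy_est <- setNames(
    numeric(length(groups)), groups)
  for (grp in groups) {
    rows <- if (two_group) res_psms$group == grp
            else rep(TRUE, nrow(res_psms))
    drows <- if (two_group) psms$is_decoy & psms$group == grp
             else psms$is_decoy
    sel <- if (threshold_rule == "decoy")
      select_threshold_decoy(res_psms$lfdr[rows], lfdr_all[drows],
                             alpha = alpha)
    else
      select_threshold(res_psms$lfdr[rows], alpha = alpha)
    res_psms$accepted[rows] <- sel$accepted
    thresholds[grp] <- sel$threshold
    achieved[grp] <- sel$achieved_fdr_estimate
    n_acc <- sum(sel$accepted)
    decoy_est[grp] <- if (n_acc > 0)
      sum(lfdr_all[drows] <= sel$threshold) / n_acc else NA_real_
  }
  structure(list(psms = res_psms, thresholds = thresholds,
                 achieved = achieved, decoy_fdr_estimate = decoy_est,
                 priors = priors, grids = grids, mode = mode,
                 alpha = alpha, threshold_rule = threshold_rule),
            class = "lfdr_result")
}

#' @export
print.lfdr_result <- function(x, ...) {
  cat("Composite local-FDR result (mode ", x$mode, ", alpha ", x$alpha,
      ")\n", sep = "")
  for (grp in names(x$thresholds)) {
    pr <- x$priors[[grp]]
    cat(sprintf(
      " group %-12s pi1/pi0 %8.3f  threshold %.4g  accepted %d/%d\n",
      grp, pr$pi_ratio, x$thresholds[grp],
      sum(x$psms$accepted[x$psms$group == grp | grp == "all"]),
      if (grp == "all") nrow(x$psms) else sum(x$psms$group == grp)))
  }
  invisible(x)
}

#' Accepted target PSMs of an lfdr_result
#' @param result an `lfdr_result`.
#' @export
accepted_psms <- function(result) {
  result$psms[result$psms$accepted, , drop = FALSE]
}
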