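test_that("charge stratification is exhaustive and disjoint", {
  df <- make_psm_df(60, seed = 2, charges = c(1, 2, 3, 4, 5))
  strata <- stratify_by_charge(df)
  expect_named(strata, c("Z1", "Z2", "Z3plus"))
  expect_equal(sum(vapply(strata, nrow, integer(1))), nrow(df))
  expect_true(all(strata$Z1$charge == 1))
  expect_true(all(strata$Z2$charge == 2))
  expect_true(all(strata$Z3plus$charge >= 3))
  none <- stratify_by_charge(df[0, ])
  expect_equal(vapply(none, nrow, integer(1)),
               c(Z1 = 0L, Z2 = 0L, Z3plus = 0L))
  all2 <- stratify_by_charge(data.frame(charge = rep(2, 5)))
  expect_equal(nrow(all2$Z1) + nrow(all2$Z3plus), 0)
})

test_that("score grid counting follows the decoy rule and normalizes", {
  # all PSMs in one corner cell: n0 = decoys, n1 = targets - decoys
  df <- make_psm_df(12, seed = 3, charges = 2)
  df$xcorr <- c(rep(1, 11), 5)       # one point stretches the range
  df$delta_cn <- c(rep(0.1, 11), 0.9)
  df$sp_score <- c(rep(100, 11), 900)
  df$is_decoy <- c(rep(FALSE, 9), rep(TRUE, 2), FALSE)
  # degenerate without the stretcher: identical scores -> error
  expect_error(build_score_grid(df[1:11, ], bins = 3), "degenerate")
  g <- build_score_grid(df, bins = 3, smooth = FALSE)
  expect_equal(g$n0_raw[1, 1, 1], 2)
  expect_equal(g$n1_raw[1, 1, 1], 9 - 2)
  expect_equal(sum(g$p0), 1, tolerance = 1e-9)
  expect_equal(sum(g$p1), 1, tolerance = 1e-9)
  expect_true(all(is.finite(g$gamma)))

  # smoothing by a constant leaves a uniform grid unchanged
  u <- array(4, c(3, 3, 3))
  expect_equal(peplfdr:::box_smooth(u, 1), u)

  # smoothed arrays equal the brute-force per-cell box mean
  set.seed(5)
  a <- array(rpois(125, 3), c(5, 5, 5))
  sm <- peplfdr:::box_smooth(a, 1)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    nb <- expand.grid(i + (-1:1), j + (-1:1), k + (-1:1))
    nb <- nb[apply(nb >= 1 & nb <= 5, 1, all), ]
    expect_equal(sm[i, j, k], mean(a[as.matrix(nb)]))
  }
})

test_that("lfdr follows the closed form with its analytic limits", {
  expect_equal(lfdr(1, 1), 0.5)
  expect_equal(lfdr(0, 7), 1.0)
  expect_equal(lfdr(9, 3), 1 / 28)
  expect_error(lfdr(-1, 1), ">= 0")
  # strictly decreasing in gamma and in pi_ratio
  g <- sort(runif(20, 0.01, 50))
  expect_true(all(diff(lfdr(g, 2)) < 0))
  p <- sort(runif(20, 0.01, 50))
  expect_true(all(diff(lfdr(2, p)) < 0))
})

test_that("group priors follow the target-decoy estimate with guards", {
  mk <- function(t, d) data.frame(is_decoy = rep(c(FALSE, TRUE), c(t, d)))
  expect_equal(estimate_group_priors(mk(900, 100))$pi_ratio, 8)
  expect_equal(estimate_group_priors(mk(100, 100))$pi_ratio, 0)
  expect_equal(estimate_group_priors(mk(50, 0))$pi_ratio, 50)
  expect_error(estimate_group_priors(mk(0, 10)), "one_group")
  expect_warning(
    capped <- estimate_group_priors(mk(2e6 + 1, 0), cap = 1e6)$pi_ratio,
    "capped")
  expect_equal(capped, 1e6)
})

test_that("mean-lfdr threshold selection matches cumulative-mean enumeration", {
  # at alpha = 0.01 the three 0.9-lfdr PSMs push the running mean over
  # the bound as soon as the 98th PSM enters (mean 0.0102), so exactly
  # the 97 confident PSMs are accepted; at alpha = 0.03 the running mean
  # never exceeds the bound (0.028 at PSM 100) and all pass
  lf <- c(rep(0.001, 97), rep(0.9, 3))
  sel <- select_threshold(lf, alpha = 0.01)
  expect_equal(sum(sel$accepted), 97)
  expect_true(all(sel$accepted[1:97]))
  expect_equal(sum(select_threshold(lf, alpha = 0.03)$accepted), 100)
  # brute-force check of the rule on random values
  set.seed(8)
  lfr <- runif(200)^3
  alpha <- 0.1
  sel2 <- select_threshold(lfr, alpha)
  o <- order(lfr)
  best <- 0
  for (k in seq_along(o))
    if (mean(lfr[o[1:k]]) <= alpha) best <- k
  expect_equal(sum(sel2$accepted), best)
  expect_true(sel2$achieved_fdr_estimate <= alpha)
  expect_equal(sum(select_threshold(lfr, 0.999)$accepted), 200)
  expect_warning(none <- select_threshold(c(0.5, 0.6), 0.01), "no PSM")
  expect_equal(sum(none$accepted), 0)
})

test_that("decoy-counting threshold controls the decoy/target ratio", {
  set.seed(10)
  tl <- runif(500)^2
  dl <- runif(300)^0.5   # decoys skew to high lfdr
  sel <- select_threshold_decoy(tl, dl, alpha = 0.05)
  expect_true(sel$achieved_fdr_estimate <= 0.05)
  expect_equal(sel$achieved_fdr_estimate,
               sum(dl <= sel$threshold) / sum(tl <= sel$threshold))
  # enumeration: no larger threshold keeps the estimate under alpha
  cand <- sort(unique(c(tl, dl)))
  above <- cand[cand > sel$threshold]
  est <- vapply(above, function(th)
    sum(dl <= th) / max(sum(tl <= th), 1), numeric(1))
  expect_true(all(est > 0.05))
})

test_that("per-PSM lfdr equals the naive triple-loop oracle", {
  for (cfg in list(list(n = 200, bins = 3, mode = "2g3d"),
                   list(n = 500, bins = 5, mode = "1g3d"),
                   list(n = 400, bins = 6, mode = "2g1d"))) {
    df <- make_psm_df(cfg$n, seed = cfg$n + cfg$bins)
    res <- suppressWarnings(run_composite_fdr(
      df, mode = cfg$mode, bins = cfg$bins, min_psm_warning = 0))
    want <- oracle_lfdr_pipeline(df, mode = cfg$mode, bins = cfg$bins)
    targ <- !df$is_decoy
    expect_equal(res$psms$gamma, want$gamma[targ], tolerance = 1e-12)
    expect_equal(res$psms$lfdr, want$lfdr[targ], tolerance = 1e-12)
  }
})

test_that("identical priors collapse two-group mode onto one-group mode", {
  # the noncanonical group is an exact copy of the proteome group, so the
  # two group priors coincide and Eq. (1) gives every PSM the same lfdr
  # in both modes
  base <- make_psm_df(400, seed = 21, charges = 2, frac_nc = 0)
  copy <- base
  copy$group <- "noncanonical"
  copy$spectrum_key <- sub("^s", "t", copy$spectrum_key)
  df <- rbind(base, copy)
  r1 <- suppressWarnings(run_composite_fdr(df, "1g3d", bins = 4,
                                           min_psm_warning = 0))
  r2 <- suppressWarnings(run_composite_fdr(df, "2g3d", bins = 4,
                                           min_psm_warning = 0))
  expect_equal(r2$priors$proteome$pi_ratio,
               r2$priors$noncanonical$pi_ratio)
  expect_equal(r1$psms$lfdr, r2$psms$lfdr, tolerance = 1e-12)
  expect_identical(sort(r1$psms$spectrum_key[r1$psms$accepted]),
                   sort(r2$psms$spectrum_key[r2$psms$accepted]))
})

test_that("acceptance is monotone in alpha", {
  df <- make_psm_df(2000, seed = 31)
  alphas <- c(0.01, 0.03, 0.1, 0.3)
  prev <- NULL
  for (a in alphas) {
    res <- suppressWarnings(run_composite_fdr(df, "2g3d", bins = 5,
                                              alpha = a,
                                              min_psm_warning = 0))
    acc <- accepted_psms(res)$spectrum_key
    if (!is.null(prev)) expect_true(all(prev %in% acc))
    prev <- acc
  }
})

test_that("two-group mode requires group labels and warns on small strata", {
  df <- make_psm_df(50, seed = 1)
  df$group <- "unassigned"
  expect_error(run_composite_fdr(df, "2g3d"), "group")
  df2 <- make_psm_df(300, seed = 2)
  expect_warning(run_composite_fdr(df2, "2g3d", bins = 3,
                                   min_psm_warning = 1000), "below")
})
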