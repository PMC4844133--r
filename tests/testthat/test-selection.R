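test_that("model enumeration covers all subsets deterministically", {
  labs <- c("SoL_aff", "S_prox", "L_adj", "S_adj")
  specs <- enumerate_models(labs)
  expect_length(specs, 16)
  expect_equal(specs[[1]], character(0))  # null first
  expect_equal(lengths(specs), sort(lengths(specs)))
  expect_identical(specs, enumerate_models(labs))       # stable
  expect_identical(specs, enumerate_models(rev(labs)))  # order-insensitive
  expect_length(enumerate_models("A"), 2)
  expect_error(enumerate_models(character(0)))
  expect_error(enumerate_models(letters[1:5]))
})

test_that("Bayes factor doubles the BIC difference", {
  expect_equal(bayes_factor(3.53), 7.06)
  expect_equal(bayes_factor(1.74), 3.48)
  expect_equal(bayes_factor(0), 0)
  expect_error(bayes_factor(-0.1), "nonnegative")
  expect_equal(as.character(bf_band(bayes_factor(c(0.5, 2, 3.53)))),
               c("weak", "positive", "strong"))
})

test_that("bin sweep ranks all 16 models by ascending BIC", {
  w <- tiny_world(seed = 13)
  y <- sample_disturbance_outcome(list(w$weights$S_adj), 0.7, 1, 0, seed = 2)
  sw <- sweep_bin(y, w$weights)
  expect_equal(nrow(sw), 16)
  b <- sw$bic[order(sw$rank)]
  expect_true(all(diff(b) >= -1e-9))
  expect_true(all(sw$converged))
  # ranked list contains every spec exactly once
  expect_setequal(sw$model, vapply(enumerate_models(names(w$weights)),
                                   function(s) if (length(s)) paste(s, collapse = "+") else "null",
                                   ""))
})

test_that("selection tables aggregate inclusions consistently", {
  w <- tiny_world(seed = 14)
  p <- make_disturbance_panel(list(w$weights$S_adj), 0.75, n_bins = 8, seed = 6)
  st <- sweep_panel(p, w$weights)
  expect_equal(length(st$bins), 8)
  freq <- inclusion_frequencies(st)
  # each bin contributes exactly one preferred and one second model
  expect_equal(sum(freq$by_model$preferred), 8)
  expect_equal(sum(freq$by_model$second), 8)
  expect_equal(freq$by_matrix$overall,
               freq$by_matrix$preferred + freq$by_matrix$second)
  expect_true(all(freq$by_matrix$overall <= 2 * 8))
  # signal planted on S_adj: it collects the most top-two inclusions
  ov <- setNames(freq$by_matrix$overall, freq$by_matrix$matrix)
  expect_equal(names(which.max(ov)), "S_adj")
  g <- median_bic_gaps(st)
  expect_gte(g["gap12"], 0)
  expect_gte(g["gap13"], g["gap12"])
})

test_that("pure-noise panels mostly prefer the null model", {
  w <- tiny_world(seed = 15)
  set.seed(31)
  vals <- matrix(rnorm(length(w$nodes$ids) * 12), ncol = 12,
                 dimnames = list(w$nodes$ids, NULL))
  p <- panel_outcome(pmin(pmax(vals, -10), 10), 1898 + 2 * (0:11), 2,
                     "polity_state")
  st <- sweep_panel(p, w$weights)
  freq <- inclusion_frequencies(st)
  null_pref <- freq$by_model$preferred[freq$by_model$model == "null"]
  expect_gt(null_pref, 12 / 4)  # plurality winner by a wide margin
  expect_equal(names(which.max(setNames(freq$by_model$preferred,
                                        freq$by_model$model))), "null")
})

test_that("significance census counts bins and collects significant rho", {
  w <- tiny_world(seed = 16)
  # strong planted signal on the tested matrix
  p <- make_disturbance_panel(list(w$weights$S_adj), 0.8, n_bins = 10, seed = 3)
  cs <- significance_census(p, w$weights$S_adj)
  expect_equal(cs$n_tested, 10)
  expect_gte(cs$n_significant, 7)
  expect_length(cs$sig_rho, cs$n_significant)
  expect_true(all(cs$sig_rho > 0))
  # an unrelated matrix stays near the nominal rate
  cs2 <- significance_census(p, w$weights$L_adj)
  expect_lte(cs2$n_significant, 4)
  # test_start drops early bins from the census
  cs3 <- significance_census(p, w$weights$S_adj, test_start = 1904)
  expect_equal(cs3$n_tested, 7)
})

test_that("significant-rho summary matches hand-computed t statistics", {
  cs <- structure(list(matrix = "X", sig_rho = c(0.12, 0.13, 0.14),
                       n_significant = 3L, n_tested = 10L),
                  class = "significance_census")
  s <- summarize_significant_rhos(cs)
  expect_equal(s$mean, 0.13)
  expect_equal(s$df, 2)
  # frozen from the closed-form one-sample t: t = 0.13/(0.01/sqrt(3))
  expect_equal(s$p, 0.0019665702, tolerance = 1e-6)
  expect_equal(s$ci, c(0.1051586, 0.1548414), tolerance = 1e-6)
  # degenerate censuses are flagged, not errors
  cs$sig_rho <- c(0.2, 0.2, 0.2)
  expect_equal(summarize_significant_rhos(cs)$flag, "zero_variance")
  cs$sig_rho <- numeric(0)
  expect_equal(summarize_significant_rhos(cs)$flag, "too_few")
  cs$sig_rho <- 0.4
  s1 <- summarize_significant_rhos(cs)
  expect_equal(s1$flag, "too_few")
  expect_equal(s1$mean, 0.4)
})

test_that("even/odd robustness fractions follow the inclusion pattern", {
  # hand-built selection table: matrix A in top two on chosen bins only
  mk_sweep <- function(top) {
    models <- c(top, setdiff(c("A", "B", "null", "A+B"), top))
    structure(data.frame(model = models, k = 0, loglik = 0,
                         bic = seq_along(models), converged = TRUE,
                         rank = seq_along(models)),
              class = c("bin_sweep", "data.frame"))
  }
  st <- structure(list(
    bins = c(1900, 1902, 1904, 1906),
    sweeps = list(`1900` = mk_sweep(c("A", "B")),
                  `1902` = mk_sweep(c("A+B", "null")),
                  `1904` = mk_sweep(c("B", "null")),
                  `1906` = mk_sweep(c("null", "A"))),
    skipped = data.frame(), labels = c("A", "B")),
    class = "selection_table")
  r <- even_odd_robustness(st, "A")  # included on bins 1, 2, 4
  expect_equal(r$even_fraction, 2 / 3)
  expect_equal(r$n_even + r$n_odd, 3)
  # all inclusions on even-indexed bins
  st2 <- st
  st2$sweeps <- list(`1900` = mk_sweep(c("B", "null")),
                     `1902` = mk_sweep(c("A", "B")),
                     `1904` = mk_sweep(c("null", "B")),
                     `1906` = mk_sweep(c("A+B", "B")))
  expect_equal(even_odd_robustness(st2, "A")$even_fraction, 1)
  # no inclusions is flagged, not an error
  st3 <- st
  st3$sweeps <- rep(list(mk_sweep(c("B", "null"))), 4)
  names(st3$sweeps) <- names(st$sweeps)
  expect_equal(even_odd_robustness(st3, "A")$flag, "no_inclusions")
})

test_that("census results are bit-reproducible on fixed panels", {
  w <- tiny_world(seed = 17)
  p <- make_disturbance_panel(list(w$weights$S_adj), 0.6, n_bins = 5, seed = 9)
  c1 <- significance_census(p, w$weights$S_adj)
  c2 <- significance_census(p, w$weights$S_adj)
  expect_identical(c1$rho_all, c2$rho_all)
  expect_identical(c1$p_all, c2$p_all)
})
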