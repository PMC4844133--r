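#' Enumerate all weight-matrix subsets
#'
#' All \eqn{2^k} model specifications over the supplied matrix labels:
#' the null (intercept-only) model first, then by increasing size, ties in
#' C-locale lexicographic label order. Deterministic across runs.
#'
#' @param labels Character vector of 1-4 matrix labels.
#' @return List of character vectors (the null model is `character(0)`).
#' @export
enumerate_models <- function(labels) {
  if (length(labels) < 1 || length(labels) > 4)
    stop("between 1 and 4 matrices supported")
  if (anyDuplicated(labels)) stop("labels must be unique")
  subsets <- list(character(0))
  for (size in seq_along(labels)) {
    combos <- utils::combn(sort(labels, method = "radix"), size,
                           simplify = FALSE)
    key <- vapply(combos, paste, "", collapse = "+")
    subsets <- c(subsets, combos[order(key, method = "radix")])
  }
  subsets
}

model_label <- function(spec) if (length(spec) == 0) "null" else paste(spec, collapse = "+")

#' Exhaustive BIC sweep over one time bin
#'
#' Fits every subset of the supplied weight matrices to the aligned outcome
#' vector and ranks the models by BIC (ascending). Ties within 1e-6 are
#' broken by fewer matrices, then lexicographic model label; non-converged
#' fits rank last and are flagged.
#'
#' @param y Aligned outcome vector (from [align_bin()]).
#' @param weights Aligned list of [weight_matrix] objects.
#' @param se Compute per-rho standard errors (off by default in sweeps).
#' @return Data frame of class `bin_sweep`: columns `model`, `k`, `loglik`,
#'   `bic`, `converged`, `rank`, plus the fits as an attribute.
#' @export
sweep_bin <- function(y, weights, se = FALSE) {
  labels <- vapply(weights, function(w) attr(w, "label"), "")
  names(weights) <- labels
  specs <- enumerate_models(labels)
  fits <- lapply(specs, function(spec) {
    tryCatch(fit_disturbance(disturbance_model(y, weights[spec]), se = se),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  conv <- vapply(fits, function(f) !is.null(f) && f$converged, TRUE)
  df <- data.frame(
    model = vapply(specs, model_label, ""),
    k = lengths(specs),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik, 0),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 0),
    converged = conv,
    stringsAsFactors = FALSE
  )
  bic_key <- ifelse(conv, round(df$bic / 1e-6) * 1e-6, Inf)
  ord <- order(bic_key, df$k, df$model, method = "radix")
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "fits") <- stats::setNames(fits[ord], df$model)
  attr(df, "labels") <- labels
  class(df) <- c("bin_sweep", "data.frame")
  df
}

#' Sweep every bin of a panel
#'
#' Runs [align_bin()] plus [sweep_bin()] for each bin at or after
#' `test_start`; bins with fewer than 3 countries, a constant outcome, or
#' other degeneracies are skipped and logged.
#'
#' @param p A [panel_outcome].
#' @param weights List of [weight_matrix] objects on the full node set.
#' @param test_start Optional first bin start year to test (earlier bins
#'   are excluded, e.g. default-state tests starting from 1904).
#' @param verbose Print a note per skipped bin.
#' @return Object of class `selection_table`: list with `bins` (start
#'   years swept), `sweeps` (list of `bin_sweep`), `skipped`
#'   (data frame of bin, reason), `labels`.
#' @export
sweep_panel <- function(p, weights, test_start = NULL, verbose = FALSE) {
  stopifnot(inherits(p, "panel_outcome"))
  labels <- vapply(weights, function(w) attr(w, "label"), "")
  idx <- seq_along(p$bin_start)
  if (!is.null(test_start)) idx <- idx[p$bin_start >= test_start]
  sweeps <- list(); bins <- integer(0)
  skipped <- data.frame(bin = integer(0), reason = character(0))
  for (b in idx) {
    res <- tryCatch({
      al <- align_bin(p, b, weights)
      if (stats::var(al$y) == 0) stop("constant outcome in bin")
      sweep_bin(al$y, al$weights)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(bin = p$bin_start[b],
                                  reason = conditionMessage(res)))
      if (verbose) message("skipping bin ", p$bin_start[b], ": ",
                           conditionMessage(res))
    } else {
      bins <- c(bins, p$bin_start[b])
      sweeps[[as.character(p$bin_start[b])]] <- res
    }
  }
  structure(list(bins = bins, sweeps = sweeps, skipped = skipped,
                 labels = labels),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat("selection_table:", length(x$bins), "bins swept,",
      nrow(x$skipped), "skipped; matrices:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' BIC-difference to Bayes-factor conversion
#'
#' The reporting convention doubles the BIC difference (the 2 log BF
#' scale), read against the Kass-Raftery bands: 0-2 weak, 2-6 positive,
#' 6-10 strong, >10 very strong.
#'
#' @param delta_bic Nonnegative BIC difference(s).
#' @return `2 * delta_bic`.
#' @export
bayes_factor <- function(delta_bic) {
  if (any(delta_bic < 0)) stop("delta_bic must be nonnegative")
  2 * delta_bic
}

#' Interpretation band of a Bayes factor on the 2 log BF scale
#'
#' @param bf Value from [bayes_factor()].
#' @return Character band label.
#' @export
bf_band <- function(bf) {
  cut(bf, c(-Inf, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"))
}

top_two <- function(sweep) sweep$model[sweep$rank <= 2]

#' Inclusion frequencies of each matrix in the top-two models
#'
#' Counts, per matrix, how often it appears in the preferred and in the
#' 2nd-best model across bins; `overall = preferred + second` (a matrix in
#' both models of one bin counts twice). Also returns the per-model-spec
#' frequency table (rows = model specs, columns preferred / 2nd best).
#'
#' @param st A `selection_table`.
#' @return List with `by_matrix` (data frame: matrix, preferred, second,
#'   overall) and `by_model` (data frame: model, preferred, second).
#' @export
inclusion_frequencies <- function(st) {
  stopifnot(inherits(st, "selection_table"))
  if (length(st$bins) < 1) stop("no swept bins")
  specs <- vapply(enumerate_models(st$labels), model_label, "")
  pref <- vapply(st$sweeps, function(s) s$model[s$rank == 1], "")
  secd <- vapply(st$sweeps, function(s) s$model[s$rank == 2], "")
  by_model <- data.frame(
    model = specs,
    preferred = as.integer(table(factor(pref, levels = specs))),
    second = as.integer(table(factor(secd, levels = specs)))
  )
  in_model <- function(lab, models)
    sum(vapply(strsplit(models, "+", fixed = TRUE),
               function(s) lab %in% s, TRUE))
  by_matrix <- data.frame(
    matrix = st$labels,
    preferred = vapply(st$labels, in_model, 0L, models = pref),
    second = vapply(st$labels, in_model, 0L, models = secd)
  )
  by_matrix$overall <- by_matrix$preferred + by_matrix$second
  rownames(by_matrix) <- NULL
  list(by_matrix = by_matrix, by_model = by_model)
}

#' Median BIC gaps between the top-ranked models
#'
#' Across bins, the median gap from the preferred to the 2nd-best model
#' and from the preferred to the 3rd-best.
#'
#' @param st A `selection_table`.
#' @return Named numeric: `gap12`, `gap13`.
#' @export
median_bic_gaps <- function(st) {
  stopifnot(inherits(st, "selection_table"))
  g <- vapply(st$sweeps, function(s) {
    b <- s$bic[order(s$rank)]
    c(b[2] - b[1], b[3] - b[1])
  }, numeric(2))
  c(gap12 = stats::median(g[1, ], na.rm = TRUE),
    gap13 = stats::median(g[2, ], na.rm = TRUE))
}

#' Single-matrix significance census across bins
#'
#' Fits the one-matrix model in every estimable bin and counts bins where
#' the matrix's autocorrelation is significant at `alpha` (two-sided z).
#'
#' @param p A [panel_outcome].
#' @param w A single [weight_matrix].
#' @param alpha Significance level.
#' @param test_start Optional first bin start year to test.
#' @return Object of class `significance_census`: list with `matrix`,
#'   `n_significant`, `n_tested`, `sig_rho` (estimates from significant
#'   bins), `sig_bins`, `tested_bins`, `skipped`, `rho_all`, `p_all`.
#' @export
significance_census <- function(p, w, alpha = 0.05, test_start = NULL) {
  stopifnot(inherits(p, "panel_outcome"))
  idx <- seq_along(p$bin_start)
  if (!is.null(test_start)) idx <- idx[p$bin_start >= test_start]
  tested <- integer(0); rho <- numeric(0); pv <- numeric(0)
  skipped <- data.frame(bin = integer(0), reason = character(0))
  for (b in idx) {
    res <- tryCatch({
      al <- align_bin(p, b, list(w))
      if (stats::var(al$y) == 0) stop("constant outcome in bin")
      fit_disturbance(disturbance_model(al$y, al$weights), se = TRUE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(bin = p$bin_start[b],
                                  reason = conditionMessage(res)))
    } else {
      tested <- c(tested, p$bin_start[b])
      rho <- c(rho, res$rho[1])
      pv <- c(pv, res$rho_p[1])
    }
  }
  sig <- !is.na(pv) & pv < alpha
  structure(list(matrix = attr(w, "label"),
                 n_significant = sum(sig), n_tested = length(tested),
                 sig_rho = rho[sig], sig_bins = tested[sig],
                 tested_bins = tested, skipped = skipped,
                 rho_all = stats::setNames(rho, tested),
                 p_all = stats::setNames(pv, tested), alpha = alpha),
            class = "significance_census")
}

#' @export
print.significance_census <- function(x, ...) {
  cat("significance_census '", x$matrix, "': ", x$n_significant, " of ",
      x$n_tested, " bins significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' One-sample t summary of the significant autocorrelations
#'
#' Groups the significant rho estimates across bins and tests their mean
#' against zero (one-sample t, df = count - 1, 95 percent CI).
#'
#' @param census A `significance_census`.
#' @return List with `mean`, `ci` (length 2), `p`, `df`, `n`, `flag`
#'   (`"ok"`, `"too_few"`, or `"zero_variance"`).
#' @export
summarize_significant_rhos <- function(census) {
  v <- census$sig_rho
  if (length(v) < 2)
    return(list(mean = if (length(v)) mean(v) else NA_real_,
                ci = c(NA_real_, NA_real_), p = NA_real_,
                df = length(v) - 1, n = length(v), flag = "too_few"))
  if (stats::sd(v) == 0)
    return(list(mean = mean(v), ci = c(mean(v), mean(v)), p = NA_real_,
                df = length(v) - 1, n = length(v), flag = "zero_variance"))
  tt <- stats::t.test(v, mu = 0)
  list(mean = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       p = tt$p.value, df = unname(tt$parameter), n = length(v), flag = "ok")
}

#' Even/odd temporal robustness of top-two inclusions
#'
#' Of the bins where `matrix` sits in the top-two models, the fraction
#' whose (1-based) bin index is even — near 50 percent when a finding is
#' not driven by temporally clustered adjacent intervals.
#'
#' @param st A `selection_table`.
#' @param matrix Matrix label.
#' @return List with `even_fraction`, `n_even`, `n_odd`, `flag`.
#' @export
even_odd_robustness <- function(st, matrix) {
  stopifnot(inherits(st, "selection_table"))
  included <- vapply(st$sweeps, function(s)
    matrix %in% unlist(strsplit(top_two(s), "+", fixed = TRUE)), TRUE)
  idx <- seq_along(st$bins)[included]
  if (length(idx) == 0)
    return(list(even_fraction = NA_real_, n_even = 0L, n_odd = 0L,
                flag = "no_inclusions"))
  n_even <- sum(idx %% 2 == 0)
  list(even_fraction = n_even / length(idx), n_even = n_even,
       n_odd = length(idx) - n_even, flag = "ok")
}

#' Write a Table-1/2-shaped frequency CSV
#'
#' Model-spec rows with preferred / 2nd-best counts, followed by the
#' per-matrix frequency footer.
#'
#' @param freq Output of [inclusion_frequencies()].
#' @param path File path.
#' @export
write_frequency_csv <- function(freq, path) {
  top <- freq$by_model
  foot <- data.frame(model = paste("frequency", freq$by_matrix$matrix,
                                   "included"),
                     preferred = freq$by_matrix$preferred,
                     second = freq$by_matrix$second)
  utils::write.csv(rbind(top, foot), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
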