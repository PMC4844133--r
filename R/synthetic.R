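#' Toy socio-linguistic distance matrix from a random family-structured tree
#'
#' Simulates an ultrametric language tree with the nested structure of a
#' real language-family sample — a handful of families that split from one
#' another deep in time (55-100 percent of `depth_years`), shallow random
#' coalescent trees within each family (15-45 percent of the depth) — and
#' returns the patristic (cophenetic) distance matrix in years. Optionally
#' attaches `n_colonies` colony nodes to randomly chosen parent tips at
#' recent split times: a colony sits at distance `2 * split` years from
#' its parent (path up to the split and back down) and inherits the
#' parent's distances to everyone else, which keeps the matrix additive
#' over the generating tree.
#'
#' @param n_tips Number of language tips (>= 2).
#' @param depth_years Root-to-tip depth in years.
#' @param n_colonies Number of colonial offshoots to attach.
#' @param colony_range Range of colony split times, years before present.
#' @param n_families Number of deep clades; default about one per 6 tips.
#' @param n_powers Number of distinct colonial-power parent tips.
#' @param seed Random seed.
#' @return A [distance_matrix] in years, ids `L1..` and `C1..`.
#' @export
make_toy_phylogeny <- function(n_tips, depth_years = 6000, n_colonies = 0,
                               colony_range = c(50, 400),
                               n_families = NULL, n_powers = 4, seed = 1) {
  if (n_tips < 2) stop("need at least 2 tips")
  set.seed(seed)
  if (is.null(n_families)) n_families <- max(2, round(n_tips / 6))
  n_families <- max(1, min(n_families, floor(n_tips / 2)))
  if (n_tips == 2) {
    d <- matrix(c(0, 2 * depth_years, 2 * depth_years, 0), 2, 2,
                dimnames = list(c("L1", "L2"), c("L1", "L2")))
  } else {
    ids <- paste0("L", seq_len(n_tips))
    fam <- sort(rep_len(seq_len(n_families), n_tips))
    # join depths between families: an ultrametric family-level tree with
    # its nodes mapped into the deep band of the timescale
    if (n_families > 1) {
      fd <- join_depths(n_families) # in (0, 1]
      fam_join <- depth_years * (0.55 + 0.45 * fd)
    }
    d <- matrix(0, n_tips, n_tips, dimnames = list(ids, ids))
    for (f in seq_len(n_families)) {
      tips_f <- which(fam == f)
      m <- length(tips_f)
      if (m > 1) {
        wdepth <- stats::runif(1, 0.15, 0.45) * depth_years
        d[tips_f, tips_f] <- 2 * wdepth * join_depths(m)
      }
    }
    if (n_families > 1) {
      for (f in seq_len(n_families - 1)) for (g in (f + 1):n_families) {
        tf <- which(fam == f); tg <- which(fam == g)
        d[tf, tg] <- 2 * fam_join[f, g]
        d[tg, tf] <- 2 * fam_join[f, g]
      }
    }
  }
  if (n_colonies > 0) {
    # colonies concentrate on a few colonial powers, so the matrix gets
    # the large blocks of very recent splits a colonial sample has
    powers <- sample(rownames(d), min(n_powers, nrow(d)))
    parents <- sample(powers, n_colonies, replace = TRUE)
    splits <- stats::runif(n_colonies, colony_range[1], colony_range[2])
    for (ci in seq_len(n_colonies)) {
      id <- paste0("C", ci)
      row <- d[parents[ci], ]  # path to anyone else runs through the parent lineage
      d <- rbind(cbind(d, row), c(row, 0))
      rownames(d)[nrow(d)] <- id
      colnames(d)[ncol(d)] <- id
      d[id, parents[ci]] <- d[parents[ci], id] <- 2 * splits[ci]
      if (ci > 1) {
        sisters <- which(parents[seq_len(ci - 1)] == parents[ci])
        for (sj in sisters) {
          # sister colonies branch off the same terminal lineage at
          # depths s_i and s_j: patristic distance is s_i + s_j
          sid <- paste0("C", sj)
          d[id, sid] <- d[sid, id] <- splits[ci] + splits[sj]
        }
      }
    }
  }
  distance_matrix(d, units = "years")
}

# normalized pairwise join depths of a random coalescent tree:
# symmetric matrix in [0, 1] with zero diagonal, ultrametric
join_depths <- function(m) {
  if (m == 2) return(matrix(c(0, 1, 1, 0), 2, 2))
  co <- ape::cophenetic.phylo(ape::rcoal(m)) / 2
  co / max(co)
}

#' Synthetic study world
#'
#' Bundles everything the empirical pipeline consumes, with known ground
#' truth: a node set with coordinates, a tree-derived socio-linguistic
#' distance matrix (with colonial splits), a spatial distance matrix, a
#' border adjacency, and the four derived weight matrices under the study
#' labels `SoL_aff`, `S_prox`, `L_adj`, `S_adj`.
#'
#' Coordinates cluster into continent-like regions (a few widely separated
#' region centres with countries scattered a few hundred km around them),
#' so spatial affinities get the near-0 to near-1 contrast of a real
#' country sample; borders connect each country to its spatially nearest
#' neighbours, which gives a sparse, connected-ish adjacency like a
#' land-border graph.
#'
#' @param n_countries Number of countries; the default is roughly the
#'   scale of a one-language-family country sample.
#' @param depth_years Phylogeny depth in years.
#' @param n_colonies Colonial offshoots (counted inside `n_countries`);
#'   colony-heavy by default, as in a sample where much of the world
#'   speaks a colonial language.
#' @param intelligibility_years Language-adjacency threshold in years.
#' @param border_k Nearest-neighbour count for the synthetic border graph.
#' @param n_regions Number of continent-like coordinate clusters.
#' @param seed Random seed.
#' @return Object of class `synthetic_world`: list with `nodes`,
#'   `lang_dist`, `geo_dist`, `border_adj` and `weights` (named list of
#'   the four [weight_matrix] objects).
#' @export
make_synthetic_world <- function(n_countries = 56, depth_years = 6000,
                                 n_colonies = 20,
                                 intelligibility_years = 1000,
                                 border_k = 3, n_regions = 5, seed = 1) {
  if (n_countries < 4) stop("need at least 4 countries")
  n_tips <- n_countries - n_colonies
  lang <- make_toy_phylogeny(n_tips, depth_years, n_colonies, seed = seed)
  ids <- rownames(lang)
  set.seed(seed + 1)
  centre_lat <- stats::runif(n_regions, -35, 55)
  centre_lon <- stats::runif(n_regions, -160, 160)
  region <- rep_len(seq_len(n_regions), n_countries)[sample(n_countries)]
  nodes <- node_set(ids,
                    lat = pmin(pmax(centre_lat[region] +
                                      stats::rnorm(n_countries, 0, 7), -89), 89),
                    lon = pmin(pmax(centre_lon[region] +
                                      stats::rnorm(n_countries, 0, 9), -179), 179))
  geo <- spatial_distance_matrix(nodes)
  # k-nearest-neighbour borders, symmetrized
  n <- n_countries
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    nb <- order(geo[i, ])[2:(border_k + 1)]
    adj[i, nb] <- 1
  }
  adj <- 1 * ((adj + t(adj)) > 0)
  diag(adj) <- 0
  weights <- list(
    SoL_aff = distance_to_affinity(lang, label = "SoL_aff"),
    S_prox = distance_to_affinity(geo, label = "S_prox"),
    L_adj = row_normalize(
      adjacency_from_distance(lang, intelligibility_years), label = "L_adj"),
    S_adj = row_normalize(adj, label = "S_adj")
  )
  structure(list(nodes = nodes, lang_dist = lang, geo_dist = geo,
                 border_adj = adj, weights = weights, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$nodes$ids), "countries;",
      "weights:", paste(names(x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Draw one outcome vector from the disturbances model
#'
#' The exact sampler: \eqn{\nu \sim N(0, \sigma^2 I)},
#' \eqn{y = \mu + (I - \sum_k \rho_k W_k)^{-1} \nu}. Errors when the
#' requested \eqn{\rho} leaves the stability domain.
#'
#' @param w_list List of [weight_matrix] objects.
#' @param rho Autocorrelation per matrix.
#' @param sigma2 Innovation variance.
#' @param intercept Mean level.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return Numeric outcome vector named by node id.
#' @export
sample_disturbance_outcome <- function(w_list, rho, sigma2 = 1,
                                       intercept = 0, seed = NULL) {
  if (!is.list(w_list)) w_list <- list(w_list)
  stopifnot(length(rho) == length(w_list))
  n <- nrow(w_list[[1]])
  A <- diag(n)
  for (k in seq_along(w_list)) A <- A - rho[k] * unclass(w_list[[k]])
  if (!in_stability_domain(A))
    stop("rho outside the stability domain (det(A) <= 0)")
  if (!is.null(seed)) set.seed(seed)
  nu <- stats::rnorm(n, sd = sqrt(sigma2))
  y <- intercept + solve(A, nu)
  stats::setNames(as.numeric(y), rownames(w_list[[1]]))
}

# round half away from zero (base round() goes half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Polity-like synthetic panel
#'
#' Bounded integer series on the -10..10 autocracy-democracy scale with
#' rare changes. The initial cross-section is network-correlated (a
#' disturbances-model draw scaled across the full range, so culturally
#' close countries start at similar scores, as real polity levels do); in
#' each subsequent bin a country changes with probability `change_prob`,
#' and the changing countries' increments are network-correlated too
#' (drawn from the disturbances model on `w_list` with the given `rho`),
#' rounded half away from zero and clipped to the scale. Because changes
#' are rare, the initial network signal persists through the panel. Set
#' `init = "uniform"` for an uncorrelated start.
#'
#' @param world A `synthetic_world` (or any list with `$weights`).
#' @param n_bins Number of biennial bins (>= 2).
#' @param change_prob Per-country-per-bin change probability.
#' @param w_list Weight matrices carrying the planted signal (default the
#'   world's socio-linguistic affinity).
#' @param rho,sigma2 Generating parameters of the increment process.
#' @param start_year,bin_width Bin labelling.
#' @param missing_prob Per-cell missingness probability.
#' @param init Initial cross-section: `"network"` (correlated draw) or
#'   `"uniform"` (independent random scores).
#' @param seed Random seed.
#' @return A [panel_outcome] of variable `polity_state`.
#' @export
make_polity_like_panel <- function(world, n_bins = 20, change_prob = 0.25,
                                   w_list = NULL, rho = 0.02, sigma2 = 9,
                                   start_year = 1898, bin_width = 2,
                                   missing_prob = 0,
                                   init = c("network", "uniform"), seed = 1) {
  if (n_bins < 2) stop("need at least 2 bins")
  init <- match.arg(init)
  if (is.null(w_list)) w_list <- list(world$weights$SoL_aff)
  if (!is.list(w_list)) w_list <- list(w_list)
  ids <- rownames(w_list[[1]])
  n <- length(ids)
  set.seed(seed)
  vals <- matrix(NA_real_, n, n_bins, dimnames = list(ids, NULL))
  if (init == "network") {
    base <- sample_disturbance_outcome(w_list, rho = rep(rho, length(w_list)),
                                       sigma2 = 1, intercept = 0)
    base <- base / stats::sd(base) * 5  # spread over the 21-point scale
    vals[, 1] <- pmin(pmax(round_half_away(base), -10), 10)
  } else {
    vals[, 1] <- sample(-10:10, n, replace = TRUE)
  }
  for (b in 2:n_bins) {
    incr <- sample_disturbance_outcome(w_list, rho = rep(rho, length(w_list)),
                                       sigma2 = sigma2, intercept = 0)
    changes <- stats::rbinom(n, 1, change_prob)
    step <- round_half_away(incr) * changes
    vals[, b] <- pmin(pmax(vals[, b - 1] + step, -10), 10)
  }
  if (missing_prob > 0) {
    drop <- matrix(stats::runif(n * n_bins) < missing_prob, n, n_bins)
    vals[drop] <- NA_real_
  }
  panel_outcome(vals, start_year + bin_width * (0:(n_bins - 1)),
                bin_width, "polity_state")
}

#' Panel of independent draws from the disturbances model
#'
#' Each bin's outcome vector is an independent draw from the network
#' disturbances model with the same generating parameters — the cleanest
#' panel for power and parameter-recovery checks, with no serial
#' dependence between bins.
#'
#' @param w_list Weight matrices carrying the signal.
#' @param rho,sigma2,intercept Generating parameters.
#' @param n_bins Number of bins.
#' @param start_year,bin_width Bin labelling.
#' @param variable Panel variable tag.
#' @param seed Random seed.
#' @return A [panel_outcome].
#' @export
make_disturbance_panel <- function(w_list, rho, sigma2 = 1, intercept = 0,
                                   n_bins = 20, start_year = 1898,
                                   bin_width = 2,
                                   variable = "polity_state", seed = 1) {
  if (!is.list(w_list)) w_list <- list(w_list)
  ids <- rownames(w_list[[1]])
  set.seed(seed)
  vals <- matrix(NA_real_, length(ids), n_bins, dimnames = list(ids, NULL))
  for (b in seq_len(n_bins))
    vals[, b] <- sample_disturbance_outcome(w_list, rho, sigma2, intercept)
  if (variable == "polity_state")
    vals <- pmin(pmax(vals, -10), 10)
  panel_outcome(vals, start_year + bin_width * (0:(n_bins - 1)),
                bin_width, variable)
}

#' Default-like synthetic event tables and panel
#'
#' Rare sovereign-default emulation: each (country, bin) experiences an
#' event with probability `event_rate` (Bernoulli, no serial dependence);
#' an event lands in a uniformly chosen year of the bin and is assigned to
#' the foreign or domestic creditor stream at random. The expected total
#' count is `n * n_bins * event_rate`.
#'
#' @param world A `synthetic_world`.
#' @param n_bins Number of bins.
#' @param event_rate Per-country-per-bin event probability in \eqn{[0,1]}.
#' @param start_year,bin_width Bin grid.
#' @param seed Random seed.
#' @return List with `foreign` and `domestic` [country_year_table]s and
#'   `panel`, the binned [panel_outcome] (variable `default_count`).
#' @export
make_default_like_panel <- function(world, n_bins = 22, event_rate = 0.08,
                                    start_year = 1899, bin_width = 5,
                                    seed = 1) {
  if (event_rate < 0 || event_rate > 1) stop("event_rate must be in [0, 1]")
  ids <- world$nodes$ids
  n <- length(ids)
  set.seed(seed)
  recs <- list()
  for (b in seq_len(n_bins)) {
    hit <- which(stats::runif(n) < event_rate)
    for (i in hit) {
      yr <- start_year + bin_width * (b - 1) + sample.int(bin_width, 1) - 1
      recs[[length(recs) + 1]] <- data.frame(
        country = ids[i], year = yr,
        stream = sample(c("foreign", "domestic"), 1))
    }
  }
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(country = character(0), year = integer(0), stream = character(0))
  mk <- function(s) {
    r <- recs[recs$stream == s, ]
    agg <- if (nrow(r)) stats::aggregate(list(value = rep(1, nrow(r))),
                                         r[c("country", "year")], sum)
           else data.frame(country = character(0), year = integer(0), value = numeric(0))
    country_year_table(agg$country, agg$year, agg$value)
  }
  foreign <- mk("foreign"); domestic <- mk("domestic")
  end <- start_year + bin_width * n_bins - 1
  panel <- bin_defaults(foreign, domestic, start = start_year,
                        width = bin_width, end = end, countries = ids)
  list(foreign = foreign, domestic = domestic, panel = panel)
}
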