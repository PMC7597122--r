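#' Sweep segment and rule counts over the asynchrony probability
#'
#' For each rule and each probability on the grid: draw one seeded random row
#' of `n_cells` cells (with a random boundary pair), apply one asynchronous
#' step of the rule, segment the transition against the rule, and record the
#' segment count `N1` and distinct-rule count `N2`, normalized as
#' `N1 / n_cells` and `N2 / 256`.  With `replicates > 1` the counts are
#' averaged over independently seeded realizations.
#'
#' @param rules Rules to sweep (default all 256).
#' @param p_grid Strictly increasing probabilities in `[0, 1]`.  The default
#'   stops at 0.95: at `p = 1` no cell updates, the transition is the
#'   identity and the segmentation degenerates to a single segment
#'   (`N1 = N2 = 1`) — a property of the endpoint, not of the sweep, and a
#'   discontinuous outlier for the polynomial fits.  Include 1 explicitly if
#'   the degenerate point is wanted.
#' @param n_cells Row length per realization (default 10^4).
#' @param seed Master seed; every (rule, p, replicate) gets a derived
#'   sub-seed, so single entries are reproducible in isolation.
#' @param replicates Realizations averaged per (rule, p).
#' @return An `eca_sweep` tibble: `rule`, `p`, `N1`, `N2`, `N1_norm`,
#'   `N2_norm`, `ratio` (= `N1 / N2`), `seed`.
#' @examples
#' sw <- sweep_segments(c(18, 90), p_grid = c(0, 0.5, 1), n_cells = 500, seed = 1)
#' @export
sweep_segments <- function(rules = 0:255, p_grid = seq(0, 0.95, by = 0.05),
                           n_cells = 10000, seed = 1L, replicates = 1) {
  rules <- vapply(rules, parse_rule, integer(1))
  if (length(rules) == 0) abort("`rules` must be non-empty.")
  if (length(p_grid) == 0 || any(p_grid < 0 | p_grid > 1) ||
      any(diff(p_grid) <= 0)) {
    abort("`p_grid` must be strictly increasing within [0, 1].")
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 10) abort("`n_cells` must be >= 10.")
  replicates <- as.integer(replicates)
  grid <- tidyr::expand_grid(rule = rules, p = p_grid)
  nseeds <- nrow(grid) * replicates
  subseeds <- matrix(derive_seeds(seed, nseeds), nrow = nrow(grid))
  counts <- purrr::map(seq_len(nrow(grid)), function(i) {
    per <- vapply(seq_len(replicates), function(j) {
      withr::with_seed(subseeds[i, j], {
        cfg <- random_configuration(n_cells)
        seg <- segment_transition(cfg, step_async(cfg, grid$rule[i],
                                                  grid$p[i])$cells,
                                  base = grid$rule[i])
        c(seg$N1, seg$N2)
      })
    }, numeric(2))
    rowMeans(matrix(per, nrow = 2))
  })
  out <- dplyr::mutate(grid,
    N1 = vapply(counts, `[`, numeric(1), 1),
    N2 = vapply(counts, `[`, numeric(1), 2),
    N1_norm = .data$N1 / n_cells,
    N2_norm = .data$N2 / 256,
    ratio = .data$N1 / .data$N2,
    seed = as.integer(seed)
  )
  attr(out, "n_cells") <- n_cells
  attr(out, "replicates") <- replicates
  class(out) <- c("eca_sweep", class(out))
  out
}

#' Per-probability averages of a sweep over rules
#'
#' Averages the normalized segment count, normalized rule count and the
#' `N1 / N2` ratio over rules, per probability.
#'
#' @param sweep An `eca_sweep` from [sweep_segments()].
#' @return A tibble: `p`, `N1_norm`, `N2_norm`, `ratio`, `n_rules`.
#' @export
sweep_summary <- function(sweep) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(sweep), .data$p),
                   N1_norm = mean(.data$N1_norm),
                   N2_norm = mean(.data$N2_norm),
                   ratio = mean(.data$ratio),
                   n_rules = dplyr::n(),
                   .groups = "drop")
}

#' Ordinary least-squares polynomial fit with R-squared
#'
#' Fits `y ~ x + x^2 + ... + x^degree` by OLS.  `r_squared` is
#' `1 - SS_res / SS_tot`; a constant target (`SS_tot = 0`) is reported as
#' `r_squared = 0`.
#'
#' @param x,y Numeric vectors (at least `degree + 2` points recommended;
#'   `degree + 1` required).
#' @param degree Polynomial degree (default 4).
#' @return An `eca_polyfit`: list with `degree`, `coefficients` (highest
#'   degree first, constant last), `r_squared` and the underlying `lm` fit.
#'   `tidy()` gives one row per term, `glance()` the degree and R-squared.
#' @examples
#' f <- fit_polynomial(0:10 / 10, (0:10 / 10)^2, degree = 2)
#' f$r_squared  # 1
#' @export
fit_polynomial <- function(x, y, degree = 4) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(unique(x)) < degree + 1) {
    abort(sprintf("Need at least %d distinct x values for degree %d.",
                  degree + 1, degree))
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- rev(unname(stats::coef(fit)))  # highest degree first
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(degree = as.integer(degree), coefficients = cf,
                 r_squared = r2, fit = fit),
            class = "eca_polyfit")
}

#' @export
print.eca_polyfit <- function(x, digits = 4, ...) {
  terms <- sprintf("%.*gx^%d", digits, x$coefficients[seq_len(x$degree)],
                   x$degree:1)
  cat(sprintf("<eca_polyfit> y = %s + %.*g,  R^2 = %.5f\n",
              paste(terms, collapse = " + "), digits,
              x$coefficients[x$degree + 1], x$r_squared))
  invisible(x)
}

#' @export
tidy.eca_polyfit <- function(x, ...) {
  tibble::tibble(term = paste0("x^", x$degree:0), estimate = x$coefficients)
}

#' @export
glance.eca_polyfit <- function(x, ...) {
  tibble::tibble(degree = x$degree, r.squared = x$r_squared)
}

#' Quartic fits of the averaged sweep curves
#'
#' Fits the rule-averaged normalized segment and rule counts against `p`
#' with [fit_polynomial()] (default degree 4).
#'
#' @inheritParams sweep_summary
#' @param degree Polynomial degree.
#' @return A list with elements `segments` and `rules`, each an
#'   `eca_polyfit`, plus the averaged `summary` tibble.
#' @export
fit_sweep <- function(sweep, degree = 4) {
  sm <- sweep_summary(sweep)
  list(segments = fit_polynomial(sm$p, sm$N1_norm, degree),
       rules = fit_polynomial(sm$p, sm$N2_norm, degree),
       summary = sm)
}

#' Regress the breaking degree on the segment/rule ratio
#'
#' Joins a sweep summary and a breaking-degree curve on their shared grid
#' probabilities within `p_range`, then linearly regresses `D_B(p)` on the
#' rule-averaged `#Segments/#Rules` ratio (raw counts `N1 / N2`), and also
#' on the reciprocal `#Rules/#Segments` ratio for comparison.
#'
#' The range over which the trade-off is broken is an analysis choice; the
#' default `[0.05, 0.55]` is used with a warning so the caller states it
#' deliberately.
#'
#' @inheritParams sweep_summary
#' @param breaking A tibble with columns `p` and `D_B` (e.g. from
#'   [run_tradeoff_study()] or rows of `glance()`ed [breaking_degree()]
#'   results).
#' @param p_range Inclusive probability range used for the regression.
#' @return A list: `ratio` and `reciprocal` (`eca_polyfit` of degree 1, with
#'   slope and intercept in `coefficients`), and `data` (the joined tibble).
#' @export
ratio_vs_breaking <- function(sweep, breaking, p_range = NULL) {
  if (is.null(p_range)) {
    p_range <- c(0.05, 0.55)
    warn("`p_range` not given; defaulting to [0.05, 0.55].")
  }
  sm <- if (inherits(sweep, "eca_sweep")) sweep_summary(sweep) else sweep
  if (!all(c("p", "ratio") %in% names(sm))) {
    abort("`sweep` must be an `eca_sweep` or a tibble with `p` and `ratio`.")
  }
  if (!all(c("p", "D_B") %in% names(breaking))) {
    abort("`breaking` must have columns `p` and `D_B`.")
  }
  df <- dplyr::inner_join(dplyr::select(sm, "p", "ratio"),
                          dplyr::select(breaking, "p", "D_B"), by = "p")
  df <- dplyr::filter(df, .data$p >= p_range[1], .data$p <= p_range[2])
  if (nrow(df) < 3) abort("Fewer than 3 shared grid points in `p_range`.")
  list(ratio = fit_polynomial(df$ratio, df$D_B, degree = 1),
       reciprocal = fit_polynomial(1 / df$ratio, df$D_B, degree = 1),
       data = df)
}

#' Plot sweep curves against the probability
#'
#' @param object An `eca_sweep`.
#' @param value Which normalized count to plot.
#' @param ... Unused.
#' @return A ggplot with one line per rule plus the rule-averaged curve.
#' @export
autoplot.eca_sweep <- function(object, value = c("N1_norm", "N2_norm"), ...) {
  value <- match.arg(value)
  sm <- sweep_summary(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p, y = .data[[value]],
                               group = .data$rule)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = sm, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "p", y = if (value == "N1_norm")
      expression(N[1] / n[cells]) else expression(N[2] / 256))
}
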