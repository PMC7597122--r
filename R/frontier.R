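# Bin index of a universality value in 1..m: half-open bins
# [(k-1)/m, k/m), with the last bin closed at 1.0 so every U_N in (0, 1]
# lands in exactly one bin.
frontier_bin <- function(u, m) {
  pmin(as.integer(floor(u * m)) + 1L, as.integer(m))
}

#' Lower-margin step frontier of the universality-efficiency cloud
#'
#' Divides the universality axis `[0, 1]` into `m` subintervals and takes,
#' per bin, the minimum efficiency `E` among rules whose `U_N` falls in the
#' bin (`sub_min`); empty bins are filled with the maximum `E` over all
#' rules.  The frontier `e_min` is the suffix minimum
#' `e_min(k) = min(sub_min(k..m))`, a monotone non-decreasing step function
#' of `k` that traces the lower margin of the `(U_N, E)` cloud — the best
#' efficiency attainable at or above each level of universality, i.e. the
#' trade-off between the two.
#'
#' @param points A tibble with columns `U_N` and `E`, one row per rule —
#'   typically the output of [rule_metrics()] for all 256 rules.
#' @param m Number of subintervals (default 52).
#' @return An `eca_frontier`: a tibble with columns `k`, `bin_low`,
#'   `bin_high`, `sub_min`, `e_min`, carrying the synchronous points and
#'   parameters as attributes.
#' @examples
#' pts <- rule_metrics(0:255, n = 4, horizon = 3, cap = 16, t_theta = 70)
#' fr <- build_frontier(pts, m = 10)
#' all(diff(fr$e_min) >= 0)
#' @export
build_frontier <- function(points, m = 52) {
  if (!all(c("U_N", "E") %in% names(points))) {
    abort("`points` must have columns `U_N` and `E`.")
  }
  if (nrow(points) == 0) abort("`points` is empty.")
  if (m < 1) abort("`m` must be >= 1.")
  m <- as.integer(m)
  fill <- max(points$E)
  bin <- frontier_bin(points$U_N, m)
  sub_min <- rep(fill, m)
  mins <- tapply(points$E, bin, min)
  sub_min[as.integer(names(mins))] <- mins
  e_min <- rev(cummin(rev(sub_min)))
  out <- tibble::tibble(
    k = seq_len(m),
    bin_low = (seq_len(m) - 1) / m,
    bin_high = seq_len(m) / m,
    sub_min = sub_min,
    e_min = e_min
  )
  structure(out,
            m = m, fill_value = fill, points = points,
            params = attr(points, "params"),
            class = c("eca_frontier", class(out)))
}

#' @export
tidy.eca_frontier <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.eca_frontier <- function(x, ...) {
  tibble::tibble(m = attr(x, "m"), fill_value = attr(x, "fill_value"),
                 n_points = nrow(attr(x, "points")))
}

#' Degree of trade-off breaking
#'
#' Counts the rules whose asynchronous `(U_N, E)` point lies strictly below
#' the synchronous frontier at the bin containing the rule's own asynchronous
#' universality, and divides by 256 (the number of ECA rules).  A rule
#' strictly below the frontier reaches the same level of universality faster
#' than any synchronous rule — it breaks the synchronous trade-off.
#'
#' @param frontier An `eca_frontier` built from synchronous points with the
#'   same `n`, `horizon`, `cap` and `t_theta` as `async_points`.
#' @param async_points A tibble with columns `rule`, `U_N`, `E` (typically
#'   [rule_metrics()] with `p > 0`).
#' @return An `eca_breaking` object; `tidy()` gives the per-rule table
#'   (`rule`, `U_N`, `E`, `bin`, `e_min`, `below`), `glance()` the summary
#'   (`p`, `D_B`, `n_below`).
#' @examples
#' pts <- rule_metrics(0:255, n = 4, horizon = 3, cap = 16)
#' fr <- build_frontier(pts, m = 10)
#' glance(breaking_degree(fr, pts))$D_B  # 0: sync points never break
#' @export
breaking_degree <- function(frontier, async_points) {
  if (!inherits(frontier, "eca_frontier")) {
    abort("`frontier` must be built by `build_frontier()`.")
  }
  if (!all(c("U_N", "E") %in% names(async_points))) {
    abort("`async_points` must have columns `U_N` and `E`.")
  }
  fp <- attr(frontier, "params")
  ap <- attr(async_points, "params")
  if (!is.null(fp) && !is.null(ap)) {
    for (f in c("n", "horizon", "cap", "t_theta", "boundary_seed")) {
      if (!identical(fp[[f]], ap[[f]])) {
        abort(sprintf(
          "`frontier` and `async_points` disagree on `%s` (%s vs %s); refusing to compare.",
          f, format(fp[[f]]), format(ap[[f]])))
      }
    }
  }
  m <- attr(frontier, "m")
  bin <- frontier_bin(async_points$U_N, m)
  e_min <- frontier$e_min[bin]
  below <- async_points$E < e_min
  tab <- tibble::tibble(
    rule = if ("rule" %in% names(async_points)) async_points$rule
           else seq_len(nrow(async_points)) - 1L,
    U_N = async_points$U_N, E = async_points$E,
    bin = bin, e_min = e_min, below = below
  )
  p <- if ("p" %in% names(async_points)) unique(async_points$p)[1] else NA_real_
  structure(list(p = p, table = tab, n_below = sum(below),
                 D_B = sum(below) / 256),
            class = "eca_breaking")
}

#' @export
print.eca_breaking <- function(x, ...) {
  cat(sprintf("<eca_breaking> p = %g: %d of 256 rules below the frontier (D_B = %.4f)\n",
              x$p, x$n_below, x$D_B))
  invisible(x)
}

#' @export
tidy.eca_breaking <- function(x, ...) x$table

#' @export
glance.eca_breaking <- function(x, ...) {
  tibble::tibble(p = x$p, D_B = x$D_B, n_below = x$n_below)
}

#' Plot the trade-off frontier and point cloud
#'
#' @param object An `eca_frontier`.
#' @param async_points Optional asynchronous `(U_N, E)` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eca_frontier <- function(object, async_points = NULL, ...) {
  pts <- attr(object, "points")
  steps <- tibble::tibble(
    x = c(object$bin_low, 1),
    y = c(object$e_min, object$e_min[nrow(object)])
  )
  gg <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$U_N, y = .data$E),
                        shape = 1, colour = "grey40") +
    ggplot2::geom_step(data = steps, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.7) +
    ggplot2::labs(x = expression(U[N]), y = "E")
  if (!is.null(async_points)) {
    gg <- gg + ggplot2::geom_point(
      data = async_points, ggplot2::aes(x = .data$U_N, y = .data$E),
      colour = "red", shape = 16, size = 1.5)
  }
  gg
}
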