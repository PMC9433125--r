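# Nonparametric comparison of band power / PLV across brain states.

#' Kruskal--Wallis rank test
#'
#' Omnibus rank test for a location difference among k groups:
#' `H = 12 / (n (n + 1)) * sum(R_i^2 / n_i) - 3 (n + 1)`, divided by the
#' tie-correction factor `1 - sum(t^3 - t) / (n^3 - n)`, with the p-value
#' from the upper chi-square tail on `k - 1` degrees of freedom. Computed
#' via [stats::kruskal.test()], which implements exactly this statistic.
#' H is invariant under any strictly increasing transform of the pooled
#' data (it depends on ranks only).
#'
#' @param groups List of >= 2 non-empty numeric vectors (total n >= 3).
#' @return A `kruskal_wallis` object: list with `H`, `df`, `p.value`,
#'   `n` (total), and `group_sizes`.
#' @examples
#' kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' kw$H  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("design error: need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("design error: empty group", call. = FALSE)
  if (sum(sizes) < 3) stop("design error: total n must be >= 3",
                           call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    stop("degenerate ties: all observations identical", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(pooled, g)
  structure(
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, n = length(pooled),
         group_sizes = as.integer(sizes)),
    class = "kruskal_wallis"
  )
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d: %s)\n",
              x$H, x$df, x$p.value, x$n,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname kruskal_wallis
#' @param x A `kruskal_wallis` object.
#' @param ... Unused.
#' @export
tidy.kruskal_wallis <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p.value = x$p.value,
                 method = "Kruskal-Wallis rank sum test")
}

#' @rdname kruskal_wallis
#' @export
glance.kruskal_wallis <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p.value = x$p.value,
                 n = x$n, k = length(x$group_sizes))
}

#' Compare inter-ictal, pre-ictal and ictal states per rhythm
#'
#' For each band, runs the omnibus Kruskal--Wallis test across the three
#' states on a feature (log band power or PLV), followed by the three
#' pairwise two-group contrasts. Per-epoch observations are pooled within
#' each state (per-channel values for band power, per-pair values for
#' PLV). No multiple-testing correction is applied by default, matching
#' per-band reporting conventions; Bonferroni over bands is available.
#'
#' @param features Tidy table with columns `state`, `band`, and the value
#'   column named by `value_col` ([band_power_table()] or [plv_table()]
#'   output).
#' @param feature_kind Label stored in the result, e.g. `"band_power"` or
#'   `"plv"`; defaults from `value_col`.
#' @param value_col Name of the value column: `"power"` or `"plv"`
#'   (auto-detected).
#' @param states States to compare, default the three-state design.
#' @param alpha Significance level for the flag, default 0.05.
#' @param bonferroni If `TRUE`, multiply p-values by the number of bands
#'   (capped at 1) before flagging. Default `FALSE`.
#' @return Tibble with one row per band per contrast (`"omnibus"` plus
#'   each state pair): `feature`, `band`, `contrast`, `H`, `df`, `p`,
#'   group sizes, and `significant`.
#' @export
compare_states <- function(features, feature_kind = NULL, value_col = NULL,
                           states = c("inter_ictal", "pre_ictal", "ictal"),
                           alpha = 0.05, bonferroni = FALSE) {
  value_col <- value_col %||%
    intersect(c("power", "plv"), names(features))[1]
  if (is.na(value_col) || is.null(value_col)) {
    stop("no power or plv column found", call. = FALSE)
  }
  feature_kind <- feature_kind %||%
    c(power = "band_power", plv = "plv")[[value_col]]
  features <- features[features$state %in% states, , drop = FALSE]
  bands <- unique(as.character(features$band))
  n_tests <- length(bands)

  one <- function(d, contrast, who) {
    gs <- lapply(who, function(s) d[[value_col]][d$state == s])
    empty <- who[lengths(gs) == 0]
    if (length(empty) > 0) {
      stop("design error: no observations in state ", empty[1],
           call. = FALSE)
    }
    kw <- kruskal_wallis(gs)
    tibble::tibble(
      contrast = contrast, H = kw$H, df = kw$df, p = kw$p.value,
      n_groups = list(stats::setNames(kw$group_sizes, who))
    )
  }
  res <- purrr::map(bands, function(b) {
    d <- features[as.character(features$band) == b, , drop = FALSE]
    pairs <- utils::combn(states, 2, simplify = FALSE)
    dplyr::bind_rows(
      one(d, "omnibus", states),
      purrr::map(pairs, function(pr)
        one(d, paste(pr, collapse = " vs "), pr)) |> dplyr::bind_rows()
    ) |>
      dplyr::mutate(band = b, .before = 1)
  }) |> dplyr::bind_rows()

  res$p_adj <- if (bonferroni) pmin(1, res$p * n_tests) else res$p
  res$significant <- res$p_adj < alpha
  dplyr::mutate(res, feature = feature_kind, alpha = alpha, .before = 1)
}
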