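# Statistical evaluation: rank-based group screening, validation
# correlations and tail-based outlier removal by linear quantile
# regression.

#' Kruskal-Wallis rank test
#'
#' H is computed on mid-ranks, `H = 12/(N(N+1)) * sum(R_i^2 / n_i) - 3(N+1)`,
#' divided by the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`;
#' the p-value comes from the chi-square upper tail on k - 1 degrees of
#' freedom. When every value across all groups is identical the test
#' carries no information and returns `H = 0, p = 1` by convention.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return List with `statistic` (H), `df`, `p.value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) == 0L)) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values are not allowed; filter them first")
  k <- length(groups)
  n_i <- vapply(groups, length, 0L)
  N <- sum(n_i)
  if (N < 3L) stop("need a total of at least 3 observations")
  df <- k - 1L
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, df = df, p.value = 1, n = N))
  }
  r <- rank(x)  # mid-ranks for ties
  g <- rep(seq_len(k), n_i)
  R <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n_i) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(statistic = H, df = df,
       p.value = stats::pchisq(H, df, lower.tail = FALSE), n = N)
}

#' Pearson validation correlation
#'
#' Standard product-moment correlation with pairwise deletion of missing
#' pairs; degenerate inputs (fewer than 3 complete pairs, zero variance)
#' yield a missing value rather than an error.
#'
#' @param x,y paired numeric vectors.
#' @return r in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Linear quantile regression by pinball-loss minimization
#'
#' Fits `value ~ covariate` at quantile `tau` exactly: some optimal line
#' of the pinball-loss linear program interpolates two data points, so
#' the minimizer is found by enumerating candidate lines through all
#' point pairs with distinct covariate values (vectorized loss over the
#' candidate set). With a constant covariate the fit degenerates to the
#' empirical `tau` quantile as a flat line.
#'
#' @param x covariate; @param y response; @param tau quantile in (0, 1).
#' @return List with `intercept`, `slope`, `loss`.
#' @export
quantile_regression_fit <- function(x, y, tau) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1)
  n <- length(x)
  if (length(unique(x)) == 1L) {
    a <- as.numeric(stats::quantile(y, tau, type = 1))
    r <- y - a
    return(list(intercept = a, slope = 0, loss = sum(r * (tau - (r < 0)))))
  }
  pr <- utils::combn(n, 2)
  dx <- x[pr[2, ]] - x[pr[1, ]]
  keep <- abs(dx) > 1e-12
  b <- (y[pr[2, keep]] - y[pr[1, keep]]) / dx[keep]
  a <- y[pr[1, keep]] - b * x[pr[1, keep]]
  cand <- unique(cbind(a, b))
  # residual matrix: n rows x candidates
  R <- matrix(y, n, nrow(cand)) -
    matrix(cand[, 1], n, nrow(cand), byrow = TRUE) -
    outer(x, cand[, 2])
  loss <- colSums(R * (tau - (R < 0)))
  i <- which.min(loss)
  list(intercept = cand[i, 1], slope = cand[i, 2], loss = loss[i])
}

#' Quantile-regression outlier filter
#'
#' Within each (trait, view, stage, treatment) cell, fits linear quantile
#' regressions of value on day at `taus[1]` and `taus[2]` and removes
#' rows lying strictly below the lower line or strictly above the upper
#' line. Cells with fewer than `min_cell` observations are passed through
#' unfiltered with a warning.
#'
#' @param table long trait table (columns trait_name, view, stage,
#'   treatment, day, value; see [traits_to_long()]).
#' @param taus lower/upper quantiles, `0 < taus[1] < taus[2] < 1`.
#' @param min_cell smallest cell that is filtered.
#' @return List with `table` (filtered rows), `report` (per-row flag data
#'   frame plus the fitted `lines` per cell and `taus`).
#' @export
quantile_outlier_filter <- function(table, taus = c(0.05, 0.95), min_cell = 10L) {
  stopifnot(taus[1] > 0, taus[1] < taus[2], taus[2] < 1)
  table$.row <- seq_len(nrow(table))
  key <- interaction(table$trait_name, table$view, table$stage,
                     table$treatment, drop = TRUE)
  removed <- logical(nrow(table))
  lines <- list()
  for (cell in levels(key)) {
    idx <- which(key == cell)
    sub <- table[idx, ]
    ok <- is.finite(sub$value)
    if (sum(ok) < min_cell) {
      warning(sprintf("cell '%s' has %d observations (< %d): passed through unfiltered",
                      cell, sum(ok), min_cell))
      next
    }
    x <- sub$day[ok]; y <- sub$value[ok]
    lo <- quantile_regression_fit(x, y, taus[1])
    hi <- quantile_regression_fit(x, y, taus[2])
    ylo <- lo$intercept + lo$slope * sub$day
    yhi <- hi$intercept + hi$slope * sub$day
    out <- ok & (sub$value < ylo - 1e-9 | sub$value > yhi + 1e-9)
    removed[idx[out]] <- TRUE
    lines[[cell]] <- data.frame(cell = cell, tau = taus,
                                intercept = c(lo$intercept, hi$intercept),
                                slope = c(lo$slope, hi$slope))
  }
  report <- data.frame(row = table$.row, trait_name = table$trait_name,
                       view = table$view, stage = table$stage, day = table$day,
                       removed = removed, stringsAsFactors = FALSE)
  out_table <- table[!removed, setdiff(names(table), ".row")]
  rownames(out_table) <- NULL
  list(table = out_table,
       report = list(flags = report,
                     lines = if (length(lines)) do.call(rbind, lines) else NULL,
                     taus = taus))
}

#' Kruskal-Wallis screening tables
#'
#' One Kruskal-Wallis row per (trait, view, stage, day, grouping
#' variable), flagged at the supplied alpha. No multiple-testing
#' adjustment is applied (raw per-test thresholds); an optional
#' Benjamini-Hochberg column can be added for inspection but never
#' drives the flag.
#'
#' @param table long trait table ([traits_to_long()]), outlier-filtered.
#' @param grouping grouping variables, subset of
#'   `c("treatment", "variety")`.
#' @param alpha significance threshold for the flag.
#' @param by_day if `TRUE` (default) one row per day; otherwise days are
#'   pooled within a cell.
#' @param bh_column add a BH-adjusted p column (diagnostic only).
#' @return `screening_table` data frame with columns trait_name, view,
#'   stage, day, grouping, n_groups, statistic, df, p_value, significant.
#' @export
build_screening_tables <- function(table, grouping = c("treatment", "variety"),
                                   alpha = 0.005, by_day = TRUE,
                                   bh_column = FALSE) {
  grouping <- match.arg(grouping, several.ok = TRUE)
  days <- if (by_day) sort(unique(table$day)) else NA
  rows <- list()
  for (g in grouping) {
    for (tn in unique(table$trait_name)) {
      for (v in unique(table$view)) {
        for (s in unique(table$stage)) {
          for (d in days) {
            sub <- table[table$trait_name == tn & table$view == v &
                           table$stage == s, ]
            if (by_day) sub <- sub[sub$day == d, ]
            sub <- sub[is.finite(sub$value), ]
            gl <- split(sub$value, sub[[g]], drop = TRUE)
            row <- data.frame(trait_name = tn, view = v, stage = s,
                              day = if (by_day) d else NA,
                              grouping = g, n_groups = length(gl),
                              statistic = NA_real_, df = NA_integer_,
                              p_value = NA_real_, significant = NA,
                              stringsAsFactors = FALSE)
            if (length(gl) >= 2L && all(lengths(gl) > 0L) && nrow(sub) >= 3L) {
              kw <- kruskal_wallis(gl)
              row$statistic <- kw$statistic; row$df <- kw$df
              row$p_value <- kw$p.value
              row$significant <- kw$p.value < alpha
            }
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (bh_column) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_table", class(out))
  out
}
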