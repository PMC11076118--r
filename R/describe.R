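#' Descriptive statistics by group
#'
#' Arithmetic mean and standard error of one or more measurement columns
#' within every combination of grouping columns. Groups of size one get a
#' standard error of 0 and are flagged.
#'
#' @param records data frame.
#' @param measure character vector of numeric column names.
#' @param grouping character vector of grouping column names.
#' @return data frame with one row per group x measure: grouping columns,
#'   `variable`, `n`, `mean`, `se`, `single_obs`.
#' @export
describe_by <- function(records, measure, grouping) {
  stopifnot(all(measure %in% names(records)),
            all(grouping %in% names(records)))
  key <- interaction(records[grouping], drop = TRUE, lex.order = TRUE)
  if (any(table(key) < 1)) stop("empty group")
  out <- do.call(rbind, lapply(measure, function(v) {
    do.call(rbind, lapply(levels(key), function(k) {
      x <- records[[v]][key == k]
      n <- length(x)
      if (n == 0L) stop("empty group: ", k)
      g <- records[key == k, grouping, drop = FALSE][1, , drop = FALSE]
      cbind(g, data.frame(variable = v, n = n, mean = mean(x),
                          se = if (n > 1) sd(x) / sqrt(n) else 0,
                          single_obs = n == 1L,
                          stringsAsFactors = FALSE))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with tie handling
#'
#' Computes the Spearman coefficient from average ranks (ties receive the
#' mean of the ranks they span) together with the rank-difference sum
#' `S = sum((rank(x) - rank(y))^2)` and a large-sample p-value from the
#' t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `S`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(rho = rho, S = sum((rx - ry)^2), p_value = p, n = n)
}
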