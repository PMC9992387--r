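# Net-primary-productivity statistics: per-unit summaries, rank-based
# two-sample comparison and productivity-diversity correlation. NPP
# series are consumed as externally produced data (kg/m^2/year against
# years BP); no ecosystem simulation happens here.

#' Build / read an NPP series
#'
#' @param year_bp Time stamps in calendar years BP.
#' @param npp NPP values (kg/m^2/year, >= 0).
#' @return A tibble sorted from oldest to youngest.
#' @export
npp_series <- function(year_bp, npp) {
  if (length(year_bp) != length(npp)) stop("lengths differ", call. = FALSE)
  if (any(npp < 0, na.rm = TRUE)) stop("NPP must be >= 0", call. = FALSE)
  dplyr::arrange(tibble::tibble(year_bp = year_bp, npp = npp),
                 dplyr::desc(.data$year_bp))
}

#' @rdname npp_series
#' @param path CSV with columns `year_bp`, `npp_kg_m2_yr`.
#' @export
read_npp_series <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    year_bp = readr::col_double(), npp_kg_m2_yr = readr::col_double()
  ), progress = FALSE)
  npp_series(x$year_bp, x$npp_kg_m2_yr)
}

#' Per-unit NPP statistics
#'
#' Mean and sample standard deviation of the NPP values dated inside a
#' unit's occupation interval (`start_bp` older than `end_bp`).
#'
#' @param series An [npp_series()] tibble.
#' @param start_bp,end_bp Interval bounds in years BP, `start_bp >=
#'   end_bp`.
#' @return A list with `mean`, `sd` and `n`.
#' @export
unit_npp_stats <- function(series, start_bp, end_bp) {
  if (start_bp < end_bp) stop("start_bp must be older (larger) than end_bp",
                              call. = FALSE)
  v <- series$npp[series$year_bp <= start_bp & series$year_bp >= end_bp]
  if (length(v) == 0) {
    stop("occupation interval does not overlap the series", call. = FALSE)
  }
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

# All C(n, n_a) group assignments of the pooled sample; exact null
# distribution of the Mann-Whitney U statistic (midrank ties).
mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' U statistic with a two-sided p-value: exact by enumeration of all
#' group assignments when the pooled size is at most 12 (ties handled
#' by midranks), otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_limit Pooled-size limit for exact enumeration.
#' @return A list with `statistic` (U of sample `a`), `p.value`, and
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty",
                                             call. = FALSE)
  u <- mw_u(a, b)
  n <- length(a) + length(b)
  if (n <= exact_limit) {
    pool <- c(a, b)
    combs <- utils::combn(n, length(a))
    us <- apply(combs, 2, function(ix) mw_u(pool[ix], pool[-ix]))
    mu <- length(a) * length(b) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    p <- wt$p.value
    method <- "normal approximation, tie corrected"
  }
  list(statistic = u, p.value = p, method = method)
}

#' Spearman rank correlation test
#'
#' Tie-corrected rho (Pearson correlation of midranks) with a two-sided
#' p-value: exact by enumeration of all permutations for n at most 7,
#' otherwise the t approximation.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @param exact_limit Sample-size limit for exact permutation.
#' @return A list with `rho`, `p.value` and `method`.
#' @export
spearman_test <- function(x, y, exact_limit = 7) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector; rho undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p.value = p, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

#' Productivity-diversity correlation
#'
#' Spearman correlation between per-unit NPP means and per-unit
#' diversity (inverse Simpson), computed separately for each consumer
#' group present.
#'
#' @param units A tibble with columns `unit`, `npp`, `diversity` and
#'   optionally `group` (e.g. primary / secondary / all consumers).
#' @return A tibble with one row per group: `group`, `n`, `rho`,
#'   `p.value`.
#' @export
npp_diversity_correlation <- function(units) {
  if (!("group" %in% names(units))) units$group <- "all"
  rows <- lapply(split(units, units$group), function(d) {
    if (nrow(d) < 3) {
      stop(sprintf("group '%s' has fewer than 3 units", d$group[1]), call. = FALSE)
    }
    st <- spearman_test(d$npp, d$diversity)
    tibble::tibble(group = d$group[1], n = nrow(d),
                   rho = st$rho, p.value = st$p.value)
  })
  dplyr::bind_rows(rows)
}
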