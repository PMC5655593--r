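#' Spearman rank correlation with a two-sided P value
#'
#' Midranks are assigned to ties and the coefficient is the Pearson
#' correlation of the rank vectors. The two-sided P value is exact — full
#' enumeration of all n! rank permutations — for n of at most
#' `exact_max_n` (default 9), and otherwise uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on n - 2 degrees of freedom; when
#' |rs| = 1 the t statistic degenerates and the exact-enumeration value
#' `2 / n!` is reported instead.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, no missing values
#'   (drop incomplete pairs before calling).
#' @param exact_max_n Largest n for which the exact permutation P value is
#'   computed.
#' @return A `correlation_result`: list with `rs`, `p_two_sided`, `n` and
#'   `method` (`"exact-permutation"` or `"t-approximation"`).
#' @examples
#' spearman(c(1, 2, 3, 4), c(1, 4, 9, 16)) # rs = 1
#' @export
spearman <- function(x, y, exact_max_n = 9L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not accepted; drop incomplete pairs first")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in a rank vector; correlation undefined")
  }
  rs <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- .permutations(n)
    num <- as.numeric(perms_apply(perms, ry) %*% rx) - n * mean(rx) * mean(ry)
    rs_all <- num / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rs_all) >= abs(rs) - 1e-12)
    method <- "exact-permutation"
  } else if (abs(rs) >= 1 - 1e-12) {
    p <- 2 / factorial(n)
    method <- "exact-permutation"
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rs = rs, p_two_sided = p, n = n, method = method),
            class = "correlation_result")
}

## all permutations of 1..n as an n! x n integer matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

## apply a permutation matrix to a value vector
perms_apply <- function(perms, values) {
  matrix(values[perms], nrow(perms))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs = %.4f, two-sided P = %.4g (n = %d, %s)\n",
              x$rs, x$p_two_sided, x$n, x$method))
  invisible(x)
}

#' @export
as.data.frame.correlation_result <- function(x, ...) {
  data.frame(rs = x$rs, p_two_sided = x$p_two_sided, n = x$n,
             method = x$method, stringsAsFactors = FALSE)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#'
#' @param values Numeric vector with at least two values.
#' @return The standard error of the mean.
#' @export
sem <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  stats::sd(values) / sqrt(length(values))
}
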