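#' Spearman rank correlation with a two-sided p-value
#'
#' rho is the Pearson correlation of average ranks (the standard tie
#' treatment). The two-sided p-value is exact by full permutation
#' enumeration for n <= 8 and uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom above
#' that.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.na(rho)) {
    # constant ranks on one side: no monotone association is estimable
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant input)"))
  }
  if (n <= 8L) {
    perms <- all_permutations(n)
    # rho is a monotone function of sum(rx * ry[perm]) for fixed margins
    obs <- sum(rx * ry)
    cross <- apply(perms, 1L, function(p) sum(rx * ry[p]))
    mu <- mean(cross)
    p <- mean(abs(cross - mu) >= abs(obs - mu) - 1e-12)
    list(rho = rho, p_value = p, n = n, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    list(rho = rho, p_value = p, n = n, method = "t approximation")
  }
}

# All permutations of 1..n as an (n!, n) integer matrix (n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
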