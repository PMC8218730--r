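#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent groups. The U
#' statistic is computed from midranks (ties share their average rank). The
#' p-value is two-sided and comes from one of two null models:
#'
#' * `exact`: full enumeration of the permutation null of U (no ties
#'   allowed). The distribution is obtained by the standard counting
#'   recurrence over rank arrangements, and the two-sided p is twice the
#'   smaller tail probability of values at least as extreme as observed,
#'   capped at 1.
#' * `normal`: tie-corrected normal approximation with continuity
#'   correction.
#' * `auto` (default): exact when there are no ties and
#'   `min(n1, n2) <= exact_max`, otherwise normal.
#'
#' @param a,b Numeric vectors, the two groups (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max Largest `min(n1, n2)` for which `auto` picks the exact
#'   test (default 8).
#' @return List with `U` (statistic for group `a`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p  # exact two-sided p = 1/3
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal"), exact_max = 8L) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty",
                                               call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto") {
    mode <- if (!ties && min(n1, n2) <= exact_max) "exact" else "normal"
  }
  if (mode == "exact") {
    if (ties) stop("exact mode requires data without ties; use mode = \"normal\"",
                   call. = FALSE)
    freq <- mwu_null_counts(n1, n2)
    total <- sum(freq)
    u_obs <- as.integer(round(U))
    p_le <- sum(freq[seq_len(u_obs + 1L)]) / total
    p_ge <- sum(freq[(u_obs + 1L):length(freq)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact"))
  }
  # tie-corrected normal approximation, continuity-corrected
  n <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  mu <- n1 * n2 / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

# Null distribution of U for group sizes (n1, n2): number of rank
# arrangements with each U in 0..n1*n2. Recurrence on the largest element:
# N(i, j, u) = N(i-1, j, u-j) + N(i, j-1, u).
mwu_null_counts <- function(n1, n2) {
  len <- n1 * n2 + 1L
  # A[[i+1]] holds N(i, j, .) for the current j; start at j = 0
  A <- lapply(0:n1, function(i) c(1, rep(0, len - 1L)))
  for (j in seq_len(n2)) {
    B <- vector("list", n1 + 1L)
    B[[1L]] <- A[[1L]]  # N(0, j, .) = point mass at 0
    for (i in seq_len(n1)) {
      shifted <- c(rep(0, j), B[[i]][seq_len(len - j)])
      B[[i + 1L]] <- shifted + A[[i + 1L]]
    }
    A <- B
  }
  A[[n1 + 1L]]
}
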