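#' Contingency table of two labelings
#'
#' Cross-tabulates reference labels against predicted labels. Basis for
#' [nmi()] and [ari()].
#'
#' @param truth,pred Equal-length label vectors (any atomic type).
#' @return Integer matrix of counts, rows = truth classes, columns =
#'   predicted classes.
#' @export
contingency_table <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("label vectors differ in length: ", length(truth), " vs ",
         length(pred))
  }
  if (length(truth) == 0L) stop("empty label vectors")
  unclass(as.matrix(table(truth, pred)))
}

#' Normalized mutual information of two labelings
#'
#' `NMI = 2 I(T, P) / (H(T) + H(P))` with natural-log entropies computed
#' from the contingency table; the value is invariant to the logarithm
#' base. Equals 1 for identical partitions and 0 for statistically
#' independent ones. When both partitions are the same single class the
#' degenerate 0/0 is resolved to 1.
#'
#' @param truth,pred Equal-length label vectors.
#' @return Value in `[0, 1]`.
#' @examples
#' nmi(c("a", "a", "b", "b"), c(1, 1, 2, 2))   # 1
#' nmi(c("a", "a", "b", "b"), c(1, 2, 1, 2))   # 0
#' @export
nmi <- function(truth, pred) {
  tab <- contingency_table(truth, pred)
  n <- sum(tab)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  h_t <- -sum(p_i[p_i > 0] * log(p_i[p_i > 0]))
  h_p <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (h_t + h_p == 0) {
    # both single-class: identical partitions by construction
    return(1)
  }
  pos <- p_ij > 0
  mi <- sum(p_ij[pos] * log(p_ij[pos] / outer(p_i, p_j)[pos]))
  val <- 2 * mi / (h_t + h_p)
  min(max(val, 0), 1)   # clamp roundoff
}

#' Adjusted Rand index of two labelings
#'
#' Hubert–Arabie chance-corrected pair-counting agreement:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
#'   {\tfrac12\left[\sum_i\binom{n_{i\cdot}}{2} +
#'    \sum_j\binom{n_{\cdot j}}{2}\right] - E}, \quad
#'   E = \frac{\sum_i\binom{n_{i\cdot}}{2}\sum_j\binom{n_{\cdot j}}{2}}
#'   {\binom{n}{2}}.}
#' Equals 1 for identical partitions, is 0 in expectation under random
#' labelings, and can be negative. When the denominator degenerates (both
#' partitions all singletons, or both one single cluster) the convention is
#' 1 for identical partitions and 0 otherwise.
#'
#' @param truth,pred Equal-length label vectors (n >= 2).
#' @return Value `<= 1`.
#' @examples
#' ari(c("a", "a", "b", "b"), c(2, 2, 1, 1))   # 1
#' @export
ari <- function(truth, pred) {
  tab <- contingency_table(truth, pred)
  n <- sum(tab)
  if (n < 2) stop("ARI needs at least 2 observations")
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) {
    return(if (sum_ij == sum_i && sum_i == sum_j) 1 else 0)
  }
  (sum_ij - expected) / denom
}
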