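#' One-sided hypergeometric upper-tail probability
#'
#' The shared statistical kernel of both enrichment axes: the probability of
#' observing at least `observed` successes when `draws` items are taken
#' without replacement from a population of size `population` containing
#' `successes` distinguished items,
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n, K)}
#'   \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.}
#' This inclusive upper tail is the one-sided Fisher exact p-value of the
#' corresponding 2x2 table. Terms are accumulated in log space
#' (log-binomials via `lchoose`) so that counts in the hundreds do not
#' overflow.
#'
#' @param population Total count (N or S_T). Vectorised; vectors recycle.
#' @param successes Count in the distinguished class (e.g. Group 1 size).
#' @param draws Count carrying the property (e.g. samples covered by a
#'   pathway signature).
#' @param observed Overlap count whose tail is evaluated.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(138, 63, 90, 60)   # 8.55e-13
#' hypergeom_upper_tail(10, 4, 5, 3)       # 66/252
#' @export
hypergeom_upper_tail <- function(population, successes, draws, observed) {
  n <- max(length(population), length(successes), length(draws), length(observed))
  population <- rep_len(as.numeric(population), n)
  successes <- rep_len(as.numeric(successes), n)
  draws <- rep_len(as.numeric(draws), n)
  observed <- rep_len(as.numeric(observed), n)

  counts <- cbind(population, successes, draws, observed)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("All counts must be finite non-negative integers.")
  }
  if (any(successes > population) || any(draws > population)) {
    abort("`successes` and `draws` cannot exceed `population`.")
  }
  if (any(observed > pmin(successes, draws))) {
    abort("`observed` cannot exceed min(successes, draws).")
  }
  if (any(observed < pmax(0, draws + successes - population))) {
    abort("`observed` is below the support of the hypergeometric distribution.")
  }

  vapply(seq_len(n), function(j) {
    k <- observed[j]
    if (k == 0) return(1)
    i <- k:min(draws[j], successes[j])
    lt <- lchoose(successes[j], i) + lchoose(population[j] - successes[j], draws[j] - i) -
      lchoose(population[j], draws[j])
    mx <- max(lt)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to input
#' order, where `m` is the number of tests actually performed in the calling
#' batch. Delegates to [stats::p.adjust()] after validating the input domain.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

# Vectorised per-row Welch test on a values matrix split into two sample sets.
# Zero variance in both groups: equal means -> p = 1; unequal -> p = 0
# (flagged degenerate), keeping the decision rule continuous on toy fixtures.
welch_rows <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- m[, idx1, drop = FALSE]; x2 <- m[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(mean1 = m1, mean2 = m2, t = tstat, df = df, p = p, degenerate = degen)
}
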