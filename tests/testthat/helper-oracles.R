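# Independent brute-force oracles, kept deliberately naive.

# Two-class F-score straight from the defining formula.
oracle_f_score <- function(x, y) {
  xp <- x[y == 1]; xn <- x[y == 0]
  num <- (mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
    sum((xn - mean(xn))^2) / (length(xn) - 1)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

# O(n^2) pairwise-concordance AUC (ties count one half).
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
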