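# Independent brute-force oracles for the statistical operations.  Each
# recomputes the target quantity from first principles (explicit loops,
# exhaustive enumeration, hand-coded formulas) without sharing code with
# the package implementation.

# ICC(A,1) from an explicit two-way ANOVA decomposition by loops
oracle_icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0; ssc <- 0; sse <- 0
  rm_ <- numeric(n); cm_ <- numeric(k)
  for (i in 1:n) rm_[i] <- sum(x[i, ]) / k
  for (j in 1:k) cm_[j] <- sum(x[, j]) / n
  for (i in 1:n) ssr <- ssr + k * (rm_[i] - gm)^2
  for (j in 1:k) ssc <- ssc + n * (cm_[j] - gm)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - rm_[i] - cm_[j] + gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# midranks by pairwise counting, then Pearson on the ranks by sums
oracle_spearman <- function(x, y) {
  n <- length(x)
  midrank <- function(v) {
    r <- numeric(n)
    for (i in 1:n) {
      below <- 0; equal <- 0
      for (j in 1:n) {
        if (v[j] < v[i]) below <- below + 1
        if (v[j] == v[i]) equal <- equal + 1
      }
      r[i] <- below + (equal + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  rho <- sxy / sqrt(sxx * syy)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), n - 2, lower.tail = FALSE)  # avoids 1 - pt cancellation
  }
  list(rho = rho, p = p)
}

# Mann-Whitney U by pairwise counting; exact p by exhaustive enumeration
# of group assignments (no ties), asymptotic p by the hand-coded
# tie-corrected normal approximation
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  # U of wilcoxon rank-sum convention: number of (x, y) pairs with x > y
  # equals R1 - n1(n1+1)/2
  pooled <- c(x, y)
  has_ties <- any(duplicated(pooled))
  exact_p <- NA_real_
  if (!has_ties && choose(n1 + n2, n1) <= 1e5) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(id) {
      xx <- pooled[id]; yy <- pooled[-id]
      s <- 0
      for (xi in xx) for (yj in yy) s <- s + (xi > yj)
      s
    })
    m <- n1 * n2 / 2
    exact_p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    # match the pwilcox-style two-sided rule used by the implementation
    exact_p <- if (u > m) min(1, 2 * mean(us >= u)) else min(1, 2 * mean(us <= u))
  }
  nn <- n1 + n2
  tie_sizes <- table(pooled)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  asym_p <- if (sigma2 <= 0) 1 else
    2 * pnorm(-abs((u - n1 * n2 / 2) / sqrt(sigma2)))
  list(u = u, exact_p = exact_p, asym_p = asym_p)
}

# Kruskal-Wallis H with tie correction from the definition
oracle_kruskal <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    h <- h + sum(r[idx])^2 / sum(idx)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# log-rank chi-square by walking the event times: observed minus
# expected deaths in group 1 with the hypergeometric variance
oracle_logrank <- function(times, events, groups) {
  groups <- as.integer(factor(groups))
  stopifnot(all(groups %in% 1:2))
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & groups == 1)
    d_tot <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == 1)
    o_minus_e <- o_minus_e + d1 - d_tot * n1 / n_tot
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  o_minus_e^2 / v
}

# Cox partial log-likelihood (Breslow) evaluated on a beta grid; used to
# check the closed-form single-risk-set case and small fits
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
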