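# Independent oracles used to validate the package implementations. Each is
# written as directly as possible (brute force / enumeration) and shares no
# code with the functions it checks.

# Benjamini-Hochberg by literal step-up definition:
# q_i = min over j with p_(j) >= p_i of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- m * ps[i:m] / (i:m)
    q[ord[i]] <- min(1, min(cands))
  }
  q
}

# Two-sample KS D by double-loop ECDF maximisation over the pooled support.
oracle_ks_d <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (t in pts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Exact two-sided tail probability of the pooled two-proportion Z statistic:
# X1 ~ Bin(n1, p_pool), X2 ~ Bin(n2, p_pool) independently, P(|Z| >= |z_obs|).
oracle_ztest_enum <- function(x1, n1, x2, n2) {
  zstat <- function(a, b) {
    pp <- (a + b) / (n1 + n2)
    if (pp <= 0 || pp >= 1) return(0)
    (a / n1 - b / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  pp <- (x1 + x2) / (n1 + n2)
  zobs <- abs(zstat(x1, x2))
  tot <- 0
  for (a in 0:n1) for (b in 0:n2)
    if (abs(zstat(a, b)) >= zobs - 1e-12)
      tot <- tot + stats::dbinom(a, n1, pp) * stats::dbinom(b, n2, pp)
  tot
}

# Wallenius tail by exhaustive enumeration of ordered weighted draws without
# replacement: items with weights w, draw n, P(# drawn from `category` >= k).
oracle_wallenius_tail <- function(w, category, n, k) {
  total <- 0
  recurse <- function(remaining, drawn_cat, depth, prob) {
    if (depth == n) {
      if (drawn_cat >= k) total <<- total + prob
      return(invisible())
    }
    wsum <- sum(w[remaining])
    for (i in remaining) {
      recurse(setdiff(remaining, i),
              drawn_cat + (i %in% category),
              depth + 1L, prob * w[i] / wsum)
    }
  }
  recurse(seq_along(w), 0L, 0L, 1)
  total
}

# Small cohort used across unit tests (fast; not the acceptance-scale cohort).
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(n_patients = 40, n_controls = 15,
                                n_probes = 300, n_rnas = 200, seed = seed, ...))
}

# Minimal hand-built sample sheet for model-level tests.
toy_sheet <- function(n, group, age = NULL, sex = NULL, bmi = NULL) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             group = group,
             age = age %||% (40 + (seq_len(n) * 7) %% 23),
             sex = sex %||% rep(c("male", "female"), length.out = n),
             bmi = bmi %||% (22 + (seq_len(n) * 5) %% 11 / 2),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
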