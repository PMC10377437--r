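# Independent oracles: deliberately naive implementations used only to check
# the package's results, never shared with the implementation path.

# k-group log-rank statistic accumulated straight from the hypergeometric
# model: at each distinct event time, observed minus expected events per
# group and the full tie-corrected covariance; chi-square quadratic form on
# the first k-1 groups
logrank_oracle <- function(time, event, group) {
  g <- factor(group)
  k <- nlevels(g)
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dg <- vapply(levels(g), function(l) sum(event == 1 & time == t & g == l),
                 numeric(1))
    U <- U + dg - d * ng / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          V[a, b] <- V[a, b] +
            mult * (ng[a] / n) * ((a == b) - ng[b] / n)
        }
      }
    }
  }
  # quadratic form via the Moore-Penrose pseudo-inverse: U sums to zero, so
  # this reduces to the usual (k-1)-submatrix solve when V has full rank k-1
  # and handles groups that are never at risk at an event time
  sv <- svd(V)
  pos <- sv$d > max(sv$d) * 1e-10
  vinv <- sv$v[, pos, drop = FALSE] %*%
    diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  chi2 <- drop(t(U) %*% vinv %*% U)
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

# product-limit estimator computed directly from its definition
km_oracle <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n <- sum(time >= t)
    d <- sum(event == 1 & time == t)
    s <- s * (1 - d / n)
  }
  s
}

# random small survival instance with guaranteed >= 2 groups and >= 1 event
random_toy_surv <- function(n = 8, k = 2) {
  repeat {
    time <- sample(1:10, n, replace = TRUE)
    event <- stats::rbinom(n, 1, 0.7)
    group <- sample(letters[seq_len(k)], n, replace = TRUE)
    if (length(unique(group)) == k && sum(event) >= 1 &&
        all(table(group) >= 1)) {
      return(list(time = time, event = event, group = group))
    }
  }
}

# greedy nearest-neighbour matching re-implemented naively for cross-checks
greedy_oracle <- function(score_t, score_c, id_t, id_c, caliper = Inf) {
  sc <- score_c[order(id_c)]
  ic <- sort(id_c)
  st <- score_t[order(id_t)]
  it <- sort(id_t)
  taken <- logical(length(sc))
  out <- NULL
  for (i in seq_along(st)) {
    best_j <- 0
    best_d <- Inf
    for (j in seq_along(sc)) {
      if (taken[j]) next
      dj <- abs(sc[j] - st[i])
      if (dj < best_d) {
        best_d <- dj
        best_j <- j
      }
    }
    if (best_j > 0 && best_d <= caliper) {
      taken[best_j] <- TRUE
      out <- rbind(out, data.frame(treated_id = it[i], control_id = ic[best_j],
                                   distance = best_d))
    }
  }
  out
}

# best achievable single-split AUC for a binary label over every cutpoint of
# a single feature, by exhaustive search over observed values and both
# directions
best_single_split_auc <- function(x, label) {
  ok <- !is.na(label)
  x <- x[ok]; label <- label[ok]
  best <- 0.5
  for (cut in sort(unique(x))) {
    for (hi in list(x >= cut, x < cut)) {
      n1 <- sum(label == 1); n0 <- sum(label == 0)
      tpr <- sum(hi & label == 1) / n1
      fpr <- sum(hi & label == 0) / n0
      auc <- (1 + tpr - fpr) / 2
      best <- max(best, auc)
    }
  }
  best
}
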