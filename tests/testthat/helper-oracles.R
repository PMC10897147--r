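# Independent oracles used across the suite. These deliberately avoid the
# package's convolution/NNLS/silhouette code paths: enumeration, closed forms
# and grid search only. They share only the embedded isotope constant table,
# so both routes agree on physical constants.

# all compositions of n atoms over j isotope slots (rows sum to n)
enumerate_compositions <- function(n, j) {
  if (j == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (k in 0:n) {
    rest <- enumerate_compositions(n - k, j - 1)
    out[[k + 1]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

# brute-force isotopologue envelope: enumerate every per-element isotope
# composition with its multinomial probability and exact mass, cross elements,
# and aggregate by total neutron shift
oracle_envelope <- function(sequence, scheme = "natural", p15 = NULL,
                            trunc = 1e-6) {
  comp <- peptide_composition(sequence)
  iso <- isotope_table()
  per_element <- list()
  for (el in names(comp$counts)) {
    n <- comp$counts[[el]]
    if (n == 0) next
    rows <- iso[iso$element == el, ]
    ab <- rows$abundance
    if (el == "N" && scheme == "nitrogen15") ab <- c(1 - p15, p15)
    combos <- enumerate_compositions(n, nrow(rows))
    lp <- lgamma(n + 1) - rowSums(lgamma(combos + 1)) +
      as.numeric(combos %*% ifelse(ab > 0, log(ab), -Inf))
    lp[apply(combos, 1, function(k) any(k > 0 & ab == 0))] <- -Inf
    per_element[[el]] <- data.frame(
      shift = as.integer(combos %*% rows$shift),
      prob = exp(lp),
      mass = as.numeric(combos %*% rows$mass)
    )
  }
  # cross elements, aggregating by cumulative shift (probabilities and
  # probability-weighted masses are additive across bins)
  acc <- data.frame(shift = 0L, prob = 1, mmom = 0)
  for (d in per_element) {
    d <- d[d$prob > 1e-18, ]
    shift <- outer(acc$shift, d$shift, `+`)
    prob <- outer(acc$prob, d$prob)
    mmom <- outer(acc$mmom, d$prob) + outer(acc$prob, d$prob * d$mass)
    key <- as.vector(shift)
    acc <- data.frame(
      shift = sort(unique(key)),
      prob = as.numeric(tapply(as.vector(prob), key, sum)),
      mmom = as.numeric(tapply(as.vector(mmom), key, sum))
    )
  }
  acc$mass <- acc$mmom / acc$prob + comp$fixed_mass
  acc <- acc[acc$prob / sum(acc$prob) >= trunc, ]
  acc$prob <- acc$prob / sum(acc$prob)
  acc
}

# grid-search mixture-fraction oracle: minimize SSE over w with per-w optimal
# scale (independent of the NNLS path)
oracle_fit_w <- function(observed, xo, xn, grid = seq(0, 1, by = 1e-4)) {
  sse <- vapply(grid, function(w) {
    shape <- w * xo + (1 - w) * xn
    s <- sum(shape * observed) / sum(shape^2)
    sum((observed - s * shape)^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# brute-force mean silhouette on a small matrix
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# exhaustive hypergeometric upper tail
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# closed-form two-sample Student t
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# closed-form Kruskal-Wallis H (no ties)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  12 / (n * (n + 1)) *
    sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
}

# deterministic small peptide panel for envelope oracle comparisons
oracle_peptide_panel <- function(n = 50, max_len = 6, seed = 1) {
  set.seed(seed)
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(2:max_len, 1), replace = TRUE), collapse = "")
  }, "")
}
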