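# Independent oracles used to cross-check the package's statistics.
# These deliberately re-derive each quantity from first principles
# (enumeration / closed form), not by calling the code paths they check.

# Two-sided Fisher exact p for a 2x2 table, by direct hypergeometric
# enumeration: sum the probabilities of all tables (fixed margins) no more
# likely than the observed one.
fisher_p_oracle <- function(a, b, c, d) {
  K <- a + b          # row 1 total
  N <- a + b + c + d
  k <- a + c          # column 1 total
  x_min <- max(0L, k - (N - K))
  x_max <- min(k, K)
  xs <- x_min:x_max
  probs <- dhyper(xs, K, N - K, k)
  p_obs <- dhyper(a, K, N - K, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments (zero differences dropped before calling).
wilcoxon_p_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 15)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  p_low <- mean(v_null <= v_obs)
  p_high <- mean(v_null >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Naive run-length segmentation oracle: smooth with an explicit loop,
# threshold, scan for state changes. No run-merging (use on toys whose
# runs all exceed the minimum length).
segment_oracle <- function(pos, ml, w, thr) {
  n <- length(ml)
  h <- (w - 1) %/% 2
  sm <- numeric(n)
  for (i in seq_len(n)) sm[i] <- mean(ml[max(1, i - h):min(n, i + h)])
  st <- sm >= thr
  bounds <- which(diff(st) != 0)
  starts <- c(1, bounds + 1)
  ends <- c(bounds, n)
  data.frame(start = pos[starts], end = pos[ends] + 1,
             state = ifelse(st[starts], "methylated", "unmethylated"),
             n_cpgs = ends - starts + 1)
}

# Textbook Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Quick MethylomeTable from parallel vectors
make_mt <- function(pos, n_meth, n_total, chrom = "chr1", strand = "+",
                    context = "CG", ...) {
  methylome_table(data.frame(chrom = chrom, pos = pos, strand = strand,
                             context = context, n_meth = n_meth,
                             n_total = n_total), ...)
}

# Uniform-coverage table with given per-site MLs (exact counts)
make_ml_mt <- function(pos, ml, cov = 10L, ...) {
  make_mt(pos, as.integer(round(ml * cov)), rep(cov, length(pos)), ...)
}
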