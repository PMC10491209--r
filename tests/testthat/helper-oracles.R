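# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: exhaustive enumeration for the rank-sum test, the
# literal step-up definition for BH, and the closed-form pooled-variance
# two-sample t-test.

# Exact two-sided Mann-Whitney p by enumerating all C(n, m) assignments of
# the pooled ranks to the condition group. Assumes no ties.
wilcox_enum_p <- function(ctrl, cond) {
  pooled <- c(ctrl, cond)
  n <- length(pooled)
  m <- length(cond)
  r <- rank(pooled)
  w_obs <- sum(r[length(ctrl) + seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  w_all <- apply(combs, 2L, function(i) sum(r[i]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Literal Benjamini-Hochberg step-up: for the i-th smallest p-value,
# adj_i = min over j >= i of min(1, m * p_(j) / j). O(m^2) on purpose.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * sorted[j] / j), numeric(1))
    adj[i] <- min(vals)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form equal-variance two-sample t-test p-value.
ttest_pooled_p <- function(ctrl, cond) {
  n0 <- length(ctrl); n1 <- length(cond)
  sp2 <- ((n0 - 1) * stats::var(ctrl) + (n1 - 1) * stats::var(cond)) / (n0 + n1 - 2)
  t <- (mean(cond) - mean(ctrl)) / sqrt(sp2 * (1 / n0 + 1 / n1))
  2 * stats::pt(-abs(t), n0 + n1 - 2)
}

# 3-versus-3 design used by most fixtures (matches simulate_scenario()).
toy_design <- function() {
  new_design(c(sprintf("ctrl_%d", 1:3), sprintf("case_%d", 1:3)),
             rep(c("control", "shortened"), each = 3),
             reference = "control")
}

# Read-length table from a list: tbl_spec[[transcript]][[library]] = lengths.
table_from_spec <- function(tbl_spec) {
  rows <- list()
  for (tx in names(tbl_spec)) {
    for (lib in names(tbl_spec[[tx]])) {
      lens <- tbl_spec[[tx]][[lib]]
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s_%s_%d", tx, lib, seq_along(lens)),
        library_id = lib, transcript_id = tx, length = lens,
        stringsAsFactors = FALSE)
    }
  }
  as_length_table(do.call(rbind, rows))
}
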