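# Independent brute-force oracles used to freeze expected values.

# Exact two-sided Mann-Whitney p by enumeration of all group assignments of
# the pooled sample (midranks), via the symmetric tail definition
# P(|U - mu| >= |u_obs - mu|).
mw_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-tailed Fisher p by hypergeometric enumeration over all tables with the
# observed margins: sum probabilities not exceeding the observed table's
# (with the conventional 1e-7 relative slack for ties).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, 1.0)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-way ANOVA F on absolute deviations, written out from sums of squares.
levene_F_oracle <- function(a, b, center = stats::median) {
  da <- abs(a - center(a)); db <- abs(b - center(b))
  dev <- c(da, db)
  gm <- mean(dev)
  ssb <- length(da) * (mean(da) - gm)^2 + length(db) * (mean(db) - gm)^2
  ssw <- sum((da - mean(da))^2) + sum((db - mean(db))^2)
  dfb <- 1
  dfw <- length(dev) - 2
  (ssb / dfb) / (ssw / dfw)
}

# match segmented nuclei to truth nuclei by nearest centroid; returns the
# truth index per segmented nucleus
match_truth_nuclei <- function(seg_nuclei, truth_nuclei) {
  vapply(seq_len(nrow(seg_nuclei)), function(i) {
    dd <- sqrt((truth_nuclei$center_z_um - seg_nuclei$centroid_z_um[i])^2 +
                 (truth_nuclei$center_y_um - seg_nuclei$centroid_y_um[i])^2 +
                 (truth_nuclei$center_x_um - seg_nuclei$centroid_x_um[i])^2)
    which.min(dd)
  }, 1L)
}
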