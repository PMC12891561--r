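test_result <- function(test_name, statistic, p_value, n_a, n_b,
                        flagged = FALSE) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_a = n_a, n_b = n_b,
                 sidedness = "two-sided", flagged = flagged),
            class = "ct_test_result")
}

#' @export
print.ct_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (two-sided, n = %d, %d)%s\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Mann-Whitney two-sided U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is exact
#' for small samples (`n_a + n_b <= 12`): by the exact U distribution when
#' there are no ties, and by full enumeration of the
#' \eqn{\binom{n_a+n_b}{n_a}} group assignments (with midranks) when there
#' are. Larger samples use the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param a,b numeric samples (each nonempty).
#' @return a test-result object with the U statistic for sample `a`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("samples must be nonempty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (na + nb <= 12L) {
    if (!ties) {
      p <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
    } else {
      # exact permutation distribution of U with midranks
      mu <- na * nb / 2
      combs <- utils::combn(na + nb, na)
      us <- apply(combs, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
      p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    }
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  test_result("Mann-Whitney U", u, min(1, p), na, nb)
}

#' Fisher's two-tailed exact test for a 2x2 table
#'
#' Two-tailed p as the sum of hypergeometric probabilities, over all tables
#' with the observed margins, of tables no more probable than the observed
#' one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return a test-result object; the statistic is the conditional
#'   odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (sum(table) == 0) stop("at least one positive margin is required")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  test_result("Fisher exact", unname(ft$estimate), ft$p.value,
              sum(table[1, ]), sum(table[2, ]))
}

#' Levene's test for equality of spread between two samples
#'
#' One-way ANOVA F on absolute deviations from the group centre. The default
#' centre is the median (the robust Brown-Forsythe variant); `center =
#' "mean"` gives the classical form.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @param center `"median"` (default) or `"mean"`.
#' @return a test-result object with the F statistic. Degenerate input with
#'   all deviations zero returns statistic 0 and p 1, flagged.
#' @export
levene_test <- function(a, b, center = c("median", "mean")) {
  center <- match.arg(center)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  cf <- if (center == "median") stats::median else mean
  dev <- c(abs(a - cf(a)), abs(b - cf(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (all(dev == 0))
    return(test_result("Levene", 0, 1, length(a), length(b), flagged = TRUE))
  fit <- stats::aov(dev ~ g)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) return(test_result("Levene", 0, 1, length(a), length(b),
                                        flagged = TRUE))
  test_result("Levene", f, p, length(a), length(b))
}

#' Detect bimodality of a sample by kernel density estimation
#'
#' Gaussian KDE with a normal-reference bandwidth (Scott's 1.06 variant of
#' the rule of thumb, which at these sample sizes avoids spurious tail modes
#' that the tighter 0.9 factor admits); modes are interior local
#' maxima of the density with height at least `prominence` times the global
#' maximum, the antimode is the interior minimum between the two highest
#' modes, and the sample is called bimodal when two or more qualifying modes
#' exist. Used on normalized paired-arm volume distributions, where the
#' antimode separates tight from loose pairing.
#'
#' @param values numeric sample.
#' @param bandwidth optional KDE bandwidth (numeric); default normal
#'   reference (`stats::bw.nrd`).
#' @param prominence mode height floor as a fraction of the maximum density.
#' @param min_n below this sample size the result is unimodal, flagged.
#' @return object of class `bimodality_result`: `is_bimodal`, `antimode`
#'   (NA when unimodal), `mode_locations`, `bandwidth`, `flag`
#'   (`"ok"`, `"low_n"` or `"constant"`).
#' @export
detect_bimodality <- function(values, bandwidth = NULL, prominence = 0.05,
                              min_n = 20L) {
  values <- as.numeric(values[is.finite(values)])
  res <- function(bi, anti, modes, bw, flag)
    structure(list(is_bimodal = bi, antimode = anti, mode_locations = modes,
                   bandwidth = bw, flag = flag), class = "bimodality_result")
  if (length(values) < min_n)
    return(res(FALSE, NA_real_, numeric(0), NA_real_, "low_n"))
  if (stats::sd(values) == 0)
    return(res(FALSE, NA_real_, values[1], NA_real_, "constant"))
  dd <- stats::density(values, bw = bandwidth %||% "nrd", n = 512L)
  y <- dd$y; x <- dd$x; m <- length(y)
  i <- 2:(m - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L]
  modes_i <- i[is_max]
  modes_i <- modes_i[y[modes_i] >= prominence * max(y)]
  if (length(modes_i) < 2L)
    return(res(FALSE, NA_real_, x[modes_i], dd$bw, "ok"))
  top2 <- modes_i[order(y[modes_i], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  anti_i <- between[which.min(y[between])]
  res(TRUE, x[anti_i], x[modes_i], dd$bw, "ok")
}

#' @export
print.bimodality_result <- function(x, ...) {
  if (x$is_bimodal)
    cat(sprintf("<bimodality_result> bimodal; antimode at %.4g (bw %.4g)\n",
                x$antimode, x$bandwidth))
  else
    cat(sprintf("<bimodality_result> unimodal (%s)\n", x$flag))
  invisible(x)
}
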