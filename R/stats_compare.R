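# Strategy comparison harness: normality screen, paired one-sided Wilcoxon
# signed-rank tests, per-class best-alignment frequencies.
#
# The score store is a plain data.frame with columns benchmark, band,
# instance, variation, class, ds (one row per instance x strategy).

#' Shapiro-Wilk normality screen
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return the Shapiro-Wilk p-value.
#' @export
shapiro_normality <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("need 3 <= n <= 5000")
  if (length(unique(values)) == 1) stop("constant sample")
  stats::shapiro.test(values)$p.value
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests the alternative "a > b" on paired samples.  Zero differences are
#' dropped; with up to `exact_n` non-zero differences the p-value is exact
#' (rank-sum distribution by convolution, ties handled through midranks),
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.  If every difference is zero the p-value is 1 by
#' convention.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_n exact/approximate switch (default 25).
#' @return one-sided p-value for "a > b".
#' @export
wilcoxon_one_sided <- function(a, b, exact_n = 25) {
  if (length(a) != length(b)) stop("a and b must be paired")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_n) {
    # exact: P(W* >= W) over the 2^n equiprobable sign assignments.
    # Midranks are multiples of 1/2, so doubling gives integer weights.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)       # f[s+1] = #assignments with doubled sum s
    f[1] <- 1
    for (w in r2) {
      g <- f
      g[(w + 1):(total + 1)] <- g[(w + 1):(total + 1)] + f[1:(total + 1 - w)]
      f <- g
    }
    W2 <- as.integer(round(2 * W))
    sum(f[(W2 + 1):(total + 1)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

CLASSES <- c("P", "C", "I", "CI")
HYPOTHESES <- c("C>P", "I>P", "C>I", "CI>P", "CI>I", "CI>C")

#' Pairwise class comparison table for one benchmark group
#'
#' For each of the 20 variations, runs the six one-sided Wilcoxon tests
#' among its P/C/I/CI results over the group's instances.
#'
#' @param store score store data.frame (columns benchmark, band, instance,
#'   variation, class, ds).
#' @param benchmark,band which group to tabulate.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per variation, one column per
#'   hypothesis (`C>P`, `I>P`, `C>I`, `CI>P`, `CI>I`, `CI>C`), plus a
#'   parallel logical `significant` matrix as attribute.
#' @export
build_comparison_table <- function(store, benchmark, band, alpha = 0.05) {
  sub <- store[store$benchmark == benchmark & store$band == band, ]
  variations <- sort(unique(store$variation))
  missing <- character(0)
  get_sample <- function(v, cl) {
    s <- sub[sub$variation == v & sub$class == cl, ]
    s <- s[order(s$instance), ]
    if (nrow(s) == 0) missing <<- c(missing, paste0(v, "+", cl))
    s$ds
  }
  tab <- base::matrix(NA_real_, length(variations), length(HYPOTHESES),
                      dimnames = list(variations, HYPOTHESES))
  for (v in variations) {
    smp <- lapply(setNames(CLASSES, CLASSES), get_sample, v = v)
    if (length(missing)) next
    for (h in HYPOTHESES) {
      cls <- strsplit(h, ">", fixed = TRUE)[[1]]
      tab[v, h] <- wilcoxon_one_sided(smp[[cls[1]]], smp[[cls[2]]])
    }
  }
  if (length(missing))
    stop("missing strategy results: ", paste(unique(missing), collapse = ", "))
  out <- data.frame(variation = variations, tab, check.names = FALSE,
                    row.names = NULL)
  attr(out, "significant") <- tab < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Tied-best and unique-best frequencies per heuristic class
#'
#' For each instance of the group the best Developer Score over all
#' strategies is found; a class is *tied-best* on the instance if any of
#' its variants attains that score, and *unique-best* if additionally no
#' other class does.  Frequencies are percentages over the group's
#' instances.
#'
#' @inheritParams build_comparison_table
#' @return data.frame with columns class, tied_best, unique_best
#'   (percentages).
#' @export
best_class_frequencies <- function(store, benchmark, band) {
  sub <- store[store$benchmark == benchmark & store$band == band, ]
  if (nrow(sub) == 0) stop("empty benchmark group")
  instances <- unique(sub$instance)
  tied <- setNames(numeric(length(CLASSES)), CLASSES)
  uniq <- tied
  for (ins in instances) {
    si <- sub[sub$instance == ins, ]
    best <- max(si$ds)
    hit <- vapply(CLASSES, function(cl) any(si$ds[si$class == cl] == best),
                  TRUE)
    tied[hit] <- tied[hit] + 1
    if (sum(hit) == 1) uniq[hit] <- uniq[hit] + 1
  }
  data.frame(class = CLASSES,
             tied_best = 100 * tied / length(instances),
             unique_best = 100 * uniq / length(instances),
             row.names = NULL)
}
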