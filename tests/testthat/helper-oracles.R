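# Independent brute-force oracles.  These enumerate the full search space
# (alignments, HMM paths, sign assignments) directly and are deliberately
# slow and simple; they never call the package's DP kernels.

# all global alignments of a[1..la] vs b[1..lb] by exhaustive recursion,
# scored with affine gaps: a run of length g costs open*mult + (g-1)*ext,
# where mult is the position-specific multiplier of the profile receiving
# the gap indexed by the other profile's current position; free_ends
# leaves runs at j==0 / j==lb (or i==0 / i==la) uncharged.
oracle_affine_best <- function(match, open, ext, mult_a = NULL, mult_b = NULL,
                               free_ends = FALSE) {
  la <- nrow(match); lb <- ncol(match)
  if (is.null(mult_a)) mult_a <- rep(1, la + 1)
  if (is.null(mult_b)) mult_b <- rep(1, lb + 1)
  rec <- function(i, j, state) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb)
      best <- max(best, match[i + 1, j + 1] + rec(i + 1, j + 1, "M"))
    if (i < la) {   # gap in B
      cost <- if (free_ends && (j == 0 || j == lb)) 0
              else if (state == "X") ext else open * mult_b[j + 1]
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j < lb) {   # gap in A
      cost <- if (free_ends && (i == 0 || i == la)) 0
              else if (state == "Y") ext else open * mult_a[i + 1]
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(0, 0, "start")
}

# classic quadratic LCS table
oracle_lcs <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  D <- matrix(0L, length(a) + 1, length(b) + 1)
  for (i in seq_along(a))
    for (j in seq_along(b))
      D[i + 1, j + 1] <- if (a[i] == b[j]) D[i, j] + 1L
                         else max(D[i, j + 1], D[i + 1, j])
  D[length(a) + 1, length(b) + 1]
}

# pair-HMM posteriors by explicit path enumeration (probability space).
# Matches the package model: start behaves as M (start->M = 1-2d,
# start->X = start->Y = d), no end transition.
oracle_pairhmm_posterior <- function(s1, s2, params) {
  ab <- params$alphabet
  x <- match(strsplit(toupper(s1), "")[[1]], ab)
  y <- match(strsplit(toupper(s2), "")[[1]], ab)
  lx <- length(x); ly <- length(y)
  d <- params$delta; e <- params$epsilon
  trans <- function(from, to) {
    if (from %in% c("start", "M"))
      switch(to, M = 1 - 2 * d, X = d, Y = d)
    else if (to == from) e
    else if (to == "M") 1 - e
    else 0
  }
  total <- 0
  mass <- matrix(0, lx, ly)
  rec <- function(i, j, state, p, mcells) {
    if (p == 0) return(invisible())
    if (i == lx && j == ly) {
      total <<- total + p
      if (nrow(mcells)) mass[mcells] <<- mass[mcells] + p
      return(invisible())
    }
    if (i < lx && j < ly)
      rec(i + 1, j + 1, "M",
          p * trans(state, "M") * params$em[x[i + 1], y[j + 1]],
          rbind(mcells, c(i + 1, j + 1)))
    if (i < lx)
      rec(i + 1, j, "X", p * trans(state, "X") * params$bg[x[i + 1]], mcells)
    if (j < ly)
      rec(i, j + 1, "Y", p * trans(state, "Y") * params$bg[y[j + 1]], mcells)
  }
  rec(0, 0, "start", 1, matrix(0L, 0, 2))
  mass / total
}

# best monotone path sum over a posterior matrix, by recursion
oracle_mea <- function(post) {
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    max(rec(i - 1, j - 1) + post[i, j], rec(i - 1, j), rec(i, j - 1))
  }
  rec(nrow(post), ncol(post))
}

# exact one-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ge <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(r[signs]) >= W - 1e-12) ge <- ge + 1L
  }
  ge / 2^n
}

# tied/unique best-class frequencies recomputed the long way
oracle_best_class <- function(store, benchmark, band) {
  classes <- c("P", "C", "I", "CI")
  sub <- store[store$benchmark == benchmark & store$band == band, ]
  instances <- unique(sub$instance)
  out <- data.frame(class = classes, tied_best = 0, unique_best = 0)
  for (ins in instances) {
    si <- sub[sub$instance == ins, ]
    best <- max(si$ds)
    winners <- unique(si$class[si$ds == best])
    for (cl in winners) {
      k <- match(cl, classes)
      out$tied_best[k] <- out$tied_best[k] + 1
      if (length(winners) == 1) out$unique_best[k] <- out$unique_best[k] + 1
    }
  }
  out$tied_best <- 100 * out$tied_best / length(instances)
  out$unique_best <- 100 * out$unique_best / length(instances)
  out
}

# random residue string
rand_seq <- function(len, alphabet = c("A", "C", "D", "E", "F", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
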