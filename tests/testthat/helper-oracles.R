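# Independent reference implementations used as oracles. These are written
# directly from the definitions (plain R, no shared code with the package
# internals) and are only run at small problem sizes.

# pairwise compatibility matrix over an interval (diagonal TRUE)
oracle_compat <- function(mat, j, k) {
  v <- unclass(mat)[, j:k, drop = FALSE]
  m <- nrow(v)
  comp <- matrix(TRUE, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a >= b) next
      both <- !is.na(v[a, ]) & !is.na(v[b, ])
      ok <- all(v[a, both] == v[b, both])
      comp[a, b] <- comp[b, a] <- ok
    }
  }
  comp
}

# classify rows of an interval: ambiguous / common / singleton + counts
oracle_classify <- function(mat, j, k) {
  comp <- oracle_compat(mat, j, k)
  m <- nrow(comp)
  partners <- lapply(seq_len(m), function(r) setdiff(which(comp[r, ]), r))
  amb <- vapply(seq_len(m), function(r) {
    nb <- partners[[r]]
    if (length(nb) < 2L) return(FALSE)
    any(!comp[nb, nb][upper.tri(matrix(0, length(nb), length(nb)))])
  }, logical(1L))
  common <- vapply(seq_len(m), function(r) {
    if (amb[r]) return(FALSE)
    any(!amb[partners[[r]]])
  }, logical(1L))
  cls <- ifelse(amb, "ambiguous", ifelse(common, "common", "singleton"))
  U <- sum(!amb)
  S <- sum(cls == "singleton")
  list(U = U, C = sum(cls == "common"), S = S, ambiguous = sum(amb),
       delta = if (U > 0) S / U else 0, class = cls, comp = comp)
}

oracle_delta <- function(mat, j, k) oracle_classify(mat, j, k)$delta

# n x n upper-triangular delta table by exhaustive recomputation
oracle_delta_table <- function(mat) {
  n <- ncol(mat)
  d <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (e in j:n) d[j, e] <- oracle_delta(mat, j, e)
  }
  d
}

# n x n upper-triangular feasibility matrix under (D, W)
oracle_feasible <- function(mat, D, W = Inf) {
  n <- ncol(mat)
  feas <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    for (e in j:min(n, j + W - 1)) {
      feas[j, e] <- oracle_delta(mat, j, e) <= D
    }
  }
  feas
}

# good-partner table by exhaustive per-interval recomputation
oracle_partner <- function(mat, D, W = Inf) {
  n <- ncol(mat)
  vapply(seq_len(n), function(i) {
    for (s in max(1L, i - as.integer(min(W, n)) + 1L):i) {
      if (oracle_delta(mat, s, i) <= D) return(s)
    }
    NA_integer_
  }, integer(1L))
}

# best total length using at most k disjoint feasible intervals, by
# memoised recursion over all feasible intervals starting at each locus
# (independent of the good-partner/Eq-style DP)
oracle_longest_k <- function(feas, k) {
  n <- nrow(feas)
  memo <- array(NA_real_, dim = c(n + 1L, k + 1L))
  rec <- function(j, kk) {
    if (j > n || kk == 0L) return(0)
    if (!is.na(memo[j, kk + 1L])) return(memo[j, kk + 1L])
    best <- rec(j + 1L, kk)
    for (e in j:n) {
      if (feas[j, e]) best <- max(best, (e - j + 1) + rec(e + 1L, kk - 1L))
    }
    memo[j, kk + 1L] <<- best
    best
  }
  rec(1L, k)
}

# flat enumeration over every set of <= k disjoint feasible intervals
# (tiny n only; cross-checks oracle_longest_k itself)
oracle_longest_k_flat <- function(feas, k) {
  n <- nrow(feas)
  ints <- which(feas, arr.ind = TRUE)
  ints <- ints[ints[, 1] <= ints[, 2], , drop = FALSE]
  if (nrow(ints) == 0L) return(0)
  best <- 0
  rec2 <- function(i, chosen, len) {
    best <<- max(best, len)
    if (length(chosen) / 2 >= k || i > nrow(ints)) return()
    for (h in i:nrow(ints)) {
      s <- ints[h, 1]; e <- ints[h, 2]
      disjoint <- TRUE
      if (length(chosen)) {
        cs <- chosen[c(TRUE, FALSE)]; ce <- chosen[c(FALSE, TRUE)]
        disjoint <- all(e < cs | s > ce)
      }
      if (disjoint) rec2(h + 1L, c(chosen, s, e), len + e - s + 1)
    }
  }
  rec2(1L, numeric(0), 0)
  best
}

# minimum number of feasible blocks fully covering [1, n]; Inf if impossible
oracle_min_blocks <- function(feas) {
  n <- nrow(feas)
  memo <- rep(NA_real_, n + 1L)
  rec <- function(j) {
    if (j > n) return(0)
    if (!is.na(memo[j])) return(memo[j])
    best <- Inf
    for (e in j:n) {
      if (feas[j, e]) {
        sub <- rec(e + 1L)
        if (is.finite(sub)) best <- min(best, 1 + sub)
      }
    }
    memo[j] <<- best
    best
  }
  rec(1L)
}

# do the loci in T tell all representative rows apart? (NA = wildcard)
oracle_distinguishes <- function(reps, T) {
  sub <- reps[, T, drop = FALSE]
  kg <- nrow(sub)
  for (a in seq_len(kg - 1L)) {
    for (b in (a + 1L):kg) {
      d <- !is.na(sub[a, ]) & !is.na(sub[b, ]) & sub[a, ] != sub[b, ]
      if (!any(d)) return(FALSE)
    }
  }
  TRUE
}

# lexicographically-first minimum distinguishing subset by flat enumeration
oracle_tagsnp <- function(reps) {
  w <- ncol(reps)
  if (nrow(reps) <= 1L) return(integer(0))
  for (size in 1:w) {
    cmb <- utils::combn(w, size)
    for (i in seq_len(ncol(cmb))) {
      if (oracle_distinguishes(reps, cmb[, i])) return(cmb[, i])
    }
  }
  NULL
}

# seeded random complete/missing matrices for property tests
rand_hap <- function(m, n, seed, missing_rate = 0, p1 = 0.5) {
  set.seed(seed)
  v <- matrix(sample(0:1, m * n, replace = TRUE, prob = c(1 - p1, p1)), m, n)
  if (missing_rate > 0) {
    v[matrix(runif(m * n) < missing_rate, m, n)] <- NA_integer_
  }
  hap_matrix(v)
}

# the six printed sample strings; two of them duplicated gives the 8-row
# worked example with delta = 4/8
sample_strings <- c("10001", "11100", "00011", "11110", "00001", "01001")

strings_to_hap <- function(strs) {
  chars <- do.call(rbind, strsplit(strs, "", fixed = TRUE))
  v <- matrix(NA_integer_, nrow(chars), ncol(chars))
  v[chars == "0"] <- 0L
  v[chars == "1"] <- 1L
  hap_matrix(v)
}
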