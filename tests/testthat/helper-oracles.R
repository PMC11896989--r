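# Independent oracles: deliberately naive implementations used only to
# validate the package's fast paths.

# Pairwise-counting GLCM + direct Haralick sums for one window.
oracle_window_features <- function(gray, center, levels, window = 3L,
                                   symmetric = TRUE) {
  h <- window %/% 2
  offs <- cbind(c(0, -1, -1, -1), c(1, 1, 0, -1))
  counts <- matrix(0, levels, levels)
  for (o in seq_len(nrow(offs))) {
    for (r in (center[1] - h):(center[1] + h)) {
      for (c in (center[2] - h):(center[2] + h)) {
        r2 <- r + offs[o, 1]; c2 <- c + offs[o, 2]
        inside <- function(rr, cc) rr >= 1 && cc >= 1 && rr <= nrow(gray) &&
          cc <= ncol(gray) && rr >= center[1] - h && rr <= center[1] + h &&
          cc >= center[2] - h && cc <= center[2] + h
        if (!inside(r, c) || !inside(r2, c2)) next
        a <- gray[r, c]; b <- gray[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
        if (symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
      }
    }
  }
  if (sum(counts) == 0) return(rep(NaN, 8))
  P <- counts / sum(counts)
  G <- levels
  acc <- c(MEA = 0, VAR = 0, HOM = 0, CON = 0, DIS = 0, ENT = 0, SEC = 0,
           COR = 0)
  ui <- 0; uj <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    ui <- ui + i * P[i + 1, j + 1]; uj <- uj + j * P[i + 1, j + 1]
  }
  vi <- 0; vj <- 0; cv <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    acc["MEA"] <- acc["MEA"] + i * p
    acc["HOM"] <- acc["HOM"] + p / (1 + (i - j)^2)
    acc["CON"] <- acc["CON"] + (i - j)^2 * p
    acc["DIS"] <- acc["DIS"] + abs(i - j) * p
    if (p > 0) acc["ENT"] <- acc["ENT"] - p * log2(p)
    acc["SEC"] <- acc["SEC"] + p^2
    vi <- vi + (i - ui)^2 * p; vj <- vj + (j - uj)^2 * p
    cv <- cv + (i - ui) * (j - uj) * p
  }
  for (i in 0:(G - 1)) for (j in 0:(G - 1))
    acc["VAR"] <- acc["VAR"] + (i - ui)^2 * P[i + 1, j + 1]
  acc["COR"] <- if (vi <= 0 || vj <= 0) 1 else cv / sqrt(vi * vj)
  acc
}

# Exhaustive-search MIC: same y-equipartition as the estimator, but the
# column partition is found by brute force over all boundary subsets between
# distinct sorted x values (a superset of the DP's clump candidates).
oracle_mic <- function(x, y, alpha = 0.6, c_param = 15) {
  n <- length(x)
  B <- max(floor(n^alpha), 4)
  one_side <- function(xv, yv) {
    best <- 0
    qmax <- floor(B / 2)
    if (qmax < 2) return(0)
    oy <- order(yv)
    for (q in 2:qmax) {
      lmax <- floor(B / q)
      if (lmax < 2) next
      ys <- yv[oy]
      grp <- cumsum(c(TRUE, ys[-1] != ys[-n]))
      bins <- chlorotex:::equipartition_groups(tabulate(grp), q)
      row_of <- integer(n); row_of[oy] <- bins[grp]
      q_act <- length(unique(row_of))
      if (q_act < 2) next
      ox <- order(xv); xs <- xv[ox]; rs <- row_of[ox]
      gaps <- which(xs[-1] != xs[-n])      # candidate boundaries after idx
      for (l in 2:min(lmax, length(gaps) + 1)) {
        cuts <- utils::combn(gaps, l - 1, simplify = FALSE)
        for (cut in cuts) {
          col_of <- findInterval(seq_len(n), cut + 1) + 1L
          tab <- table(col_of, rs)
          pj <- tab / n
          pi_ <- rowSums(pj); pr <- colSums(pj)
          mi <- 0
          for (a in seq_len(nrow(pj))) for (b in seq_len(ncol(pj)))
            if (pj[a, b] > 0)
              mi <- mi + pj[a, b] * log2(pj[a, b] / (pi_[a] * pr[b]))
          best <- max(best, mi / log2(min(l, q_act)))
        }
      }
    }
    best
  }
  max(one_side(x, y), one_side(y, x))
}

# Closed-form simple-regression coefficients via normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}
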