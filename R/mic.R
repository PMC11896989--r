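# Maximal information coefficient (MINE family, ApproxMaxMI estimator).
#
# The characteristic matrix entry for an nx x ny grid is the maximum mutual
# information over grids with that shape, normalized by log2(min(nx, ny)).
# One axis is equipartitioned; the other is optimized by dynamic programming
# over clump boundaries, with superclumps capping the candidate set at
# c * max_columns. MIC is the maximum entry over nx * ny <= B(n) = n^alpha,
# taken over both axis orientations.

# Greedy equipartition of ordered tie-groups into <= q bins of near-equal
# point mass; tie-groups are atomic. Returns bin assignment per (sorted) item.
equipartition_groups <- function(sizes, q) {
  n <- sum(sizes)
  assign <- integer(length(sizes))
  bin <- 1L; in_bin <- 0L; done <- 0L
  for (g in seq_along(sizes)) {
    remaining_bins <- q - bin + 1L
    target <- (n - done) / remaining_bins
    if (in_bin > 0L && remaining_bins > 1L &&
        abs(in_bin + sizes[g] - target) > abs(in_bin - target)) {
      bin <- bin + 1L; done <- done + in_bin; in_bin <- 0L
    }
    assign[g] <- bin
    in_bin <- in_bin + sizes[g]
  }
  assign
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Optimal column partitions over clump boundaries for a fixed row assignment.
# cum_rows: (k+1) x q matrix of cumulative per-row counts at clump ends
# (row 1 = zeros). Returns MI (bits, computed over all points) for each
# column count l = 2..lmax.
optimize_axis_dp <- function(cum_rows, lmax) {
  k <- nrow(cum_rows) - 1L
  n <- sum(cum_rows[k + 1L, ])
  ctot <- rowSums(cum_rows)            # points up to each clump end
  hq <- entropy_bits(cum_rows[k + 1L, ])
  # segment row-entropy cost: (c_t - c_s) * H(rows in (s, t])
  seg_cost <- function(s, t) {
    cnt <- cum_rows[t + 1L, ] - cum_rows[s + 1L, ]
    m <- sum(cnt)
    if (m == 0) return(0)
    m * entropy_bits(cnt)
  }
  if (k < 2L || lmax < 2L) return(numeric(0))
  lmax <- min(lmax, k)
  # g[t, l]: max over partitions of clumps 1..t into l columns of
  #          -sum_cols m_col * H(rows | col)
  g <- matrix(-Inf, k, lmax)
  for (t in seq_len(k)) g[t, 1L] <- -seg_cost(0L, t)
  for (l in 2:lmax) {
    for (t in l:k) {
      best <- -Inf
      for (s in (l - 1L):(t - 1L)) {
        v <- g[s, l - 1L] - seg_cost(s, t)
        if (v > best) best <- v
      }
      g[t, l] <- best
    }
  }
  vapply(2:lmax, function(l) hq + g[k, l] / n, numeric(1))
}

# Characteristic-matrix entries with rows = equipartitioned `yv`, columns
# optimized over `xv`. Returns max over l of I(l, q)/log2(min(l, q_actual))
# for each q, as a vector indexed by q = 2..floor(B/2).
mic_one_orientation <- function(xv, yv, B, c_param) {
  n <- length(xv)
  out <- 0
  qmax <- floor(B / 2)
  if (qmax < 2) return(0)
  oy <- order(yv)
  for (q in 2:qmax) {
    lmax <- floor(B / q)
    if (lmax < 2) next
    # rows: equipartition y tie-groups
    ys <- yv[oy]
    grp <- cumsum(c(TRUE, ys[-1] != ys[-n]))
    sizes <- tabulate(grp)
    bins <- equipartition_groups(sizes, q)
    row_of <- integer(n)
    row_of[oy] <- bins[grp]
    q_actual <- length(unique(row_of))
    if (q_actual < 2) next
    # clumps along x: atomic tie-groups, consecutive same-row groups merged
    ox <- order(xv)
    xs <- xv[ox]; rs <- row_of[ox]
    xgrp <- cumsum(c(TRUE, xs[-1] != xs[-n]))
    ng <- max(xgrp)
    grow <- vapply(seq_len(ng), function(i) {
      r <- unique(rs[xgrp == i]); if (length(r) == 1L) r else NA_integer_
    }, integer(1))
    gsize <- tabulate(xgrp, ng)
    new_clump <- rep(TRUE, ng)
    if (ng > 1L) {
      same <- !is.na(grow[-ng]) & !is.na(grow[-1]) & grow[-ng] == grow[-1]
      new_clump[-1][same] <- FALSE
    }
    clump_id <- cumsum(new_clump)
    k <- max(clump_id)
    # superclumps cap the DP size at c_param * lmax
    khat <- max(2L, floor(c_param * lmax))
    if (k > khat) {
      csize <- vapply(seq_len(k), function(i) sum(gsize[clump_id == i]),
                      numeric(1))
      sup <- equipartition_groups(csize, khat)
      clump_id <- sup[clump_id]
      k <- max(clump_id)
    }
    # cumulative per-row counts at clump ends
    point_clump <- clump_id[xgrp]          # per sorted-x point
    cum <- matrix(0L, k + 1L, q_actual)
    rows_f <- factor(rs, levels = sort(unique(rs)))
    tab <- table(factor(point_clump, levels = seq_len(k)), rows_f)
    cum[-1L, ] <- apply(tab, 2, cumsum)
    mi <- optimize_axis_dp(cum, lmax)
    if (length(mi)) {
      norm <- log2(pmin(2:(length(mi) + 1L), q_actual))
      out <- max(out, max(mi / norm))
    }
  }
  out
}

#' Maximal information coefficient
#'
#' MINE-family MIC statistic: the maximum, over grid shapes `nx * ny <=
#' n^alpha`, of mutual information normalized by `log2(min(nx, ny))`, with
#' one axis equipartitioned and the other optimized by dynamic programming
#' over clump boundaries (candidate set capped at `c * nx` superclumps).
#' Both orientations are searched. Captures linear and nonlinear association;
#' ranges 0 (independence) to 1 (noiseless functional relationship).
#'
#' @param x,y numeric vectors of equal length (n >= 10).
#' @param alpha grid-budget exponent, default 0.6.
#' @param c superclump factor, default 15.
#' @return MIC value in \[0, 1\].
#' @examples
#' x <- seq_len(20); mic(x, x)  # 1: noiseless functional relationship
#' @export
mic <- function(x, y, alpha = 0.6, c = 15) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("mic requires n >= 10 paired finite values", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: MIC is 0 by convention")
    return(0)
  }
  B <- max(floor(n^alpha), 4)
  max(mic_one_orientation(x, y, B, c),
      mic_one_orientation(y, x, B, c))
}
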