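#' Hartigans' dip statistic and bootstrap test of unimodality
#'
#' The dip of a sample is the maximum deviation of its empirical CDF from the
#' closest unimodal CDF, i.e. \eqn{D(F_n) = \min_U \sup_x |F_n(x) - U(x)|}
#' over all CDFs \eqn{U} that are convex up to some mode and concave beyond it.
#' Large dips indicate multimodality. The statistic is computed with the
#' iterative greatest-convex-minorant / least-concave-majorant algorithm of
#' Hartigan and Hartigan, working in rank ("count") units; the final value is
#' the count-scale discrepancy divided by \eqn{2n}.
#'
#' The p-value is obtained by a seeded parametric bootstrap under the uniform
#' null distribution, the asymptotically least favourable unimodal null: the
#' dip is location/scale invariant, so uniform(0,1) samples of the same size
#' serve as the reference.
#'
#' @param values numeric sample (at least 10 values for `dip_test`).
#' @param n_boot number of uniform-null bootstrap replicates.
#' @param seed integer seed for the bootstrap (local RNG, does not disturb the
#'   global stream).
#' @return `dip_stat` returns the dip statistic (a fraction in
#'   \eqn{[1/(2n), 1/4]}; 0 for constant samples). `dip_test` returns a list
#'   with elements `dip`, `p_value`, `n`, `n_boot`.
#' @examples
#' d <- dip_stat(c(rnorm(100, 0), rnorm(100, 6)))
#' @export
dip_stat <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 1L || anyNA(x)) stop("values must be non-empty and free of NA")
  if (n == 1L || x[n] == x[1L]) return(0)
  if (n < 4L) return(1 / (2 * n))
  low <- 1L
  high <- n
  dip <- 1 # count units; lower bound of the discrepancy
  repeat {
    gcm <- .hull_minorant(x, low, high) # descending indices: high .. low
    lcm <- .hull_majorant(x, low, high) # ascending indices:  low .. high
    lg <- length(gcm)
    ll <- length(lcm)
    # largest count-scale distance between the two hulls on [low, high]
    if (lg == 2L && ll == 2L) {
      d <- 1
      ig <- lg
      ih <- 1L
    } else {
      sc <- .hull_scan(x, gcm, lcm)
      d <- sc$d
      ig <- sc$ig
      ih <- sc$ih
    }
    if (d <= dip) break
    # deviations of the ECDF from each hull on the flanks outside the new
    # modal interval [gcm[ig], lcm[ih]]
    dl <- .gcm_flank_dip(x, gcm, ig)
    du <- .lcm_flank_dip(x, lcm, ih)
    dip <- max(dip, dl, du)
    new_low <- gcm[ig]
    new_high <- lcm[ih]
    if (new_low == low && new_high == high) break
    low <- new_low
    high <- new_high
  }
  dip / (2 * n)
}

#' @rdname dip_stat
#' @export
dip_test <- function(values, n_boot = 2000, seed = 1L) {
  x <- as.numeric(values)
  if (length(x) < 10L) stop("dip_test needs at least 10 values")
  d <- dip_stat(x)
  if (d == 0) {
    return(list(dip = 0, p_value = 1, n = length(x), n_boot = 0L))
  }
  n <- length(x)
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)), numeric(1))
  })
  p <- (1 + sum(boot >= d)) / (n_boot + 1)
  list(dip = d, p_value = p, n = n, n_boot = n_boot)
}

# Greatest convex minorant of the points (x[i], i), i in low..high.
# Returns touchpoint indices in descending order (high first, low last).
.hull_minorant <- function(x, low, high) {
  g <- integer(high - low + 1L)
  m <- 0L
  for (i in low:high) {
    while (m >= 2L) {
      a <- g[m - 1L]
      b <- g[m]
      # pop b if it lies on or above the chord a -> i
      if ((x[i] - x[a]) * (b - a) >= (x[b] - x[a]) * (i - a)) m <- m - 1L else break
    }
    m <- m + 1L
    g[m] <- i
  }
  rev(g[seq_len(m)])
}

# Least concave majorant; ascending order (low first, high last).
.hull_majorant <- function(x, low, high) {
  g <- integer(high - low + 1L)
  m <- 0L
  for (i in low:high) {
    while (m >= 2L) {
      a <- g[m - 1L]
      b <- g[m]
      # pop b if it lies on or below the chord a -> i
      if ((x[i] - x[a]) * (b - a) <= (x[b] - x[a]) * (i - a)) m <- m - 1L else break
    }
    m <- m + 1L
    g[m] <- i
  }
  g[seq_len(m)]
}

# Walk both hulls from low to high and find the largest count-scale distance
# between the LCM (above) and GCM (below), in the +1 convention that accounts
# for the ECDF jump at each sample point. Returns the hull indices (ig into
# gcm, ih into lcm) bounding the new candidate modal interval.
.hull_scan <- function(x, gcm, lcm) {
  lg <- length(gcm)
  ll <- length(lcm)
  d <- 0
  ig <- lg
  ih <- 1L
  ix <- lg - 1L
  iv <- 2L
  repeat {
    gx <- gcm[ix]
    lv <- lcm[iv]
    if (gx > lv) {
      # LCM vertex lv lies within GCM segment (gcm[ix+1], gcm[ix])
      a <- gcm[ix + 1L]
      b <- gx
      if (x[b] > x[a]) {
        line <- a + (x[lv] - x[a]) * (b - a) / (x[b] - x[a])
      } else {
        line <- a
      }
      dx <- lv - line + 1
      if (dx >= d) {
        d <- dx
        ig <- ix + 1L # gcm touchpoint at/below the argmax -> new low
        ih <- iv # the lcm vertex itself -> new high
      }
      iv <- iv + 1L
      if (iv > ll) iv <- ll
    } else {
      # GCM vertex gx lies within LCM segment (lcm[iv-1], lcm[iv])
      a <- lcm[iv - 1L]
      b <- lv
      if (x[b] > x[a]) {
        line <- a + (x[gx] - x[a]) * (b - a) / (x[b] - x[a])
      } else {
        line <- b
      }
      dx <- line - gx + 1
      if (dx >= d) {
        d <- dx
        ig <- ix # the gcm vertex itself -> new low
        ih <- iv # lcm touchpoint at/above the argmax -> new high
      }
      ix <- ix - 1L
      if (ix < 1L) ix <- 1L
    }
    if (gcm[ix] == lcm[iv] || (ix == 1L && iv == ll)) break
  }
  list(d = d, ig = ig, ih = ih)
}

# Max deviation of the ECDF above the GCM between hull vertices ig..end (the
# flank from the new low down to the current low), count units.
.gcm_flank_dip <- function(x, gcm, ig) {
  dl <- 0
  lg <- length(gcm)
  if (ig < lg) {
    for (i in ig:(lg - 1L)) {
      jb <- gcm[i + 1L]
      je <- gcm[i]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (j in jb:je) {
          t <- (j - jb + 1) - (x[j] - x[jb]) * C
          if (t > dl) dl <- t
        }
      }
    }
  }
  dl
}

# Max deviation of the ECDF below the LCM between hull vertices ih..end (the
# flank from the new high up to the current high), count units.
.lcm_flank_dip <- function(x, lcm, ih) {
  du <- 0
  ll <- length(lcm)
  if (ih < ll) {
    for (i in ih:(ll - 1L)) {
      jb <- lcm[i]
      je <- lcm[i + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (j in jb:je) {
          t <- (je - j + 1) - (x[je] - x[j]) * C
          if (t > du) du <- t
        }
      }
    }
  }
  du
}
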