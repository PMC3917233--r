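# LP oracle for the dip statistic, derived from the definition:
# dip(F) = min over unimodal CDFs U of sup |F - U|.
# For a sorted sample x[1..n], a U within sup-distance D must satisfy at each
# sample point:  i/n - D <= U(x_i) <= (i-1)/n + D  (step-function band),
# be nondecreasing, convex up to the mode, concave after.
# Modes: at each sample point k (convex on 1..k, concave on k..n), or inside
# an interval (k, k+1): convex on 1..k, concave on (k+1)..n, plus the junction
# requirement  u_{k+1} - u_k >= min(s_in, s_out) * (x_{k+1} - x_k)  where
# s_in = slope into x_k, s_out = slope out of x_{k+1} (the slope profile of a
# unimodal density is up-then-down, so its minimum over the modal gap is the
# smaller endpoint slope). The min() disjunction is handled by solving two LP
# variants. Minimal D per mode via boot::simplex; dip = min over modes.


dip_lp <- function(x) {
  x <- sort(as.numeric(x)); n <- length(x)
  if (x[n] == x[1]) return(0)
  # dip is affine-invariant; rescale for simplex conditioning
  x <- (x - x[1]) / (x[n] - x[1]) * n
  best <- Inf
  for (k in 1:n) best <- min(best, dip_lp_mode(x, k, k, 0L), na.rm = TRUE)
  if (n >= 2) for (k in 1:(n - 1)) {
    best <- min(best, dip_lp_mode(x, k, k + 1, 1L), na.rm = TRUE)
    best <- min(best, dip_lp_mode(x, k, k + 1, 2L), na.rm = TRUE)
  }
  best
}

# convex on 1..kc, concave on kk..n; junction 0 = none (kc==kk),
# 1 = rise >= s_in * dx, 2 = rise >= s_out * dx
dip_lp_mode <- function(x, kc, kk, junction) {
  n <- length(x)
  m <- n + 1 # variables u_1..u_n, D
  A1 <- NULL; b1 <- NULL   # A1 v <= b1
  A2 <- NULL; b2 <- NULL   # A2 v >= b2
  row <- function(cols, vals) { r <- numeric(m); r[cols] <- vals; r }
  for (i in 1:n) {
    A1 <- rbind(A1, row(c(i, m), c(1, -1))); b1 <- c(b1, (i - 1) / n)
    A2 <- rbind(A2, row(c(i, m), c(1, 1)));  b2 <- c(b2, i / n)
    A1 <- rbind(A1, row(i, 1)); b1 <- c(b1, 1)
  }
  if (n >= 2) for (i in 1:(n - 1)) {
    A2 <- rbind(A2, row(c(i + 1, i), c(1, -1))); b2 <- c(b2, 0)
  }
  if (kc >= 3) for (i in 2:(kc - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i + 1] - x[i]
    if (d1 == 0 || d2 == 0) next
    A2 <- rbind(A2, row(c(i + 1, i, i - 1), c(1 / d2, -1 / d2 - 1 / d1, 1 / d1)))
    b2 <- c(b2, 0)
  }
  if (kk <= n - 2) for (i in (kk + 1):(n - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i + 1] - x[i]
    if (d1 == 0 || d2 == 0) next
    A1 <- rbind(A1, row(c(i + 1, i, i - 1), c(1 / d2, -1 / d2 - 1 / d1, 1 / d1)))
    b1 <- c(b1, 0)
  }
  if (junction == 1L && kc >= 2) {
    dx <- x[kc + 1] - x[kc]; d1 <- x[kc] - x[kc - 1]
    if (d1 > 0) {
      # u_{k+1} - u_k - (dx/d1)(u_k - u_{k-1}) >= 0
      A2 <- rbind(A2, row(c(kc + 1, kc, kc - 1), c(1, -1 - dx / d1, dx / d1)))
      b2 <- c(b2, 0)
    }
  }
  if (junction == 2L && kk <= n - 1) {
    dx <- x[kk] - x[kk - 1]; d2 <- x[kk + 1] - x[kk]
    if (d2 > 0) {
      # u_{k+1} - u_k - (dx/d2)(u_{k+2} - u_{k+1}) >= 0
      A2 <- rbind(A2, row(c(kk, kk - 1, kk + 1), c(1 + dx / d2, -1, -dx / d2)))
      b2 <- c(b2, 0)
    }
  }
  obj <- numeric(m); obj[m] <- 1
  res <- try(boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2, maxi = FALSE),
             silent = TRUE)
  if (inherits(res, "try-error") || res$solved != 1) return(NA_real_)
  res$value
}
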