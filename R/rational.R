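# Exact fraction arithmetic for small integer matrices.
#
# Rank and null-space computation on stoichiometry matrices must be exact:
# the number of independent reaction cycles is a discrete model property and
# floating-point rank estimation is fragile near rank deficiency.  Matrices
# here are integer with modest entries, so numerators/denominators stay far
# below 2^53 and doubles carry the fractions exactly.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(gcd2, x)
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- mapply(gcd2, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

# Reduced row echelon form of an integer (or rational) matrix, exactly.
# Returns the rref numerator/denominator pair, pivot columns and rank.
rational_rref <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    nz <- which(num[row:nr, col] != 0)
    if (length(nz) == 0L) next
    p <- row + nz[1L] - 1L
    if (p != row) {
      num[c(row, p), ] <- num[c(p, row), ]
      den[c(row, p), ] <- den[c(p, row), ]
    }
    # scale pivot row to make the pivot 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    # eliminate the column from every other row
    for (i in seq_len(nr)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      # row_i <- row_i - (fn/fd) * row_row
      an <- num[i, ] * den[row, ] * fd - fn * num[row, ] * den[i, ]
      ad <- den[i, ] * den[row, ] * fd
      r <- rat_reduce(an, ad)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

rational_rank <- function(m) rational_rref(m)$rank

# Exact null-space basis of an integer matrix, one canonical integer vector
# per free column: rref with unit free-variable assignment, cleared to a
# common denominator, divided by the gcd, sign fixed so the first nonzero
# entry is positive.  N %*% b == 0 holds exactly for every column b.
rational_nullspace <- function(m) {
  m <- as.matrix(m)
  nc <- ncol(m)
  rr <- rational_rref(m)
  free <- setdiff(seq_len(nc), rr$pivots)
  basis <- matrix(0, nrow = nc, ncol = length(free))
  if (length(free) == 0L) return(basis)
  for (j in seq_along(free)) {
    fc <- free[j]
    v_num <- numeric(nc); v_den <- rep(1, nc)
    v_num[fc] <- 1
    if (length(rr$pivots) > 0L) {
      for (i in seq_along(rr$pivots)) {
        v_num[rr$pivots[i]] <- -rr$num[i, fc]
        v_den[rr$pivots[i]] <- rr$den[i, fc]
      }
    }
    # clear denominators to the least common multiple, then normalise
    L <- Reduce(function(a, b) a / gcd2(a, b) * b, v_den)
    v <- v_num * (L / v_den)
    v <- v / gcd_vec(v)
    fz <- which(v != 0)[1L]
    if (v[fz] < 0) v <- -v
    basis[, j] <- v
  }
  basis
}
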