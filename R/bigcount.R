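# Arbitrary-precision non-negative integer counts.
#
# Counts of 'could fit' trajectories routinely exceed 2^53, so layer counts
# are held exactly as little-endian limb vectors in base 1e6. A whole DP
# layer is a numeric matrix (vertices x limbs); propagation through a 0/1
# admissibility matrix is an ordinary matrix product (every partial sum is
# < 2^53, hence exact) followed by carry normalization.

BIG_BASE <- 1e6

#' Construct a big count from a non-negative integer scalar
#' @param x non-negative number below 2^53
#' @return numeric limb vector, little-endian base 1e6
#' @keywords internal
big_from_num <- function(x) {
  stopifnot(length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  limbs
}

big_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0) n <- n - 1L
  a[seq_len(n)]
}

#' @keywords internal
big_add <- function(a, b) {
  n <- max(length(a), length(b))
  s <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  big_carry(s)
}

# carry-normalize a limb vector whose entries may exceed the base
big_carry <- function(s) {
  repeat {
    carry <- s %/% BIG_BASE
    if (all(carry == 0)) break
    s <- s - carry * BIG_BASE
    s <- s + c(0, carry[-length(carry)])
    if (carry[length(carry)] > 0) s <- c(s, carry[length(carry)])
  }
  big_trim(s)
}

#' @keywords internal
big_mul <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  if (big_is_zero(a) || big_is_zero(b)) return(0)
  n <- length(a) + length(b)
  s <- numeric(n)
  # schoolbook convolution; limb products < 1e12, partial sums stay < 2^53
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    j <- seq_along(b)
    s[i + j - 1L] <- s[i + j - 1L] + a[i] * b[j]
    s <- big_carry_partial(s)
  }
  big_carry(s)
}

# keep magnitudes bounded during accumulation
big_carry_partial <- function(s) {
  carry <- s %/% BIG_BASE
  if (all(carry == 0)) return(s)
  s <- s - carry * BIG_BASE
  s + c(0, carry[-length(carry)])
}

#' @keywords internal
big_is_zero <- function(a) all(a == 0)

#' Compare two big counts: -1, 0, 1
#' @keywords internal
big_cmp <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

#' @keywords internal
big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

#' Decimal string form of a big count
#' @keywords internal
big_to_string <- function(a) {
  a <- big_trim(a)
  hi <- formatC(a[length(a)], format = "d")
  lo <- rev(a[-length(a)])
  if (length(lo)) {
    paste0(hi, paste(formatC(lo, width = 6, flag = "0", format = "d"), collapse = ""))
  } else hi
}

# ---- layer matrices -------------------------------------------------------

# counts for m vertices all equal to `val`
big_layer_init <- function(m, val = 1) {
  matrix(val, nrow = m, ncol = 1)
}

# propagate: counts at layer N = adm %*% counts at layer N-1, exactly.
# adm is 0/1 with rows = next-layer vertices, cols = previous-layer vertices.
big_layer_propagate <- function(adm, layer) {
  s <- adm %*% layer
  big_layer_carry(s)
}

big_layer_carry <- function(s) {
  repeat {
    carry <- floor(s / BIG_BASE)
    if (all(carry == 0)) break
    s <- s - carry * BIG_BASE
    ncol_s <- ncol(s)
    shifted <- cbind(0, carry[, -ncol_s, drop = FALSE])
    s <- s + shifted
    last <- carry[, ncol_s]
    if (any(last > 0)) s <- cbind(s, last) else NULL
  }
  # drop all-zero high limbs
  while (ncol(s) > 1L && all(s[, ncol(s)] == 0)) s <- s[, -ncol(s), drop = FALSE]
  s
}

# total of a layer: limb vector
big_layer_total <- function(layer) {
  big_carry(colSums(layer))
}

# row i of a layer as a limb vector
big_layer_row <- function(layer, i) big_trim(layer[i, ])
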