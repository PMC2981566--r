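#' @useDynLib tvorsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Continuous-time transfer function
#'
#' A minimal rational transfer-function container used by the block-model
#' simulators. Coefficients are stored in descending powers of s, as in
#' `signal::freqs` or MATLAB's `tf`.
#'
#' @param num numeric vector of numerator coefficients, descending powers of s.
#' @param den numeric vector of denominator coefficients, descending powers of
#'   s. The leading coefficient must be non-zero.
#' @return an object of class `lti_tf`.
#' @examples
#' intg <- lti_tf(1, c(1, 0))        # pure integrator 1/s
#' lp   <- lti_tf(1, c(0.25, 1))     # first-order lag, tc 0.25 s
#' lti_eval(lti_series(intg, lp), 2i * pi)
#' @export
lti_tf <- function(num, den) {
  num <- as.numeric(num); den <- as.numeric(den)
  if (!length(num) || !length(den) || anyNA(num) || anyNA(den))
    stop("num and den must be non-empty numeric vectors")
  den <- strip_lead(den)
  num <- strip_lead(num)
  if (length(den) == 0L || den[1] == 0)
    stop("denominator must have a non-zero leading coefficient")
  if (length(num) == 0L) num <- 0
  if (length(num) > length(den))
    stop("improper transfer function (numerator degree exceeds denominator)")
  structure(list(num = num, den = den), class = "lti_tf")
}

strip_lead <- function(p) {
  i <- which(p != 0)
  if (!length(i)) return(numeric(0))
  p[i[1]:length(p)]
}

#' @export
print.lti_tf <- function(x, ...) {
  cat("transfer function: num [", paste(signif(x$num, 6), collapse = " "),
      "] / den [", paste(signif(x$den, 6), collapse = " "), "]\n")
  invisible(x)
}

#' Series (cascade) connection of transfer functions
#'
#' @param ... `lti_tf` objects, or bare numerics treated as static gains.
#' @return an `lti_tf` for the product of the blocks.
#' @export
lti_series <- function(...) {
  blocks <- lapply(list(...), as_lti)
  num <- 1; den <- 1
  for (b in blocks) {
    num <- pracma::polymul(num, b$num)
    den <- pracma::polymul(den, b$den)
  }
  lti_tf(num, den)
}

#' Parallel (summing) connection of two transfer functions
#'
#' @param a,b `lti_tf` objects or static gains.
#' @return an `lti_tf` for `a + b`.
#' @export
lti_parallel <- function(a, b) {
  a <- as_lti(a); b <- as_lti(b)
  num <- polyadd(pracma::polymul(a$num, b$den), pracma::polymul(b$num, a$den))
  lti_tf(num, pracma::polymul(a$den, b$den))
}

as_lti <- function(x) {
  if (inherits(x, "lti_tf")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(lti_tf(x, 1))
  stop("not a transfer function or gain")
}

polyadd <- function(a, b) {
  n <- max(length(a), length(b))
  c(rep(0, n - length(a)), a) + c(rep(0, n - length(b)), b)
}

#' Evaluate a transfer function at complex frequencies
#'
#' @param sys an `lti_tf`.
#' @param s complex vector (typically `1i * 2 * pi * f`).
#' @return complex vector `H(s)`.
#' @export
lti_eval <- function(sys, s) {
  sys <- as_lti(sys)
  cpolyval(sys$num, s) / cpolyval(sys$den, s)
}

cpolyval <- function(p, s) {
  out <- rep(p[1] + 0i, length(s))
  if (length(p) > 1) for (k in 2:length(p)) out <- out * s + p[k]
  out
}

# Controllable-canonical state-space realization. Returns A, B and, for each
# numerator, a C row and D scalar, all sharing the same state.
lti_ss <- function(den, num_list) {
  den <- strip_lead(den)
  a <- den / den[1]
  n <- length(a) - 1L
  if (n == 0L) {  # static gains
    return(list(A = matrix(0, 0, 0), B = numeric(0),
                C = matrix(0, length(num_list), 0),
                D = vapply(num_list, function(b) sum(b) / den[1], 0)))
  }
  A <- rbind(-a[-1], cbind(diag(1, n - 1L, n - 1L), rep(0, n - 1L)))
  if (n == 1L) A <- matrix(-a[2], 1, 1)
  B <- c(1, rep(0, n - 1L))
  C <- matrix(0, length(num_list), n)
  D <- numeric(length(num_list))
  for (i in seq_along(num_list)) {
    b <- c(rep(0, n + 1L - length(num_list[[i]])), num_list[[i]]) / den[1]
    D[i] <- b[1]
    C[i, ] <- b[-1] - b[1] * a[-1]
  }
  list(A = A, B = B, C = C, D = D)
}

# Zero-order-hold discretization of (A, B) with step dt, via the matrix
# exponential of the augmented system (Matrix::expm: scaling-and-squaring
# with balancing, accurate to machine precision for these small matrices).
lti_c2d <- function(A, B, dt) {
  n <- length(B)
  if (n == 0L) return(list(Ad = A, Bd = B))
  M <- rbind(cbind(A, B), rep(0, n + 1L))
  E <- as.matrix(Matrix::expm(M * dt))
  list(Ad = E[seq_len(n), seq_len(n), drop = FALSE], Bd = E[seq_len(n), n + 1L])
}

# State-space realization of a single low-order block (companion form is
# well-conditioned at order <= 2, which is all a block ever needs here).
ss_block <- function(tf) {
  tf <- as_lti(tf)
  lti_ss(tf$den, list(tf$num))
}

# Series interconnection of two state-space systems (y1 feeds u2).
ss_series2 <- function(s1, s2) {
  n1 <- length(s1$B); n2 <- length(s2$B)
  if (n1 == 0L && n2 == 0L)
    return(list(A = matrix(0, 0, 0), B = numeric(0),
                C = matrix(0, 1, 0), D = s2$D * s1$D))
  A <- rbind(cbind(s1$A, matrix(0, n1, n2)),
             cbind(if (n2) s2$B %*% s1$C else matrix(0, 0, n1), s2$A))
  B <- c(s1$B, if (n2) s2$B * s1$D else numeric(0))
  C <- cbind(s2$D[1] * s1$C, s2$C)
  list(A = A, B = B, C = C, D = s2$D * s1$D)
}

# Combined state space of a cascade of transfer-function blocks. Keeping the
# blocks separate (rather than multiplying their polynomials into one
# companion form) keeps the realization well-scaled for stiff chains whose
# time constants span several orders of magnitude.
lti_chain_ss <- function(blocks) {
  Reduce(ss_series2, lapply(blocks, ss_block))
}

#' Fixed-step simulation of a cascade of transfer-function blocks
#'
#' Builds the series state-space interconnection of the blocks, discretizes
#' it once with a zero-order hold at step `dt`, and simulates in compiled
#' code. With `derivative = TRUE` a second output column carrying the time
#' derivative of the chain output is produced from the same state (the
#' chain must then be strictly proper).
#'
#' @param blocks list of `lti_tf` blocks (or static gains), input first.
#' @param u input samples on the uniform grid.
#' @param dt sample period, seconds.
#' @param derivative also return the derivative of the output.
#' @return numeric matrix with one (or two) columns.
#' @export
lti_simulate_chain <- function(blocks, u, dt, derivative = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  ss <- lti_chain_ss(blocks)
  if (length(ss$B) == 0L) {
    if (derivative) stop("derivative output needs a strictly proper chain")
    return(outer(as.numeric(u), ss$D))
  }
  C <- ss$C
  D <- ss$D
  if (derivative) {
    if (abs(D[1]) > 0) stop("derivative output needs a strictly proper chain")
    C <- rbind(C, ss$C %*% ss$A)
    D <- c(D, as.numeric(ss$C %*% ss$B))
  }
  d <- lti_c2d(ss$A, ss$B, dt)
  dss_sim(d$Ad, d$Bd, C, D, as.numeric(u))
}

#' Fixed-step simulation of transfer functions sharing one denominator
#'
#' Discretizes the common denominator's state-space realization with a
#' zero-order hold at step `dt` and runs the recursion in compiled code.
#' Using a single realization for the whole chain (rather than cascading
#' separately discretized blocks) keeps the discretization phase error at one
#' half sample across the chain.
#'
#' @param den common denominator polynomial (descending powers of s).
#' @param num_list list of numerator polynomials, one per output.
#' @param u input samples on the uniform grid.
#' @param dt sample period, seconds.
#' @return numeric matrix, one column per numerator.
#' @export
lti_simulate <- function(den, num_list, u, dt) {
  if (dt <= 0) stop("dt must be positive")
  ss <- lti_ss(den, num_list)
  if (length(ss$B) == 0L)
    return(outer(as.numeric(u), ss$D))
  d <- lti_c2d(ss$A, ss$B, dt)
  dss_sim(d$Ad, d$Bd, ss$C, ss$D, as.numeric(u))
}
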