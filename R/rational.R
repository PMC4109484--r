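# Exact rational arithmetic for fractional weights.
#
# Weights are products of reciprocals of small branching factors, so
# numerators and denominators stay far below 2^53 and can be held exactly
# in doubles. All arithmetic reduces by gcd after every operation; equality
# is therefore a plain identity test, never a tolerance test.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Exact rational number
#'
#' Constructs a reduced rational number used for fractional concept weights.
#' Arithmetic (`+`, `-`, `*`, `/`), comparison and equality are exact; no
#' floating tolerance is involved, so a sum-to-one check on tree weights is
#' a true identity test.
#'
#' @param num integer-valued numerator (may be a double holding an integer).
#' @param den integer-valued denominator, non-zero.
#' @return An object of class `rational` with fields `num` and `den`
#'   (`den > 0`, `gcd(num, den) == 1`).
#' @examples
#' rational(1, 3) + rational(1, 3) + rational(1, 3) == rational(1)
#' format(rational(1, 30))  # "0.033"
#' @export
rational <- function(num, den = 1) {
  stopifnot(length(num) == 1, length(den) == 1, is.finite(num), is.finite(den))
  if (den == 0) stop("rational: zero denominator")
  if (num != trunc(num) || den != trunc(den)) {
    stop("rational: numerator and denominator must be integer-valued")
  }
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- gcd2(num, den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  structure(list(num = num, den = den), class = "rational")
}

is_rational <- function(x) inherits(x, "rational")

as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x) && length(x) == 1 && x == trunc(x)) return(rational(x))
  stop("cannot coerce to rational: ", deparse(substitute(x)))
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational")
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  switch(.Generic,
    "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = rational(a$num * b$num, a$den * b$den),
    "/" = {
      if (b$num == 0) stop("rational: division by zero")
      rational(a$num * b$den, a$den * b$num)
    },
    "==" = a$num == b$num && a$den == b$den,
    "!=" = !(a$num == b$num && a$den == b$den),
    "<"  = a$num * b$den < b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den > b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rational")
  )
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  paste0(if (x$den == 1) as.character(x$num) else paste0(x$num, "/", x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), " (", weight_display(x), ")\n", sep = "")
  invisible(x)
}

rat_sum <- function(xs) Reduce(`+`, xs, rational(0))

#' Display form of a fractional weight
#'
#' Weights are held exactly; published tables print them rounded to three
#' decimals (1/3 prints as 0.333, 1/30 as 0.033). This helper produces that
#' display form.
#'
#' @param x a `rational` or a plain numeric value.
#' @return A character scalar with three decimal places.
#' @export
weight_display <- function(x) {
  v <- if (is_rational(x)) x$num / x$den else x
  sprintf("%.3f", v)
}
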