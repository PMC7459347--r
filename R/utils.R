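# internal numerical helpers

#' Numerically stable log(sum(exp(x)))
#'
#' Max-shifted so that long products accumulated in log space can be
#' summed without overflow/underflow.
#' @noRd
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' log(exp(a) + exp(b)) for scalars
#' @noRd
logaddexp <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a "start:stop:steps" axis specification into a numeric vector
#' @noRd
parse_axis <- function(spec) {
  if (is.numeric(spec)) return(as.numeric(spec))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(as.numeric(parts))
  if (length(parts) != 3L)
    stop("axis specification must be a number or 'start:stop:steps', got '",
         spec, "'", call. = FALSE)
  vals <- as.numeric(parts)
  if (anyNA(vals) || vals[3] < 1) stop("invalid axis '", spec, "'", call. = FALSE)
  seq(vals[1], vals[2], length.out = as.integer(vals[3]))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop("'", name, "' = ", x, " is outside its valid range", call. = FALSE)
  invisible(as.numeric(x))
}
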