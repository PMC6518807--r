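#' Round half away from zero to integer percent
#'
#' Commercial ("half-up") rounding, used for all printed percentage tables;
#' base `round()` rounds half to even and does not reproduce conventional
#' clinical-table percentages.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(36.76, 62.5, 45.09))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# shared argument checks -----------------------------------------------------

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(x >= if (allow_zero) 0 else .Machine$double.xmin) &&
    all(x <= if (allow_one) 1 else 1 - 1e-12)
  if (!ok) {
    abort(sprintf("`%s` must be a probability in [0,1].", name))
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    abort(sprintf("`%s` must contain non-negative integer counts.", name))
  }
  invisible(x)
}

check_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

# seeds ----------------------------------------------------------------------

# Derive a reproducible child seed from a base seed and a stream label,
# keeping it inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- vapply(utf8ToInt(as.character(stream)), identity, numeric(1))
  as.integer((seed + sum(offsets * seq_along(offsets) * 1009)) %% .Machine$integer.max)
}
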