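#' Convert between A1-style well labels and numeric grid positions
#'
#' Plate positions are labelled the way screening labs label them: letters
#' index rows (`A`, `B`, ..., `Z`, `AA`, ...) and numbers index columns, so
#' the top-left well of a plate is `A1`. Internally the package uses 1-based
#' integer `(row, col)` pairs.
#'
#' @param row,col Integer vectors of 1-based row and column indices.
#' @return `pos_to_label()` returns a character vector of labels;
#'   `label_to_pos()` returns a data.frame with integer columns `row`, `col`.
#' @examples
#' pos_to_label(1, 1)        # "A1"
#' pos_to_label(27, 12)      # "AA12"
#' label_to_pos(c("A1", "H12"))
#' @export
pos_to_label <- function(row, col) {
  if (any(row < 1L) || any(col < 1L)) {
    ps_abort("grid positions are 1-based; row and col must be >= 1",
             "value_error")
  }
  letters_for <- function(r) {
    out <- ""
    while (r > 0L) {
      rem <- (r - 1L) %% 26L
      out <- paste0(LETTERS[rem + 1L], out)
      r <- (r - 1L) %/% 26L
    }
    out
  }
  paste0(vapply(as.integer(row), letters_for, character(1)), as.integer(col))
}

#' @rdname pos_to_label
#' @param label Character vector of A1-style labels.
#' @export
label_to_pos <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    ps_abort(sprintf("malformed position label(s): %s",
                     paste(label[bad], collapse = ", ")), "parse_error")
  }
  row <- vapply(m, function(x) {
    ch <- strsplit(toupper(x[2]), "")[[1]]
    sum((match(ch, LETTERS)) * 26L^(rev(seq_along(ch)) - 1L))
  }, numeric(1))
  data.frame(row = as.integer(row),
             col = as.integer(vapply(m, function(x) as.integer(x[3]),
                                     integer(1))))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All generators in the package funnel randomness through this.
with_seed <- function(seed, expr) {
  check_scalar_number(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

# Lognormal multiplicative noise factors with mean exactly 1 and the given
# coefficient of variation. cv = 0 returns exact ones.
lognormal_noise <- function(n, cv) {
  if (cv < 0) ps_abort("noise_cv must be >= 0", "config_error")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
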