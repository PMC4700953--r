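# internal helpers shared across modules

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# positions must be sorted within each chromosome for window arithmetic
assert_sorted_positions <- function(pos, chrom = NULL) {
  if (is.null(chrom)) {
    if (is.unsorted(pos)) abort("positions must be sorted in increasing order")
  } else {
    bad <- tapply(pos, chrom, is.unsorted)
    if (any(unlist(bad))) abort("positions must be sorted within each chromosome")
  }
  invisible(pos)
}

new_drop_log <- function() tibble(reason = character(), n = integer())

add_drop <- function(log, reason, n) {
  if (n > 0) log <- dplyr::bind_rows(log, tibble(reason = reason, n = as.integer(n)))
  log
}
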