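# Shared internal helpers.

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero ("half-up" on
#' positive values), matching how the source tables render percentages
#' (e.g. 34.955 -> 34.96). Base `round()` uses banker's rounding and would
#' disagree on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) == 2
#' round_half_up(34.955, 2)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # nudge by a few ulps so values that are exactly .5 in decimal but stored
  # fractionally below it in binary still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a TSV with a mandatory header; trims UTF-8 BOM
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  names(df) <- sub("^﻿", "", names(df))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# consistent percentage on the 0-100 scale; rendering via round_half_up
pct_render <- function(count, total, decimals) {
  round_half_up(100 * count / total, decimals)
}
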