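#' Frequency band schemes for relative band power
#'
#' Returns one of the two supported band schemes. The `"modified"` scheme
#' splits the classical alpha-to-beta range at 16 and 24 Hz, introducing the
#' intermediate "Zaeta" band (16-24 Hz) and a narrowed Beta (24-30 Hz); the
#' `"standard"` scheme is the classical five-band layout. All bands are
#' half-open `[lo, hi)` except the last (Gamma), whose upper edge is
#' inclusive, so either scheme exactly partitions the 0.5-45 Hz analysis
#' range.
#'
#' @param name `"modified"` (six bands, the default) or `"standard"`
#'   (five bands).
#' @return An object of class `band_scheme`: a data frame with columns
#'   `band`, `lo`, `hi`, `hi_inclusive`, and attributes `total_lo`,
#'   `total_hi` giving the analysis range.
#' @examples
#' band_scheme("modified")
#' @export
band_scheme <- function(name = c("modified", "standard")) {
  name <- match.arg(name)
  if (name == "modified") {
    df <- data.frame(
      band = c("Delta", "Theta", "Alpha", "Zaeta", "Beta", "Gamma"),
      lo = c(0.5, 4, 8, 16, 24, 30),
      hi = c(4, 8, 16, 24, 30, 45),
      hi_inclusive = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(
      band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
      lo = c(0.5, 4, 8, 13, 25),
      hi = c(4, 8, 13, 25, 45),
      hi_inclusive = c(FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  as_band_scheme(df, total_lo = 0.5, total_hi = 45)
}

#' Build a custom band scheme
#'
#' @param df data frame with columns `band`, `lo`, `hi` and optionally
#'   `hi_inclusive` (defaults to inclusive only for the last band).
#' @param total_lo,total_hi analysis range in Hz used as the denominator of
#'   relative band power.
#' @return A `band_scheme` object.
#' @export
as_band_scheme <- function(df, total_lo = 0.5, total_hi = 45) {
  stopifnot(is.data.frame(df), all(c("band", "lo", "hi") %in% names(df)))
  if (is.null(df$hi_inclusive)) {
    df$hi_inclusive <- c(rep(FALSE, nrow(df) - 1L), TRUE)
  }
  if (any(df$lo >= df$hi)) {
    stop("each band must satisfy lo < hi")
  }
  if (is.unsorted(df$lo, strictly = TRUE)) {
    stop("bands must be sorted by ascending lower edge")
  }
  if (nrow(df) > 1L && any(df$hi[-nrow(df)] > df$lo[-1L] + 1e-12)) {
    stop("bands must not overlap")
  }
  if (anyDuplicated(df$band)) stop("band names must be unique")
  structure(df,
    total_lo = total_lo, total_hi = total_hi,
    class = c("band_scheme", "data.frame")
  )
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf(
    "Band scheme: %d bands over [%g, %g] Hz\n",
    nrow(x), attr(x, "total_lo"), attr(x, "total_hi")
  ))
  edges <- sprintf(
    "  %-6s [%g, %g%s", x$band, x$lo, x$hi,
    ifelse(x$hi_inclusive, "]", ")")
  )
  cat(edges, sep = "\n")
  invisible(x)
}
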