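#' Parse 384-well plate addresses
#'
#' Converts well addresses of the form `"A1"`..`"P24"` (row letter A-P,
#' 1-based column 1-24, no zero padding) to 0-based row/column indices.
#' Parsing is case-insensitive and whitespace-tolerant; the canonical form
#' is upper case without padding, so `format_well(parse_well(x))`
#' canonicalizes any accepted spelling.
#'
#' @param well character vector of well addresses.
#' @return A data frame with integer columns `row` (0-15) and `col` (0-23).
#' @examples
#' parse_well(c("A1", "p24"))
#' @export
parse_well <- function(well) {
  x <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", x)
  if (any(!ok)) {
    stop("malformed well address(es) for a 16x24 plate: ",
         paste(unique(well[!ok]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    row = match(substr(x, 1L, 1L), LETTERS[1:16]) - 1L,
    col = as.integer(substring(x, 2L)) - 1L
  )
}

#' Format 0-based row/column indices as well addresses
#'
#' @param row integer vector, 0-15.
#' @param col integer vector, 0-23.
#' @return Character vector of canonical addresses (`"A1"`..`"P24"`).
#' @export
format_well <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row > 15L) || any(col < 0L | col > 23L)) {
    stop("row must be in 0..15 and col in 0..23", call. = FALSE)
  }
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Identify edge wells (outermost ring) of a 384-well plate
#'
#' @param well character vector of well addresses.
#' @return Logical vector, `TRUE` for wells in row A or P or column 1 or 24.
#' @export
is_edge_well <- function(well) {
  p <- parse_well(well)
  p$row == 0L | p$row == 15L | p$col == 0L | p$col == 23L
}

canonical_well <- function(well) {
  p <- parse_well(well)
  format_well(p$row, p$col)
}

all_wells_row_major <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}
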