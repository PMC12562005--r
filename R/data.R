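#' Built-in lifetime data sets
#'
#' Two classical complete (uncensored) samples used throughout the
#' package documentation and tests:
#' \describe{
#' \item{\code{"metal_fatigue"}}{Fatigue life of 46 metal components, in
#'   cycles to failure (125 to 5046).}
#' \item{\code{"head_neck_cancer"}}{Survival times of 44 head-and-neck
#'   cancer patients (12.20 to 1776).  Stored in its recorded order,
#'   which is not fully sorted (78.26 precedes 74.74); estimation sorts
#'   internally where needed.}
#' }
#' Values are stored verbatim as printed-text fixtures under
#' \code{inst/extdata} and parsed on load, so no re-rounding occurs.
#'
#' @param key data set name, \code{"metal_fatigue"} or
#'   \code{"head_neck_cancer"}.
#' @return A numeric vector of strictly positive lifetimes, in recorded
#'   order.
#' @examples
#' length(tiwd_data("metal_fatigue"))     # 46
#' head(tiwd_data("head_neck_cancer"))
#' @export
tiwd_data <- function(key = c("metal_fatigue", "head_neck_cancer")) {
  key <- match.arg(key)
  path <- system.file("extdata", paste0(key, ".txt"), package = "tiwd",
                      mustWork = TRUE)
  read_lifetime_sample(path)
}

#' Read a lifetime sample from a text or CSV file
#'
#' Accepts either one strictly positive value per line, or a CSV file
#' with a header from which one numeric column is taken.  Nonpositive,
#' missing, or unparsable values are rejected with the offending row
#' index.
#'
#' @param path path to the file.
#' @param column optional column name for CSV input; when \code{NULL} and
#'   the file parses as CSV with a single numeric column, that column is
#'   used.
#' @return A numeric vector in file order.
#' @export
read_lifetime_sample <- function(path, column = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  is_csv <- grepl(",", lines[1]) ||
    (!is.null(column) || is.na(suppressWarnings(as.numeric(lines[1]))))
  if (is_csv) {
    df <- read.csv(path)
    if (is.null(column)) {
      num <- names(df)[vapply(df, is.numeric, logical(1L))]
      if (length(num) != 1L) {
        stop("CSV has ", length(num), " numeric columns; give 'column'",
             call. = FALSE)
      }
      column <- num
    }
    if (!column %in% names(df)) {
      stop("no column named '", column, "' in ", path, call. = FALSE)
    }
    x <- df[[column]]
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad)) {
      stop("nonpositive or missing value at row ", bad[1], " of column '",
           column, "'", call. = FALSE)
    }
    return(as.numeric(x))
  }
  x <- suppressWarnings(as.numeric(trimws(lines)))
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop("nonpositive or unparsable value at row ", bad[1], " ('",
         lines[bad[1]], "')", call. = FALSE)
  }
  x
}
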