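#' Read a species elevational-range table
#'
#' CSV with header `species,min_elev,max_elev` (supplementary-table shape).
#' Rows whose limits are missing, non-numeric, or inverted
#' (`min_elev > max_elev`) are rejected with a warning listing their line
#' numbers; duplicate species identifiers are an error.
#'
#' @param path CSV file path.
#' @return Data frame `species`, `min_elev`, `max_elev`.
#' @export
read_ranges <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "min_elev", "max_elev")
  if (!all(required %in% names(tab))) {
    stop("ranges CSV must have columns: ", paste(required, collapse = ", "))
  }
  tab$min_elev <- suppressWarnings(as.numeric(tab$min_elev))
  tab$max_elev <- suppressWarnings(as.numeric(tab$max_elev))
  bad <- is.na(tab$min_elev) | is.na(tab$max_elev) |
    tab$min_elev > tab$max_elev
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (anyDuplicated(tab$species)) {
    stop("duplicate species in ranges: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  }
  if (nrow(tab) == 0) warning("ranges table is empty")
  rownames(tab) <- NULL
  tab[required]
}

#' Read an occurrence-point table
#'
#' CSV with header `species,x,y`, coordinates in the analysis CRS (m).
#' Malformed rows are rejected with a warning listing their line numbers.
#'
#' @param path CSV file path.
#' @return Data frame `species`, `x`, `y`.
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "x", "y")
  if (!all(required %in% names(tab))) {
    stop("occurrences CSV must have columns: ", paste(required, collapse = ", "))
  }
  tab$x <- suppressWarnings(as.numeric(tab$x))
  tab$y <- suppressWarnings(as.numeric(tab$y))
  bad <- is.na(tab$x) | is.na(tab$y) | is.na(tab$species) | tab$species == ""
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0) warning("occurrence table is empty")
  rownames(tab) <- NULL
  tab[required]
}
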