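#' Read a NONMEM-style longitudinal PK dataset
#'
#' Headered CSV with at least `ID` and `TIME` plus `DV` or `AMT`; missing
#' `DV` written as `"."`. Missing conventional columns are reconstructed:
#' `EVID` from `AMT > 0`, `MDV` from missing `DV`, `DUR`/`WT`/`DAY` filled
#' with defaults. Unknown columns are preserved. Within each subject,
#' `TIME` must be non-decreasing.
#'
#' @param path CSV file path
#' @return a `pk_dataset` tibble
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c(".", "NA", ""))
  need <- c("ID", "TIME")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_pk_dataset: missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!any(c("DV", "AMT") %in% names(df)))
    stop("read_pk_dataset: need at least one of DV or AMT")
  if (!"AMT" %in% names(df)) df$AMT <- 0
  if (!"DV" %in% names(df)) df$DV <- NA_real_
  if (!"EVID" %in% names(df)) df$EVID <- as.integer(df$AMT > 0)
  if (!"MDV" %in% names(df)) df$MDV <- as.integer(is.na(df$DV))
  if (!"DUR" %in% names(df)) df$DUR <- 0
  if (!"WT" %in% names(df)) df$WT <- NA_real_
  if (!"DAY" %in% names(df)) df$DAY <- NA_integer_
  for (id in unique(df$ID)) {
    tt <- df$TIME[df$ID == id]
    if (is.unsorted(tt)) stop("read_pk_dataset: non-monotone TIME in subject ", id)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("pk_dataset", class(out))
  out
}

#' Write a PK dataset as CSV
#'
#' Missing `DV` is written as `"."`; times carry 6 decimal places so the
#' write/read round trip is exact on the canonical columns.
#'
#' @param data a `pk_dataset` tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pk_dataset <- function(data, path) {
  df <- as.data.frame(data)
  fmt1 <- function(x) {
    if (is.na(x)) return(".")
    if (x == round(x)) return(format(x, scientific = FALSE, trim = TRUE))
    sprintf("%.6f", x)
  }
  num <- vapply(df, is.numeric, TRUE)
  for (nm in names(df)[num]) {
    df[[nm]] <- vapply(df[[nm]], fmt1, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
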