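#' Validate the panel schema
#'
#' Checks the documented one-row-per-person layout: required baseline
#' columns, yearly blocks with 4-digit calendar-year suffixes, valid
#' treatment levels, monotone non-increasing observation flags and monotone
#' non-decreasing event flags.
#'
#' @param panel A data frame in panel layout.
#' @return The panel, invisibly, with class `perio_panel` and year attributes
#'   set. Errors name the offending columns.
#' @export
validate_panel <- function(panel) {
  base_cols <- c("id", "sex", "origin", "educ", "region",
                 "hist_restorations", "hist_extractions", "hist_years_supra",
                 "hist_years_sub", "hist_years_surgery", "hist_years_exam",
                 "hist_years_endo", "hist_years_prevention",
                 "hist_years_radiograph", "hist_income_sum")
  missing_base <- setdiff(base_cols, names(panel))
  if (length(missing_base)) {
    stop(sprintf("panel is missing required column(s): %s",
                 paste(missing_base, collapse = ", ")), call. = FALSE)
  }
  oyears <- sort(as.integer(sub("^O_", "", grep("^O_\\d{4}$", names(panel), value = TRUE))))
  if (length(oyears) < 2L) {
    stop("panel is missing yearly observation columns O_<year>", call. = FALSE)
  }
  years <- oyears
  tau <- length(years) - 1L
  xcols <- paste0("X_", years[seq_len(tau)])
  missing_x <- setdiff(xcols, names(panel))
  if (length(missing_x)) {
    stop(sprintf("panel is missing treatment column(s): %s",
                 paste(missing_x, collapse = ", ")), call. = FALSE)
  }
  ycols <- paste0("Y_", years[-1])
  missing_y <- setdiff(ycols, names(panel))
  if (length(missing_y)) {
    stop(sprintf("panel is missing event column(s): %s",
                 paste(missing_y, collapse = ", ")), call. = FALSE)
  }
  if (nrow(panel)) {
    X <- as.matrix(panel[xcols])
    bad <- !is.na(X) & !(X %in% treatment_levels())
    if (any(bad)) {
      stop(sprintf("invalid treatment levels in column(s): %s",
                   paste(unique(xcols[col(bad)[bad]]), collapse = ", ")),
           call. = FALSE)
    }
    O <- as.matrix(panel[paste0("O_", years)])
    if (any(apply(O, 1L, function(o) any(diff(o) > 0L)))) {
      stop("observation flags O_<year> are not monotone non-increasing",
           call. = FALSE)
    }
    Y <- as.matrix(panel[ycols])
    nonmono <- apply(Y, 1L, function(y) {
      y <- y[!is.na(y)]
      length(y) > 1L && any(diff(y) < 0L)
    })
    if (any(nonmono)) {
      stop("event flags Y_<year> are not monotone non-decreasing",
           call. = FALSE)
    }
  }
  class(panel) <- unique(c("perio_panel", class(panel)))
  attr(panel, "years") <- years
  attr(panel, "n_treatment_years") <- tau
  invisible(panel)
}

panel_years <- function(panel) {
  attr(panel, "years") %||%
    sort(as.integer(sub("^O_", "", grep("^O_\\d{4}$", names(panel), value = TRUE))))
}

#' Write a panel to CSV
#'
#' One row per person; header row; block prefixes `L_`/`X_`/`W_`/`O_`/`Y_`
#' with 4-digit calendar-year suffixes; treatment as `NONE`/`SUPRA`/`SUB`
#' strings. The round trip through [read_panel()] is lossless.
#'
#' @param panel A validated panel.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a panel from CSV
#'
#' @param path CSV file written by [write_panel()] (or following the same
#'   layout). Malformed headers and schema violations raise errors naming the
#'   offending columns.
#' @return A validated panel of class `perio_panel`.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  out <- validate_panel(panel)
  class(out) <- c("perio_panel", "data.frame")
  out
}

#' @export
print.perio_panel <- function(x, ...) {
  years <- panel_years(x)
  cat(sprintf("<perio_panel> %d persons, calendar years %d-%d (%d treatment years)\n",
              nrow(x), min(years), max(years), length(years) - 1L))
  invisible(x)
}
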