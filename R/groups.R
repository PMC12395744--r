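#' Ancestry groups used for PRS tailoring
#'
#' The PRS is tailored to four major self-reported race/ethnicity groups.
#' Hispanic ethnicity dominates race; participants of Asian, Native Hawaiian
#' or Pacific Islander race map to `"nh_asian"`; Black participants to
#' `"nh_black"`; everyone else (White, Native American, other, mixed race, or
#' unknown race) falls back to `"nh_white"` parameters because genome-wide
#' association data are too sparse in those groups to fit separate scores.
#'
#' @return Character vector of the four group labels, in canonical order.
#' @export
prs_groups <- function() {
  c("nh_asian", "nh_black", "hispanic", "nh_white")
}

# race vocabulary -> PRS group for non-Hispanic participants
.race_to_group <- c(
  asian                         = "nh_asian",
  native_hawaiian               = "nh_asian",
  pacific_islander              = "nh_asian",
  black                         = "nh_black",
  white                         = "nh_white",
  american_indian_alaska_native = "nh_white",
  native_american               = "nh_white",
  other                         = "nh_white",
  mixed                         = "nh_white",
  unknown                       = "nh_white"
)

#' Route self-reported race/ethnicity to a PRS parameter group
#'
#' @param race Character vector of self-reported race labels. Recognised
#'   values: `"asian"`, `"native_hawaiian"`, `"pacific_islander"`, `"black"`,
#'   `"white"`, `"american_indian_alaska_native"` (or `"native_american"`),
#'   `"other"`, `"mixed"`, `"unknown"`. `NA` is treated as `"unknown"`.
#' @param hispanic Logical vector: any indication of Hispanic ethnicity routes
#'   to the `"hispanic"` group regardless of race; `NA` is treated as
#'   non-Hispanic.
#' @return Character vector of group labels from [prs_groups()].
#' @examples
#' assign_prs_group("black", hispanic = TRUE)   # "hispanic"
#' assign_prs_group("unknown", hispanic = FALSE) # "nh_white"
#' @export
assign_prs_group <- function(race, hispanic) {
  race <- tolower(as.character(race))
  race[is.na(race)] <- "unknown"
  hispanic <- as.logical(hispanic)
  hispanic[is.na(hispanic)] <- FALSE
  if (length(hispanic) == 1L) hispanic <- rep(hispanic, length(race))
  stopifnot(length(race) == length(hispanic))

  out <- unname(.race_to_group[race])
  bad <- is.na(out) & !hispanic
  if (any(bad)) {
    stop("unrecognized race label(s) for non-Hispanic participant(s): ",
         paste(unique(race[bad]), collapse = ", "))
  }
  out[hispanic] <- "hispanic"
  out
}
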