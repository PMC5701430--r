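#' Segmentation configuration
#'
#' Bundles the tunable parameters of the segmentation rules.
#'
#' @param index_year Calendar year whose service users form the cohort and
#'   whose admissions drive the frequent-admitter split.
#' @param lookback_years Number of calendar years (including the index year)
#'   scanned for chronic-condition codes.  Default 5: index years 2008-2012
#'   for index year 2012.
#' @param frequent_admission_threshold Minimum number of merged inpatient
#'   episodes in the index year that makes a complex-chronic patient a
#'   frequent admitter.  Default 3.
#' @param min_age Minimum age in completed years at 1 January of the index
#'   year.  Default 21 (adult population).
#' @param precedence Character vector: the six segment labels in the order
#'   the assignment rules are tried; the first rule that matches wins.
#'   The default runs end_of_life, complex_freq, complex_no_freq,
#'   serious_acute, stable_chronic, mostly_healthy.
#' @param serious_acute_includes_ed If `TRUE`, an index-year ED visit (not
#'   only an inpatient admission) can place a patient without complex disease
#'   in the serious-acute segment.  Default `FALSE` (admission-based).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(index_year = 2012,
                                lookback_years = 5,
                                frequent_admission_threshold = 3,
                                min_age = 21,
                                precedence = default_precedence(),
                                serious_acute_includes_ed = FALSE) {
  stopifnot(is.numeric(index_year), length(index_year) == 1)
  if (lookback_years < 1) abort("lookback_years must be >= 1")
  if (frequent_admission_threshold < 1) {
    abort("frequent_admission_threshold must be >= 1")
  }
  if (!setequal(precedence, segment_levels()) ||
      length(precedence) != length(segment_levels())) {
    abort("precedence must be a permutation of the six segment labels")
  }
  structure(list(index_year = as.integer(index_year),
                 lookback_years = as.integer(lookback_years),
                 frequent_admission_threshold =
                   as.integer(frequent_admission_threshold),
                 min_age = as.integer(min_age),
                 precedence = precedence,
                 serious_acute_includes_ed =
                   isTRUE(serious_acute_includes_ed)),
            class = "segmentation_config")
}

#' Read / write a segmentation config as JSON
#'
#' @param path File path.
#' @param config A `segmentation_config`.
#' @return `read_segmentation_config()` returns a validated
#'   `segmentation_config`; `write_segmentation_config()` returns `path`
#'   invisibly.
#' @export
read_segmentation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- segmentation_config()
  args <- utils::modifyList(unclass(defaults), raw[names(raw) %in%
                                                    names(defaults)])
  do.call(segmentation_config, args)
}

#' @rdname read_segmentation_config
#' @export
write_segmentation_config <- function(config, path) {
  stopifnot(inherits(config, "segmentation_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_config> index year %d, %d-year look-back, ",
                     "frequent-admitter threshold %d, min age %d\n"),
              x$index_year, x$lookback_years, x$frequent_admission_threshold,
              x$min_age))
  invisible(x)
}
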