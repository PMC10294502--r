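# Condition vocabularies: 30 raw KHPS chronic-condition codes, the 14 grouped
# disease categories, and the 15-condition analysis vocabulary (14 groups +
# BMI-derived obesity).

#' @keywords internal
grouped_condition_codes <- c(
  "hypertension",
  "diabetes",
  "chronic_liver_disease",
  "gonarthrosis",
  "arthritis",
  "spondylosis",
  "cancer",
  "cardiovascular_disease",
  "cerebrovascular_disease",
  "chronic_respiratory_disease",
  "thyroid_disease",
  "depression",
  "alzheimers_disease",
  "chronic_renal_failure"
)

#' The chronic-condition vocabulary used for profile building and mining
#'
#' Fourteen grouped chronic-disease categories derived from the 30 raw
#' KHPS condition codes, optionally extended with `"obesity"` (defined from
#' BMI) to give the 15-condition analysis vocabulary.
#'
#' @param include_obesity Include the BMI-derived `"obesity"` condition
#'   (default `TRUE`, giving 15 conditions).
#' @return Character vector of condition codes.
#' @export
#' @examples
#' condition_vocabulary()
condition_vocabulary <- function(include_obesity = TRUE) {
  c(grouped_condition_codes, if (include_obesity) "obesity")
}

#' Raw KHPS condition codes
#'
#' The 30 raw chronic-condition codes recorded in the source survey, each of
#' which maps onto one of the 14 grouped categories (see
#' [khps_grouping_map()]).
#'
#' @return Character vector of 30 raw condition codes.
#' @export
raw_condition_codes <- function() {
  names(khps_grouping_map())
}

#' Mapping from raw KHPS condition codes to grouped disease categories
#'
#' Reads the grouping resource shipped with the package (an editable YAML
#' file, `extdata/khps_grouping.yaml`) mapping each of the 30 raw condition
#' codes to one of 14 grouped categories, e.g. chronic hepatitis, alcoholic
#' hepatitis and hepatic cirrhosis all map to chronic liver disease.
#'
#' @param path Optional path to an alternative YAML grouping file with the
#'   same `group: [raw codes]` layout.
#' @return Named character vector: `names()` are raw codes, values are
#'   grouped codes. The map is total over the raw vocabulary and surjective
#'   onto the 14 groups.
#' @export
#' @examples
#' map <- khps_grouping_map()
#' unname(map["chronic_hepatitis"])
khps_grouping_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "khps_grouping.yaml", package = "mcdrules")
  }
  spec <- yaml::read_yaml(path)
  map <- unlist(lapply(names(spec), function(g) {
    stats::setNames(rep(g, length(spec[[g]])), spec[[g]])
  }))
  validate_grouping_map(map)
  map
}

validate_grouping_map <- function(map) {
  if (anyDuplicated(names(map))) {
    stop("grouping map assigns a raw code to more than one group", call. = FALSE)
  }
  missing_groups <- setdiff(grouped_condition_codes, unique(map))
  if (length(missing_groups)) {
    stop(
      "grouping map is not surjective onto the 14 groups; missing: ",
      paste(missing_groups, collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(unique(map), grouped_condition_codes)
  if (length(unknown)) {
    stop(
      "grouping map targets unknown groups: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(map)
}

#' Collapse raw condition codes to grouped disease categories
#'
#' Maps a set of raw condition codes to its image under the grouping map.
#' Codes that are already grouped categories pass through unchanged, so the
#' operation is idempotent; the result never has more elements than the
#' input.
#'
#' @param codes Character vector of raw or grouped condition codes.
#' @param map Grouping map as returned by [khps_grouping_map()].
#' @return Character vector of unique grouped codes, sorted.
#' @export
#' @examples
#' group_conditions(c("cerebral_hemorrhage", "cerebral_infarction"))
group_conditions <- function(codes, map = khps_grouping_map()) {
  codes <- unique(as.character(codes))
  if (!length(codes)) {
    return(character())
  }
  known_group <- codes %in% c(grouped_condition_codes, "obesity")
  known_raw <- codes %in% names(map)
  bad <- codes[!known_group & !known_raw]
  if (length(bad)) {
    stop(
      "unknown condition code(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out <- codes
  out[known_raw & !known_group] <- map[codes[known_raw & !known_group]]
  sort(unique(out))
}
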