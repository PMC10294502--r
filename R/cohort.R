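# Cohort preparation: read per-participant survey records, apply the
# eligibility filter (age > 45, complete data), and derive 15-condition
# binary profiles stratified by regular-exercise habit (AG / IG).

#' Body mass index from weight and height
#'
#' @param weight Weight in kilograms (positive).
#' @param height Height in meters (positive).
#' @param participant_id Optional identifiers used in error messages.
#' @return Numeric BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(70, 1.75)
compute_bmi <- function(weight, height, participant_id = NULL) {
  bad <- !is.finite(weight) | !is.finite(height) | weight <= 0 | height <= 0
  if (any(bad)) {
    who <- if (!is.null(participant_id)) {
      paste(participant_id[bad], collapse = ", ")
    } else {
      paste(which(bad), collapse = ", ")
    }
    stop("invalid record: non-positive weight or height for participant(s) ",
      who,
      call. = FALSE
    )
  }
  weight / height^2
}

#' Obesity indicator from BMI
#'
#' Obesity is defined as BMI strictly greater than 28 kg/m^2, the cut-point
#' above which obesity-related morbidity (stroke, ischemic heart disease,
#' diabetes) rises steeply in adults.
#'
#' @param bmi Numeric BMI values.
#' @param threshold Obesity cut-point, default 28 (strict inequality).
#' @return Logical vector.
#' @export
#' @examples
#' derive_obesity(c(22.9, 28, 31.1))
derive_obesity <- function(bmi, threshold = 28) {
  stopifnot(is.numeric(bmi), all(is.finite(bmi)))
  bmi > threshold
}

#' Read a delimited cohort file
#'
#' Expects a header row with the standard columns `participant_id`, `sex`,
#' `age`, `education`, `regular_exercise`, `height`, `weight`, plus one 0/1
#' indicator column per condition code (raw or grouped). Non-standard column
#' names can be bound through `columns`, a named character vector
#' `c(standard = "file_column")`.
#'
#' @param path Path to a CSV/TSV file.
#' @param columns Optional named character vector remapping file columns to
#'   the standard names.
#' @param height_unit `"m"` (default) or `"cm"`; cm are converted on read.
#' @param delim Field delimiter, inferred from the extension when `NULL`.
#' @return A tibble of survey records.
#' @export
read_cohort <- function(path, columns = NULL, height_unit = c("m", "cm"),
                        delim = NULL) {
  height_unit <- match.arg(height_unit)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  records <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!is.null(columns)) {
    idx <- match(unname(columns), names(records))
    if (anyNA(idx)) {
      stop("column mapping refers to absent column(s): ",
        paste(columns[is.na(idx)], collapse = ", "),
        call. = FALSE
      )
    }
    names(records)[idx] <- names(columns)
  }
  needed <- c(
    "participant_id", "sex", "age", "education",
    "regular_exercise", "height", "weight"
  )
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (height_unit == "cm") {
    records$height <- records$height / 100
  }
  records$regular_exercise <- as.logical(records$regular_exercise)
  records
}

record_condition_columns <- function(records, map = khps_grouping_map()) {
  intersect(names(records), c(names(map), grouped_condition_codes))
}

#' Apply the eligibility filter to survey records
#'
#' Retains participants aged 46 or older (integer years; the study population
#' is "aged > 45") with complete exercise, anthropometric and
#' chronic-condition data. Dropped records are counted and reported, never
#' fatal.
#'
#' @param records Tibble of survey records (see [read_cohort()]).
#' @param min_age Minimum eligible age in integer years, default 46.
#' @param quiet Suppress the retained/dropped message.
#' @return The eligible records, with a `"dropped"` attribute holding the
#'   per-reason counts.
#' @export
filter_eligible <- function(records, min_age = 46, quiet = FALSE) {
  if (!nrow(records)) {
    out <- records
    attr(out, "dropped") <- c(age = 0L, incomplete = 0L)
    return(out)
  }
  cond_cols <- record_condition_columns(records)
  required <- records[, c(
    "age", "regular_exercise", "height", "weight",
    cond_cols
  )]
  complete <- stats::complete.cases(required)
  old_enough <- !is.na(records$age) & records$age >= min_age
  keep <- complete & old_enough
  dropped <- c(
    age = sum(complete & !old_enough),
    incomplete = sum(!complete)
  )
  if (!quiet) {
    message(
      sum(keep), " of ", nrow(records), " records eligible (dropped ",
      dropped[["age"]], " under-age, ", dropped[["incomplete"]],
      " incomplete)"
    )
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Build 15-condition binary profiles from survey records
#'
#' For each participant: collapses raw condition indicators to the 14 grouped
#' categories, adds obesity when BMI > 28, flags multiple chronic disease
#' (MCD) status, and assigns the exercise stratum — AG (active group, reports
#' regular exercise including walking) or IG (inactive group).
#'
#' The MCD flag marks participants with two or more conditions. By default
#' all 15 conditions count toward the threshold, obesity included, since the
#' analysis screens 15 chronic diseases; set `mcd_includes_obesity = FALSE`
#' to count only the 14 grouped survey conditions.
#'
#' @param records Eligible survey records.
#' @param map Grouping map, see [khps_grouping_map()].
#' @param mcd_includes_obesity Count obesity toward the MCD threshold
#'   (default `TRUE`).
#' @return A tibble with one row per participant: demographics, `age_band`,
#'   `stratum` (`"AG"`/`"IG"`), `bmi`, `conditions` (list-column of condition
#'   codes), `n_conditions` and `mcd`.
#' @export
build_profiles <- function(records, map = khps_grouping_map(),
                           mcd_includes_obesity = TRUE) {
  cond_cols <- record_condition_columns(records, map)
  bmi <- compute_bmi(records$weight, records$height, records$participant_id)
  obese <- derive_obesity(bmi)
  cond_mat <- as.matrix(records[, cond_cols, drop = FALSE]) > 0
  conditions <- lapply(seq_len(nrow(records)), function(i) {
    raw <- cond_cols[cond_mat[i, ]]
    grouped <- group_conditions(raw, map)
    if (obese[i]) grouped <- sort(unique(c(grouped, "obesity")))
    grouped
  })
  counted <- vapply(conditions, function(x) {
    if (!mcd_includes_obesity) x <- setdiff(x, "obesity")
    length(x)
  }, integer(1))
  tibble::tibble(
    participant_id = records$participant_id,
    sex = records$sex,
    age = records$age,
    age_band = age_band(records$age),
    education = records$education,
    stratum = ifelse(records$regular_exercise, "AG", "IG"),
    bmi = bmi,
    conditions = conditions,
    n_conditions = lengths(conditions),
    mcd = counted >= 2L
  )
}

#' Age band used in the descriptive tables
#'
#' @param age Integer ages.
#' @return Factor with levels `46-55`, `56-65`, `66-75`, `>75`.
#' @export
age_band <- function(age) {
  cut(age,
    breaks = c(45, 55, 65, 75, Inf),
    labels = c("46-55", "56-65", "66-75", ">75"),
    right = TRUE
  )
}
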