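#' Read a sample metadata table
#'
#' Reads the cohort design: one row per sample with its group label and a
#' flag marking held-out samples. Held-out (test-set) samples take no part
#' in differential testing or DMR discovery; they are only projected onto
#' the fitted principal-component space for validation.
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `group`, and `test_set` (0/1 or logical).
#' @return A tibble with columns `sample_id` (character), `group`
#'   (character, exactly two levels expected downstream) and `test_set`
#'   (logical).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  check_df_cols(meta, c("sample_id", "group", "test_set"), "metadata")
  meta <- dplyr::mutate(
    meta,
    sample_id = as.character(.data$sample_id),
    group = as.character(.data$group),
    test_set = as.logical(.data$test_set)
  )
  validate_sample_meta(meta)
  tibble::as_tibble(meta)
}

validate_sample_meta <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop_input("sample_id values must be unique within a cohort.")
  }
  if (anyNA(meta$test_set)) {
    stop_input("test_set must be 0/1 or TRUE/FALSE with no missing values.")
  }
  invisible(meta)
}

#' Read semen analysis records
#'
#' Motility is stored as a percent in the input file (as reported
#' clinically) and converted to a fraction in \code{[0, 1]} on read, which
#' is the scale all arithmetic in the package uses.
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `timepoint` (one of `enroll`, `pre`, `post`), `volume_ml`,
#'   `concentration_mml` (million/mL), `motility_pct`.
#' @return A tibble with columns `sample_id`, `timepoint`, `volume`,
#'   `concentration`, `motility` (fraction).
#' @export
read_semen_records <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE)
  check_df_cols(
    rec,
    c("sample_id", "timepoint", "volume_ml", "concentration_mml",
      "motility_pct"),
    "semen records"
  )
  out <- tibble::tibble(
    sample_id = as.character(rec$sample_id),
    timepoint = as.character(rec$timepoint),
    volume = as.numeric(rec$volume_ml),
    concentration = as.numeric(rec$concentration_mml),
    motility = as.numeric(rec$motility_pct) / 100
  )
  validate_semen_records(out)
  out
}

validate_semen_records <- function(rec) {
  if (any(rec$volume < 0, na.rm = TRUE) ||
      any(rec$concentration < 0, na.rm = TRUE)) {
    stop_input("volume and concentration must be non-negative.")
  }
  if (any(rec$motility < 0 | rec$motility > 1, na.rm = TRUE)) {
    stop_input("motility must lie in [0, 1] (fraction).")
  }
  bad_tp <- setdiff(unique(rec$timepoint), c("enroll", "pre", "post"))
  if (length(bad_tp)) {
    stop_input(sprintf(
      "unknown timepoint value(s): %s.", paste(bad_tp, collapse = ", ")
    ))
  }
  invisible(rec)
}

#' Total motile count
#'
#' TMC = semen volume (mL) x sperm concentration (million/mL) x motile
#' fraction, in million motile sperm per ejaculate. TMC is linear in each
#' field separately.
#'
#' @param records A tibble of semen records with columns `volume`,
#'   `concentration` (million/mL) and `motility` (fraction in `[0, 1]`),
#'   e.g. from [read_semen_records()].
#' @return The input tibble with an added `tmc` column (million sperm).
#' @examples
#' total_motile_count(tibble::tibble(
#'   sample_id = "P1", volume = 2, concentration = 10, motility = 0.5
#' ))
#' @export
total_motile_count <- function(records) {
  check_df_cols(records, c("volume", "concentration", "motility"), "records")
  validate_semen_records(
    dplyr::mutate(records, timepoint = "pre")[
      , c("volume", "concentration", "motility", "timepoint")
    ]
  )
  dplyr::mutate(
    records,
    tmc = .data$volume * .data$concentration * .data$motility
  )
}

#' Classify FSH-therapy responders
#'
#' A patient is a responder when sperm concentration and/or motility rose
#' by at least `fold_threshold` between the pre- and post-treatment semen
#' analyses. A zero pre-treatment value with a positive post-treatment
#' value counts as a response for that parameter (an increase from
#' nothing); zero before and after does not.
#'
#' @param pre,post Tibbles of semen records (columns `sample_id`,
#'   `concentration`, `motility`) for the same set of samples at the two
#'   timepoints.
#' @param fold_threshold Minimum fold change that counts as a response
#'   (> 1; default 2).
#' @return A tibble with one row per sample: `sample_id`,
#'   `concentration_ratio`, `motility_ratio` (Inf for an increase from
#'   zero, NA when both values are zero) and logical `responder`.
#' @export
classify_responders <- function(pre, post, fold_threshold = 2) {
  check_df_cols(pre, c("sample_id", "concentration", "motility"), "pre")
  check_df_cols(post, c("sample_id", "concentration", "motility"), "post")
  check_number(fold_threshold, "fold_threshold")
  if (fold_threshold <= 1) {
    stop_input("`fold_threshold` must be greater than 1.")
  }
  if (!setequal(pre$sample_id, post$sample_id) ||
      anyDuplicated(pre$sample_id) || anyDuplicated(post$sample_id)) {
    stop_input("`pre` and `post` must cover the same sample_ids exactly once.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(pre, "sample_id",
                  pre_concentration = "concentration",
                  pre_motility = "motility"),
    dplyr::select(post, "sample_id",
                  post_concentration = "concentration",
                  post_motility = "motility"),
    by = "sample_id"
  )
  fold_ratio <- function(before, after) {
    dplyr::case_when(
      before > 0 ~ after / before,
      after > 0 ~ Inf,
      TRUE ~ NA_real_
    )
  }
  dplyr::mutate(
    joined,
    concentration_ratio = fold_ratio(.data$pre_concentration,
                                     .data$post_concentration),
    motility_ratio = fold_ratio(.data$pre_motility, .data$post_motility),
    responder =
      (!is.na(.data$concentration_ratio) &
         .data$concentration_ratio >= fold_threshold) |
      (!is.na(.data$motility_ratio) &
         .data$motility_ratio >= fold_threshold)
  ) |>
    dplyr::select("sample_id", "concentration_ratio", "motility_ratio",
                  "responder")
}
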