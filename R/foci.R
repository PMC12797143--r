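PARADIGM_LEVELS <- c("execution", "imagery", "working_memory")
SPACE_LEVELS <- c("MNI", "Talairach")
FOCI_COLUMNS <- c("study_id", "paradigm", "n_subjects", "x", "y", "z", "space")

#' Read and validate a foci coordinate table
#'
#' Reads a delimited table of reported activation peaks, one row per focus,
#' with columns `study_id`, `paradigm`, `n_subjects`, `x`, `y`, `z` and
#' optionally `space`.  Each `study_id` identifies one experiment (the unit
#' of meta-analysis); the convention is first-author surname + year, with a
#' trailing letter distinguishing multiple experiments from one paper
#' (`smith2010a`, `smith2010b`).  Talairach-space rows are flagged, never
#' silently transformed — convert them explicitly with [tal2mni()].
#'
#' @param source Path to a TSV/CSV file (delimiter inferred from the
#'   extension; anything not `.csv` is read as tab-separated).
#' @param space_default Space assumed for rows without a `space` column or
#'   with an empty tag (`"MNI"` or `"Talairach"`).
#' @return A validated tibble of foci with class `ale_foci`, row order
#'   preserved.
#' @seealso [foci_datasets()], [dataset_summary()], [write_foci_table()]
#' @export
read_foci_table <- function(source, space_default = "MNI") {
  space_default <- match.arg(space_default, SPACE_LEVELS)
  reader <- if (grepl("\\.csv$", source, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(source, show_col_types = FALSE, progress = FALSE)
  as_ale_foci(raw, space_default = space_default)
}

#' Validate an in-memory foci table
#'
#' @param data Data frame with the foci columns (see [read_foci_table()]).
#' @param space_default Space to assume when the `space` column is missing.
#' @return The validated tibble with class `ale_foci`.
#' @export
as_ale_foci <- function(data, space_default = "MNI") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(setdiff(FOCI_COLUMNS, "space"), names(data))
  if (length(missing_cols)) {
    stop_ale(
      "foci table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      class = "aleoverlap_schema_error"
    )
  }
  if (!"space" %in% names(data)) data$space <- space_default
  data$space[is.na(data$space) | data$space == ""] <- space_default
  bad_space <- setdiff(unique(data$space), SPACE_LEVELS)
  if (length(bad_space)) {
    stop_ale("unknown space tag(s): ", paste(bad_space, collapse = ", "),
      class = "aleoverlap_validation_error"
    )
  }
  bad_par <- setdiff(unique(data$paradigm), PARADIGM_LEVELS)
  if (length(bad_par)) {
    stop_ale("unknown paradigm label(s): ", paste(bad_par, collapse = ", "),
      class = "aleoverlap_validation_error"
    )
  }
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(data[[cc]]) || any(!is.finite(data[[cc]]))) {
      stop_ale("coordinate column '", cc, "' must be finite numeric",
        class = "aleoverlap_validation_error"
      )
    }
  }
  n <- data$n_subjects
  bad_n <- which(!is.finite(n) | n < 1 | n != floor(n))
  if (length(bad_n)) {
    stop_ale("n_subjects must be a positive integer; offending row(s): ",
      paste(utils::head(bad_n, 5), collapse = ", "),
      class = "aleoverlap_validation_error"
    )
  }
  data$n_subjects <- as.integer(n)
  # one experiment = one paradigm and one subject count
  chk <- dplyr::summarise(
    dplyr::group_by(data, .data$study_id),
    n_par = dplyr::n_distinct(.data$paradigm),
    n_n = dplyr::n_distinct(.data$n_subjects),
    .groups = "drop"
  )
  bad_id <- chk$study_id[chk$n_par > 1 | chk$n_n > 1]
  if (length(bad_id)) {
    stop_ale(
      "inconsistent paradigm or n_subjects within experiment(s): ",
      paste(utils::head(bad_id, 5), collapse = ", "),
      class = "aleoverlap_validation_error"
    )
  }
  data <- data[, FOCI_COLUMNS]
  class(data) <- c("ale_foci", class(data))
  data
}

#' Split a foci table into per-paradigm datasets
#'
#' @param foci A foci tibble (see [read_foci_table()]).
#' @return Named list of foci tibbles, one per paradigm present, each with
#'   a `paradigm` attribute; experiment and row order preserved.
#' @export
foci_datasets <- function(foci) {
  foci <- as_ale_foci(foci)
  out <- lapply(
    split(seq_len(nrow(foci)), factor(foci$paradigm, levels = PARADIGM_LEVELS))[
      intersect(PARADIGM_LEVELS, unique(foci$paradigm))
    ],
    function(idx) {
      d <- foci[sort(idx), ]
      attr(d, "paradigm") <- d$paradigm[1]
      d
    }
  )
  out
}

# strip the duplicate-experiment letter suffix to recover the paper id
paper_id <- function(study_id) {
  sub("(?<=[0-9])[a-z]$", "", study_id, perl = TRUE)
}

#' Summarise datasets: papers, experiments, participants, foci
#'
#' One row per paradigm plus an `all` row whose cells are the column sums.
#' Participants are counted once per experiment (no cross-experiment
#' de-duplication of subjects); papers are counted from experiment ids
#' after stripping the duplicate-letter suffix.
#'
#' @param foci A foci tibble.
#' @return Tibble with columns `paradigm`, `papers`, `experiments`,
#'   `participants`, `foci`.
#' @export
dataset_summary <- function(foci) {
  foci <- as_ale_foci(foci)
  per_exp <- dplyr::summarise(
    dplyr::group_by(foci, .data$paradigm, .data$study_id),
    n_subjects = .data$n_subjects[1],
    n_foci = dplyr::n(),
    .groups = "drop"
  )
  rows <- dplyr::summarise(
    dplyr::group_by(per_exp, .data$paradigm),
    papers = dplyr::n_distinct(paper_id(.data$study_id)),
    experiments = dplyr::n(),
    participants = sum(.data$n_subjects),
    foci = sum(.data$n_foci),
    .groups = "drop"
  )
  rows <- rows[order(match(rows$paradigm, PARADIGM_LEVELS)), ]
  totals <- tibble::tibble(
    paradigm = "all",
    papers = sum(rows$papers),
    experiments = sum(rows$experiments),
    participants = sum(rows$participants),
    foci = sum(rows$foci)
  )
  dplyr::bind_rows(rows, totals)
}

#' Write a foci table in canonical form
#'
#' Canonical column order, coordinates at 3-decimal mm, tab-separated.
#' Reading the file back reproduces the table row for row.
#'
#' @param foci A foci tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foci_table <- function(foci, path) {
  foci <- as_ale_foci(foci)
  out <- foci
  for (cc in c("x", "y", "z")) out[[cc]] <- round(out[[cc]], 3)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
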