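#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

trial_columns <- c("n0", "ne", "ap_offered", "ap_consumed",
                   "igp", "treatment", "replicate", "t_expose")

#' Construct a set of predation trials
#'
#' A trial set is a tibble with one row per arena-day predation trial and a
#' `metadata` attribute carrying provenance (source file, generator seed and
#' truth for synthetic data). All user-facing functions in the package accept
#' a plain data frame with the same columns; `trial_set()` validates and
#' stamps the class.
#'
#' Required columns:
#' \describe{
#'   \item{n0}{initial focal-prey density (count, >= 1)}
#'   \item{ne}{focal prey consumed (count, `0 <= ne <= n0`)}
#'   \item{ap_offered}{alternative prey offered (count)}
#'   \item{ap_consumed}{alternative prey consumed (`<= ap_offered`)}
#'   \item{igp}{context flag: `"non-parasitized"` or `"parasitized"`}
#'   \item{treatment}{alternative-prey treatment label, e.g. `"No AP"`}
#'   \item{replicate}{block id (experimentation day)}
#'   \item{t_expose}{exposure time in days (default 1 = 24 h)}
#' }
#'
#' @param trials Data frame with the columns above.
#' @param metadata Named list of free-form provenance values.
#' @return A `fr_trials` tibble.
#' @export
trial_set <- function(trials, metadata = list()) {
  trials <- tibble::as_tibble(trials)
  validate_trials(trials)
  attr(trials, "metadata") <- metadata
  class(trials) <- c("fr_trials", class(trials))
  trials
}

#' Validate predation-trial records
#'
#' Checks the schema and per-row invariants of a trial table, failing with
#' row-indexed messages on the first violated rule.
#'
#' @param trials Data frame of trials (see [trial_set()]).
#' @return The input, invisibly, if valid.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) stop("trial table has no rows", call. = FALSE)
  fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop("invalid trial row(s) ", paste(which(bad), collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  num <- c("n0", "ne", "ap_offered", "ap_consumed", "t_expose")
  for (col in num) {
    fail_rows(!is.finite(as.numeric(trials[[col]])), paste0(col, " is not a finite number"))
  }
  fail_rows(trials$n0 < 1, "n0 must be at least 1")
  fail_rows(trials$ne < 0 | trials$ne > trials$n0, "ne must satisfy 0 <= ne <= n0")
  fail_rows(trials$ap_consumed < 0 | trials$ap_consumed > trials$ap_offered,
            "ap_consumed must satisfy 0 <= ap_consumed <= ap_offered")
  fail_rows(trials$t_expose <= 0, "t_expose must be positive")
  invisible(trials)
}

#' Read predation trials from a CSV file
#'
#' Expects a UTF-8 comma-separated file with a header row containing at least
#' the required trial columns (see [trial_set()]). Extra columns are preserved.
#' Rows violating the trial invariants abort the read with row-indexed
#' messages.
#'
#' @param path Path to the CSV file.
#' @param format Input format; only `"csv"` is supported.
#' @return A validated `fr_trials` tibble with `source` recorded in metadata.
#' @export
read_trials <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  trial_set(raw, metadata = list(source = path))
}

#' Write predation trials to CSV (with optional provenance sidecar)
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @param sidecar If `TRUE`, also writes `<path>.json` holding the trial-set
#'   metadata (seed, generating model, ...).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sidecar = FALSE) {
  validate_trials(trials)
  readr::write_csv(tibble::as_tibble(as.data.frame(trials)), path)
  if (sidecar) {
    meta <- attr(trials, "metadata")
    if (is.null(meta)) meta <- list()
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Summarize consumption per treatment and density
#'
#' Per (igp context, treatment, initial density) cell: mean and standard error
#' of focal-prey consumption and of alternative-prey consumption, plus their
#' sum as total consumed prey. The standard error is the sample standard
#' deviation over `sqrt(n)`; cells with a single trial report `NA` (the sample
#' standard deviation is undefined at n = 1).
#'
#' @param trials Trial table.
#' @return Tibble with one row per cell: `igp`, `treatment`, `n0`, `n_trials`,
#'   `mean_ne`, `se_ne`, `mean_ap`, `se_ap`, `total_consumed`.
#' @export
summarize_consumption <- function(trials) {
  validate_trials(trials)
  se <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  tibble::as_tibble(trials) |>
    dplyr::group_by(.data$igp, .data$treatment, .data$n0) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_ne = mean(.data$ne),
      se_ne = se(.data$ne),
      mean_ap = mean(.data$ap_consumed),
      se_ap = se(.data$ap_consumed),
      .groups = "drop"
    ) |>
    dplyr::mutate(total_consumed = .data$mean_ne + .data$mean_ap) |>
    dplyr::arrange(.data$igp, .data$treatment, .data$n0)
}
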