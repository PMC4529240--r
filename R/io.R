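TRIAL_COLUMNS <- c("observer", "group", "condition", "block", "trial_index",
                   "exposure_ms", "n_targets", "n_distractors",
                   "location_roles", "displayed_targets",
                   "displayed_distractors", "reported")
DESIGN_EXPOSURES <- c(10, 20, 30, 50, 80, 150)

#' Write a trial table
#'
#' Comma-separated UTF-8 with a header row, preceded by comment lines
#' carrying the package version and a hash of the run configuration so that
#' outputs are traceable.
#'
#' @param trials Trial table (tibble/data.frame in the dialect of
#'   [read_trial_table()]).
#' @param path Output file.
#' @param config Optional configuration object echoed into the file hash.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path, config = NULL) {
  miss <- setdiff(setdiff(TRIAL_COLUMNS, c("group", "pair")), names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- intersect(c(TRIAL_COLUMNS, "pair"), names(trials))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("tvarace"))
  writeLines(c(paste0("# tvarace ", ver),
               paste0("# config_hash ", fnv1a(deparse(config)))), con)
  write.table(as.data.frame(trials)[, cols], con, sep = ",", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' One row per trial: `observer`, `group`, `condition`, `block`,
#' `trial_index`, `exposure_ms`, `n_targets`, `n_distractors`,
#' `location_roles` (6-character T/D/E code), `displayed_targets`,
#' `displayed_distractors`, `reported` (possibly empty). Graphemes are
#' uppercase A-Z and digits 1-9. Rows failing validation raise an error
#' naming the row and column; reported graphemes that were not displayed are
#' kept but flagged in the logical `intrusion` column.
#'
#' @param path CSV file (comment lines starting `#` are ignored).
#' @param design_only If TRUE (default), exposures must belong to the study
#'   design set (10, 20, 30, 50, 80, 150 ms).
#' @return A tibble with an added `intrusion` column and row numbers
#'   preserved in `trial_index`.
#' @export
read_trial_table <- function(path, design_only = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", colClasses = "character",
                 na.strings = NULL)
  miss <- setdiff(setdiff(TRIAL_COLUMNS, c("group", "pair")), names(df))
  if (length(miss))
    stop("header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("block", "trial_index", "exposure_ms", "n_targets",
                "n_distractors")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("row %d: column `%s` is not numeric", bad[1], col),
           call. = FALSE)
    df[[col]] <- v
  }
  if (design_only) {
    bad <- which(!(df$exposure_ms %in% DESIGN_EXPOSURES))
    if (length(bad))
      stop(sprintf("row %d: column `exposure_ms` has unknown exposure %g",
                   bad[1], df$exposure_ms[bad[1]]), call. = FALSE)
  }
  bad <- which(!grepl("^[TDE]{6}$", df$location_roles))
  if (length(bad))
    stop(sprintf("row %d: column `location_roles` is not a 6-character T/D/E code",
                 bad[1]), call. = FALSE)
  nT <- vapply(gregexpr("T", df$location_roles, fixed = TRUE),
               function(m) sum(m > 0), numeric(1))
  nD <- vapply(gregexpr("D", df$location_roles, fixed = TRUE),
               function(m) sum(m > 0), numeric(1))
  bad <- which(nT != df$n_targets | nD != df$n_distractors)
  if (length(bad))
    stop(sprintf("row %d: column `location_roles` disagrees with n_targets/n_distractors",
                 bad[1]), call. = FALSE)
  ok_ratio <- paste(df$n_targets, df$n_distractors) %in% c("6 0", "4 2", "3 3")
  if (any(!ok_ratio))
    stop(sprintf("row %d: target/distractor ratio %dT%dD is not a design ratio",
                 which(!ok_ratio)[1], df$n_targets[which(!ok_ratio)[1]],
                 df$n_distractors[which(!ok_ratio)[1]]), call. = FALSE)
  bad <- which(!grepl("^[A-Z]*$", df$displayed_targets) |
                 nchar(df$displayed_targets) != df$n_targets)
  if (length(bad))
    stop(sprintf("row %d: column `displayed_targets` is malformed", bad[1]),
         call. = FALSE)
  bad <- which(!grepl("^[1-9]*$", df$displayed_distractors) |
                 nchar(df$displayed_distractors) != df$n_distractors)
  if (length(bad))
    stop(sprintf("row %d: column `displayed_distractors` is malformed", bad[1]),
         call. = FALSE)
  bad <- which(!grepl("^[A-Z1-9]*$", df$reported))
  if (length(bad))
    stop(sprintf("row %d: column `reported` contains invalid graphemes",
                 bad[1]), call. = FALSE)
  df$intrusion <- vapply(seq_len(nrow(df)), function(r) {
    rc <- strsplit(df$reported[r], "")[[1]]
    tc <- strsplit(df$displayed_targets[r], "")[[1]]
    any(!(rc %in% tc))
  }, logical(1))
  if ("pair" %in% names(df)) df$pair <- as.integer(df$pair)
  tibble::as_tibble(df)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read grapheme-color screening mappings
#'
#' CSV with columns `observer`, `grapheme`, `presentation`, `r`, `g`, `b`;
#' `NA` channels mark a no-color response.
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_grapheme_mappings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("observer", "grapheme", "presentation", "r", "g", "b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- function(x) is.na(x) | (x >= 0 & x <= 255)
  bad <- which(!(ok(df$r) & ok(df$g) & ok(df$b)))
  if (length(bad))
    stop(sprintf("row %d: RGB channel out of [0, 255]", bad[1]),
         call. = FALSE)
  tibble::as_tibble(df)
}

#' Write a result table with a traceability header
#'
#' @param x Data frame.
#' @param path Output CSV.
#' @param config Optional configuration echoed into the header hash.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("tvarace"))
  writeLines(c(paste0("# tvarace ", ver),
               paste0("# config_hash ", fnv1a(deparse(config)))), con)
  write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}
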