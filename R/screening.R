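#' Grapheme-color consistency score
#'
#' Each grapheme is color-matched three times during screening; the
#' consistency score is the sum of the pairwise Euclidean distances between
#' the three chosen colors in unit-normalized RGB (channels divided by 255).
#' Identical choices score 0; maximally scattered choices score up to
#' 2*sqrt(3)*... ~ 3.46 for two distinct corners of the cube. Lower is more
#' consistent; the screening criterion is an average score below 1.
#'
#' @param colors A 3x3 matrix (rows = presentations, columns = R, G, B in
#'   0..255) or a list of three RGB triplets.
#' @return The score, or `NA` if any presentation carries no color.
#' @examples
#' consistency_score(rbind(c(255, 0, 0), c(250, 10, 5), c(255, 5, 0)))
#' @export
consistency_score <- function(colors) {
  if (is.list(colors)) colors <- do.call(rbind, colors)
  colors <- as.matrix(colors)
  if (!all(dim(colors) == c(3, 3)))
    stop("`colors` must be three RGB triplets", call. = FALSE)
  if (anyNA(colors)) return(NA_real_)
  if (any(colors < 0 | colors > 255))
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  u <- colors / 255
  sum(dist(u))
}

#' @rdname consistency_score
#' @param mappings Tibble of raw mappings with columns `grapheme`,
#'   `presentation`, `r`, `g`, `b` (one observer; NA channels mark a
#'   no-color response).
#' @return For `grapheme_consistency`: a tibble per grapheme with the score
#'   and the channel-wise mean color over the three presentations.
#' @export
grapheme_consistency <- function(mappings) {
  stopifnot(all(c("grapheme", "r", "g", "b") %in% names(mappings)))
  out <- lapply(split(mappings, mappings$grapheme), function(m) {
    if (nrow(m) != 3)
      stop("grapheme ", m$grapheme[1], " has ", nrow(m),
           " presentations; expected 3", call. = FALSE)
    cols <- as.matrix(m[, c("r", "g", "b")])
    tibble::tibble(grapheme = m$grapheme[1],
                   score = consistency_score(cols),
                   mean_r = mean(cols[, 1]), mean_g = mean(cols[, 2]),
                   mean_b = mean(cols[, 3]))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$grapheme)
}

# a mapping counts as "gray" (too similar to the background) when its mean
# color is nearly achromatic and close to the background level
is_gray <- function(mean_rgb, background = c(190, 190, 190)) {
  if (anyNA(mean_rgb)) return(FALSE)
  (max(mean_rgb) - min(mean_rgb)) < 10 &&
    abs(mean(mean_rgb) - mean(background)) <= 30
}

#' Select an observer's experimental stimulus set
#'
#' Picks the 12 most consistent letters and the 6 most consistent digits
#' after excluding no-color and gray (background-like) graphemes. Ties are
#' broken by character order. Every selected grapheme must individually
#' score below 1; otherwise the observer fails screening.
#'
#' @param scored Tibble from [grapheme_consistency()] (columns `grapheme`,
#'   `score`, `mean_r`, `mean_g`, `mean_b`).
#' @param background Background RGB (used for the gray exclusion).
#' @return A list with `letters` and `digits` tibbles (selected rows, sorted
#'   by score) and `excluded` (graphemes dropped as gray or colorless).
#' @export
select_test_set <- function(scored, background = c(190, 190, 190)) {
  gray <- vapply(seq_len(nrow(scored)), function(i) {
    is_gray(unlist(scored[i, c("mean_r", "mean_g", "mean_b")]), background)
  }, logical(1))
  excluded <- scored$grapheme[gray | is.na(scored$score)]
  ok <- scored[!gray & !is.na(scored$score), ]
  ok <- ok[order(ok$score, ok$grapheme), ]
  let <- ok[grepl("^[A-Z]$", ok$grapheme), ]
  dig <- ok[grepl("^[1-9]$", ok$grapheme), ]
  if (nrow(let) < 12 || nrow(dig) < 6)
    stop(sprintf("screening failure: only %d qualifying letters and %d digits (need 12 and 6)",
                 nrow(let), nrow(dig)), call. = FALSE)
  sel_let <- let[1:12, ]
  sel_dig <- dig[1:6, ]
  bad <- c(sel_let$grapheme[sel_let$score >= 1],
           sel_dig$grapheme[sel_dig$score >= 1])
  if (length(bad))
    stop("screening failure: selected grapheme(s) ",
         paste(bad, collapse = ", "), " have consistency score >= 1",
         call. = FALSE)
  list(letters = sel_let, digits = sel_dig, excluded = excluded)
}

#' Screening report for one observer
#'
#' Applies the inclusion rule (average consistency score below 1 over the
#' scored graphemes) and, when at least 12 letters and 6 digits qualify,
#' selects the test set.
#'
#' @inheritParams select_test_set
#' @return List with `mean_score`, `pass` (average-score criterion),
#'   `test_set` (or NULL if selection failed) and `test_set_mean_score`.
#' @export
screening_report <- function(scored, background = c(190, 190, 190)) {
  mean_score <- mean(scored$score, na.rm = TRUE)
  pass <- mean_score < 1
  ts <- tryCatch(select_test_set(scored, background), error = function(e) NULL)
  list(mean_score = mean_score, pass = pass, test_set = ts,
       test_set_mean_score = if (!is.null(ts))
         mean(c(ts$letters$score, ts$digits$score)) else NA_real_)
}

#' Inverse (incongruent) color
#'
#' Channel-wise subtraction from the maximum bit value: the incongruent
#' stimulus color is `255 - c` for each 8-bit channel.
#'
#' @param rgb Integer RGB triplet (or matrix of triplets), channels 0..255.
#' @return The inverted triplet(s).
#' @examples
#' invert_color(c(255, 0, 0))
#' @export
invert_color <- function(rgb) {
  if (any(rgb < 0 | rgb > 255) || anyNA(rgb))
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  255 - rgb
}

#' Weber contrast
#'
#' `(I_s - I_b) / I_b` for stimulus luminance `I_s` against background
#' luminance `I_b`.
#'
#' @param I_s Stimulus luminance (cd/m^2).
#' @param I_b Background luminance (> 0).
#' @return The contrast (dimensionless; vectorized).
#' @examples
#' weber_contrast(100, 50)
#' @export
weber_contrast <- function(I_s, I_b) {
  if (any(I_b <= 0)) stop("background luminance must be positive", call. = FALSE)
  (I_s - I_b) / I_b
}
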