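#' Vertebral injury-level coding table
#'
#' Maps spinal cord injury levels (vertebral labels such as `"T7"`) to
#' consecutive integer codes so that the level can enter a linear model as an
#' ordinal covariate. Codes run caudally: C1 = 1 ... C7 = 7, T1 = 8 ...
#' T12 = 19, L1 = 20 ... L5 = 24, S1 = 25 ... S5 = 29. A *larger* code means
#' a *lower* (more caudal) lesion, i.e. more preserved trunk function.
#'
#' @return A tibble with columns `level` (character label) and `code`
#'   (integer).
#' @export
#' @examples
#' injury_level_codes()
injury_level_codes <- function() {
  tibble::tibble(
    level = c(
      paste0("C", 1:7),
      paste0("T", 1:12),
      paste0("L", 1:5),
      paste0("S", 1:5)
    ),
    code = seq_len(29L)
  )
}

#' Convert vertebral level labels to ordinal codes
#'
#' @param level Character vector of vertebral labels (e.g. `"T7"`, `"L4"`).
#'   Case-insensitive; surrounding whitespace ignored.
#' @param coding Coding table, a data frame with columns `level` and `code`.
#'   Defaults to [injury_level_codes()]; supply your own to override.
#' @return Integer vector of codes (larger = lower lesion).
#' @export
#' @examples
#' parse_injury_level(c("T7", "L4"))
parse_injury_level <- function(level, coding = injury_level_codes()) {
  lvl <- toupper(trimws(as.character(level)))
  idx <- match(lvl, coding$level)
  bad <- which(is.na(idx) & !is.na(lvl))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown injury level label(s): %s",
      paste(unique(lvl[bad]), collapse = ", ")
    ), class = "ebvar_parse_error")
  }
  as.integer(coding$code[idx])
}
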