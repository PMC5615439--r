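#' Natural-log transform with an additive offset
#'
#' Outcomes are modelled on the natural-log scale. Outcomes that can be
#' zero on some days (MVPA minutes, alcohol percentage) need a small
#' additive offset before the log; strictly positive outcomes use offset 0.
#'
#' @param values Numeric vector, with `values + offset > 0`.
#' @param offset Non-negative additive offset; default 0.
#' @return `log(values + offset)`.
#' @export
#' @examples
#' log_transform(1)       # 0
#' log_transform(0, 1)    # 0: zero MVPA minutes under the +1 offset policy
log_transform <- function(values, offset = 0) {
  if (offset < 0) abort("offset must be non-negative", class = "ebvar_domain_error")
  bad <- which(!is.na(values) & values + offset <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "value + offset <= 0 at position %d (value = %g, offset = %g); cannot log-transform",
      bad[1], values[bad[1]], offset
    ), class = "ebvar_domain_error")
  }
  log(values + offset)
}

#' Invert the log transform
#'
#' @param log_values Log-scale values.
#' @param offset The offset used in [log_transform()].
#' @return Raw-scale values `exp(log_values) - offset`.
#' @export
back_transform <- function(log_values, offset = 0) {
  exp(log_values) - offset
}

#' Express a log-scale effect as a percent change
#'
#' A fixed-effect coefficient `b` on the natural-log scale corresponds to a
#' multiplicative factor `exp(b)`, reported as `100 * (exp(b) - 1)` percent.
#'
#' @param effect_log Log-scale effect(s).
#' @return Percent change.
#' @export
#' @examples
#' pct_from_log(log(0.85)) # -15
pct_from_log <- function(effect_log) {
  100 * (exp(effect_log) - 1)
}

#' Default log-offset policy per outcome
#'
#' Offset +1 for outcomes with true zero days (MVPA minutes, alcohol
#' percentage of intake), 0 elsewhere.
#'
#' @param outcomes Character vector of outcome names.
#' @param zero_inflated Outcomes that receive the +1 offset.
#' @param offset Offset applied to `zero_inflated` outcomes.
#' @return Named numeric vector of offsets.
#' @export
default_offsets <- function(outcomes = default_outcomes(),
                            zero_inflated = c("mvpa_min", "alcohol_pct"),
                            offset = 1) {
  setNames(ifelse(outcomes %in% zero_inflated, offset, 0), outcomes)
}
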