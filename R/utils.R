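# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign patients to the two-level age group
#'
#' Patients strictly under `cutoff` years at diagnosis are "young"; patients
#' at or above it are "old".
#'
#' @param age Integer vector of ages in years; `NA` allowed.
#' @param cutoff Age cutoff in years (default 45).
#' @return Factor with levels `c("young", "old")`; `NA` where age is missing.
#' @export
age_group2 <- function(age, cutoff = 45) {
  factor(ifelse(age < cutoff, "young", "old"), levels = c("young", "old"))
}

#' Assign patients to the four-level age group
#'
#' Default bins: under 45, 45-54, 55-64, 65 and older.
#'
#' @param age Integer vector of ages in years; `NA` allowed.
#' @param breaks Interior cut points (default `c(45, 55, 65)`); each bin is
#'   closed on the left.
#' @return Ordered factor; `NA` where age is missing.
#' @export
age_group4 <- function(age, breaks = c(45, 55, 65)) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks))
  labs <- c(
    paste0("<", breaks[1]),
    if (length(breaks) > 1)
      paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
    paste0(">=", breaks[length(breaks)])
  )
  cut(age, breaks = c(-Inf, breaks, Inf), labels = labs,
      right = FALSE, ordered_result = TRUE)
}

# Deterministic per-stage substream seeds derived from one master seed, so
# that adding draws to one table never perturbs another.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("eogc_format_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(sprintf(...), class = c("eogc_validation_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = c("eogc_config_error", "error")))
}
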