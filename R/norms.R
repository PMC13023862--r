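#' Normative sample summary
#'
#' A normative sample is the (mean, SD, N) summary of a control group's
#' scores on some measure, used as the comparison distribution in
#' single-case inference and in deficit screening. Only the summary is
#' stored; the raw control scores are not needed by any downstream method.
#'
#' @param mean Control-group mean, in the units of the measure.
#' @param sd Control-group sample standard deviation; must be positive.
#' @param n Number of controls; at least 2.
#' @param label Short free-text description of the sample.
#'
#' @return An object of class `normative_sample`: a list with elements
#'   `mean`, `sd`, `n` and `label`.
#'
#' @examples
#' normative_sample(0.082, 0.405, 180, label = "combined controls")
#' @export
normative_sample <- function(mean, sd, n, label = "") {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop("`mean` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("`sd` must be a single positive number", call. = FALSE)
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd), n = n,
         label = as.character(label)[1L]),
    class = "normative_sample"
  )
}

#' @export
print.normative_sample <- function(x, ...) {
  cat("Normative sample", if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  mean = %.4g, sd = %.4g, n = %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

is_normative_sample <- function(x) inherits(x, "normative_sample")

as_normative_sample <- function(x) {
  if (is_normative_sample(x)) return(x)
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    return(normative_sample(x$mean, x$sd, x$n,
                            label = if (is.null(x$label)) "" else x$label))
  }
  stop("cannot interpret input as a normative sample", call. = FALSE)
}
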