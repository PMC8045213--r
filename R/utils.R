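#' @import data.table
#' @importFrom stats dnbinom dpois dhyper dbinom optimize p.adjust quantile
#'   rbinom rlnorm rnbinom rpois runif cor setNames complete.cases
#' @importFrom utils head
NULL

# single "info"-level logging channel; every stage reports input dimensions,
# thresholds and filter counts through this
hs_log <- function(fmt, ...) {
  if (isTRUE(getOption("homeoscope.verbose", TRUE))) {
    message(sprintf(paste0("[homeoscope] ", fmt), ...))
  }
}

#' Quiet or restore homeoscope logging
#'
#' @param quiet logical; `TRUE` suppresses info logging.
#' @return the previous setting, invisibly.
#' @export
hs_quiet <- function(quiet = TRUE) {
  old <- getOption("homeoscope.verbose", TRUE)
  options(homeoscope.verbose = !quiet)
  invisible(old)
}

hs_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# geometric mean of strictly positive values
geo_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
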