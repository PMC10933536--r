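#' @keywords internal
"_PACKAGE"

# classed errors so callers can distinguish failure modes programmatically
fc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("focalcall_", class), "focalcall_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Convert a duration in seconds to hours
#' @param seconds numeric duration
#' @return duration in hours
#' @keywords internal
sec_to_hours <- function(seconds) seconds / 3600

# trapezoidal rule on a regular or irregular grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @importFrom utils head tail read.delim write.table
#' @importFrom stats rnorm rexp runif rbinom approx optim dnorm bw.nrd0 setNames
NULL
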