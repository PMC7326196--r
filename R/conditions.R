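#' @keywords internal
#' @import methods
#' @importFrom utils head read.csv write.csv write.table packageVersion
#' @importFrom stats runif setNames addmargins
#' @importFrom tools md5sum
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., ee_unmapped_class_code = ...) instead of matching messages.
eeStop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ee_error")))
}

eeWarn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "ee_warning")))
}

stopifnotScalarCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x))
    eeStop("ee_bad_argument", sprintf("'%s' must be a single positive integer", what))
  as.integer(x)
}
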