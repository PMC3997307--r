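#' Logit and inverse logit
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] used
#' throughout the model, exported because scenario truths and summaries are
#' usually specified on the probability scale.
#'
#' @param p probability in \[0, 1\].
#' @param x value on the logit (log-odds) scale.
#' @return `logit()` returns log(p/(1-p)); `invlogit()` returns 1/(1+exp(-x)).
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

# Leveled logging to stderr (and optionally a file set via
# options(transmark.log_file = path)). Levels: DEBUG < INFO < WARN.
# options(transmark.verbose = FALSE) silences INFO/DEBUG.
cmr_log <- function(msg, level = "INFO") {
  verbose <- getOption("transmark.verbose", TRUE)
  if (!verbose && level %in% c("DEBUG", "INFO")) return(invisible(NULL))
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  log_file <- getOption("transmark.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
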