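# shared helpers ---------------------------------------------------------

#' Round half away from zero to an integer
#'
#' Breakpoint positions are averages of integer genomic coordinates and are
#' reported as integers; ties (x.5) round up, matching the usual convention
#' for reported coordinates rather than R's round-half-even.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# package-level verbosity: detection/simulation report per-stage counts via
# message() so they can be sink'd or suppressed by the caller
lf_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# canonical unordered gene-pair key, used everywhere two gene ids identify a
# fusion irrespective of orientation
pair_key <- function(g1, g2) {
  ifelse(g1 <= g2, paste(g1, g2, sep = "|"), paste(g2, g1, sep = "|"))
}

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  invisible(TRUE)
}
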