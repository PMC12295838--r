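.color_levels <- c("GREEN", "YELLOW", "RED")
.parameters   <- c("aop", "hsd", "mla", "ad")

#' Threshold configuration for traffic-light parameter coding
#'
#' A threshold configuration holds, for each of the four geometric
#' parameters, the ordered breakpoints delimiting the GREEN/YELLOW/RED
#' bands, a flag saying whether risk increases with the value, and the
#' admissible measurement domain. With `higher_is_risk = TRUE` and
#' breakpoints `(b1, b2)` the bands are GREEN below `b1`, YELLOW in
#' `[b1, b2)`, RED at and above `b2`; a single breakpoint gives a
#' GREEN/RED split with no YELLOW band. Values falling exactly on a
#' breakpoint take the riskier color. With `higher_is_risk = FALSE` the
#' band order is mirrored (large values favorable).
#'
#' @param ... Named per-parameter entries (`aop`, `hsd`, `mla`, `ad`), each a
#'   list with elements `breakpoints` (numeric, length 1 or 2, strictly
#'   increasing), `higher_is_risk` (logical) and `domain` (numeric length 2).
#'   An optional `units` string is carried through.
#' @return An object of class `aida_thresholds`.
#' @seealso [default_thresholds()], [classify_parameter()]
#' @export
threshold_config <- function(...) {
  entries <- list(...)
  if (!setequal(names(entries), .parameters))
    stop("threshold_config needs exactly the entries: ",
         paste(.parameters, collapse = ", "))
  for (p in .parameters) {
    e <- entries[[p]]
    if (!is.list(e) || is.null(e$breakpoints) || is.null(e$higher_is_risk) ||
        is.null(e$domain))
      stop("entry '", p, "' must list breakpoints, higher_is_risk, domain")
    b <- e$breakpoints
    if (!is.numeric(b) || length(b) < 1 || length(b) > 2 || is.unsorted(b, strictly = TRUE))
      stop("entry '", p, "': breakpoints must be 1 or 2 strictly increasing numbers")
    d <- e$domain
    if (!is.numeric(d) || length(d) != 2 || d[1] >= d[2])
      stop("entry '", p, "': domain must be (lo, hi) with lo < hi")
    if (any(b <= d[1]) || any(b >= d[2]))
      stop("entry '", p, "': breakpoints must lie strictly inside the domain")
    if (!is.logical(e$higher_is_risk) || length(e$higher_is_risk) != 1)
      stop("entry '", p, "': higher_is_risk must be a single logical")
  }
  structure(entries[.parameters], class = "aida_thresholds")
}

#' Default (non-canonical) threshold configuration
#'
#' A documented placeholder: the numeric cut-offs published for the AIDA
#' classifier live in a prior publication and are not constants of this
#' package, so every analysis of recorded data consumes transcribed colors
#' directly and never these defaults. The midline-angle breakpoints (61 and
#' 64 degrees on the canonical 0-180 scale) are chosen to be consistent with
#' every case in the packaged reference cohort; the other three parameters
#' use clinically plausible round numbers so that the synthetic generator
#' and the raw-measurement path are exercisable end to end.
#'
#' @return An `aida_thresholds` object.
#' @export
default_thresholds <- function() {
  threshold_config(
    aop = list(breakpoints = c(110, 120), higher_is_risk = FALSE,
               domain = c(60, 200), units = "deg"),
    hsd = list(breakpoints = c(15, 20), higher_is_risk = TRUE,
               domain = c(0, 60), units = "mm"),
    mla = list(breakpoints = c(61, 64), higher_is_risk = TRUE,
               domain = c(0, 180), units = "deg"),
    ad  = list(breakpoints = c(20, 35), higher_is_risk = TRUE,
               domain = c(0, 90), units = "mm")
  )
}

#' @export
print.aida_thresholds <- function(x, ...) {
  cat("AIDA threshold configuration\n")
  for (p in names(x)) {
    e <- x[[p]]
    cat(sprintf("  %-3s breakpoints: %-12s risk %s with value, domain [%g, %g] %s\n",
                p, paste(e$breakpoints, collapse = ", "),
                if (e$higher_is_risk) "increases" else "decreases",
                e$domain[1], e$domain[2],
                if (is.null(e$units)) "" else e$units))
  }
  invisible(x)
}

#' Read / write a threshold configuration as flat key-value text
#'
#' Format: one `parameter.key = value` line per field, e.g.
#' `aop.breakpoints = 110, 120`. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_thresholds()` returns an `aida_thresholds` object;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed key-value line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  entries <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("key must be parameter.field: ", keys[i])
    p <- parts[1]; f <- parts[2]
    v <- switch(f,
      breakpoints = , domain = as.numeric(strsplit(vals[i], ",")[[1]]),
      higher_is_risk = as.logical(vals[i]),
      units = vals[i],
      stop("unknown threshold field: ", f))
    entries[[p]][[f]] <- v
  }
  do.call(threshold_config, entries)
}

#' @rdname read_thresholds
#' @param config An `aida_thresholds` object.
#' @export
write_thresholds <- function(config, path) {
  stopifnot(inherits(config, "aida_thresholds"))
  lines <- character()
  for (p in names(config)) {
    e <- config[[p]]
    lines <- c(lines,
      sprintf("%s.breakpoints = %s", p, paste(e$breakpoints, collapse = ", ")),
      sprintf("%s.higher_is_risk = %s", p, e$higher_is_risk),
      sprintf("%s.domain = %s", p, paste(e$domain, collapse = ", ")))
    if (!is.null(e$units)) lines <- c(lines, sprintf("%s.units = %s", p, e$units))
  }
  writeLines(lines, path)
  invisible(path)
}
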