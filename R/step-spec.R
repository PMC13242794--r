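# Step-specifier parsing: NAME:p1:p2:... tokens, validated before any
# sequence data is touched.

# schema: for each step, the minimum/maximum number of parameters and a
# checker run on the raw tokens that returns typed parameters.
int_param <- function(tok, what, min = 0L) {
  if (!grepl("^[0-9]+$", tok))
    stop("parameter '", tok, "' (", what, ") must be a non-negative integer")
  v <- as.integer(tok)
  if (v < min) stop(what, " must be >= ", min, ", got ", v)
  v
}

real_param <- function(tok, what) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("parameter '", tok, "' (", what, ") must be numeric")
  v
}

step_schemas <- list(
  ILLUMINACLIP = list(min = 4L, max = 6L, parse = function(p) {
    out <- list(fasta = p[[1L]],
                seed_mismatches = int_param(p[[2L]], "seed mismatches"),
                palindrome_threshold = real_param(p[[3L]], "palindrome threshold"),
                simple_threshold = real_param(p[[4L]], "simple threshold"),
                min_adapter_length = 8L,
                keep_both_reads = FALSE)
    if (out$palindrome_threshold < 0 || out$simple_threshold < 0)
      stop("ILLUMINACLIP thresholds must be >= 0")
    if (length(p) >= 5L)
      out$min_adapter_length <- int_param(p[[5L]], "min adapter length", 1L)
    if (length(p) >= 6L) {
      kb <- tolower(p[[6L]])
      if (!kb %in% c("true", "false"))
        stop("keepBothReads must be 'true' or 'false', got '", p[[6L]], "'")
      out$keep_both_reads <- kb == "true"
    }
    out
  }),
  SLIDINGWINDOW = list(min = 2L, max = 2L, parse = function(p) {
    list(window = int_param(p[[1L]], "window width", 1L),
         quality = int_param(p[[2L]], "mean quality threshold"))
  }),
  MAXINFO = list(min = 2L, max = 2L, parse = function(p) {
    s <- real_param(p[[2L]], "strictness")
    if (s <= 0 || s >= 1) stop("MAXINFO strictness must lie in (0, 1)")
    list(target_length = int_param(p[[1L]], "target length", 1L),
         strictness = s)
  }),
  LEADING  = list(min = 1L, max = 1L,
                  parse = function(p) list(quality = int_param(p[[1L]], "quality"))),
  TRAILING = list(min = 1L, max = 1L,
                  parse = function(p) list(quality = int_param(p[[1L]], "quality"))),
  CROP     = list(min = 1L, max = 1L,
                  parse = function(p) list(length = int_param(p[[1L]], "length"))),
  HEADCROP = list(min = 1L, max = 1L,
                  parse = function(p) list(length = int_param(p[[1L]], "length"))),
  TAILCROP = list(min = 1L, max = 1L,
                  parse = function(p) list(length = int_param(p[[1L]], "length"))),
  MINLEN   = list(min = 1L, max = 1L,
                  parse = function(p) list(length = int_param(p[[1L]], "length"))),
  BASECOUNT = list(min = 1L, max = 1L,
                   parse = function(p) list(length = int_param(p[[1L]], "length"))),
  AVGQUAL  = list(min = 1L, max = 1L,
                  parse = function(p) list(quality = int_param(p[[1L]], "quality")))
)

# ILLUMINACLIP's first field is a file path that may itself contain ':'?
# No: the dialect forbids spaces and colons inside tokens; fields split on ':'.

#' Parse one colon-delimited step token
#'
#' Splits `"NAME:p1:p2:..."` on `":"`, checks the step name against the
#' known vocabulary and validates parameter arity and numeric ranges.
#' All validation happens before any read data is processed.
#'
#' @param token Step token, e.g. `"SLIDINGWINDOW:4:20"`.
#' @return A `step_spec`: list with `step_name`, the raw `params`
#'   tokens, and typed `args`.
#' @examples
#' parse_step_spec("SLIDINGWINDOW:4:20")
#' parse_step_spec("MINLEN:36")
#' @export
parse_step_spec <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  fields <- strsplit(token, ":", fixed = TRUE)[[1L]]
  name <- fields[1L]
  schema <- step_schemas[[name]]
  if (is.null(schema))
    stop("unknown step '", name, "' in token '", token, "'")
  params <- fields[-1L]
  if (length(params) < schema$min || length(params) > schema$max)
    stop("step ", name, " takes ", schema$min,
         if (schema$max > schema$min) paste0("-", schema$max), " parameter(s), got ",
         length(params), " in '", token, "'")
  structure(list(step_name = name, params = params,
                 args = schema$parse(as.list(params))),
            class = "step_spec")
}

#' Render a step specification back into its token form
#'
#' Inverse of [parse_step_spec()]: joins the step name and raw parameters
#' with `":"`.
#'
#' @param spec A `step_spec`.
#' @return Character token.
#' @export
render_step_spec <- function(spec) {
  stopifnot(inherits(spec, "step_spec"))
  paste(c(spec$step_name, spec$params), collapse = ":")
}

#' @export
print.step_spec <- function(x, ...) {
  cat("<step_spec> ", render_step_spec(x), "\n", sep = "")
  invisible(x)
}

# Parse a vector of tokens (already-parsed specs pass through).
parse_steps <- function(steps) {
  lapply(steps, function(s) if (inherits(s, "step_spec")) s else parse_step_spec(s))
}
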