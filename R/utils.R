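# Shared helpers: seeded substreams, config digests, input checks.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from a single seed through named
#' substreams (e.g. "subjects", "noise", "mask", "shuffle", "init"), so any
#' stage can be regenerated independently of the others.  The derivation is a
#' small integer hash of the label (and optional index) folded into the seed;
#' results stay within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Master integer seed.
#' @param label Character stream label.
#' @param index Optional non-negative integer (e.g. epoch number) for
#'   per-iteration streams.
#' @return A single integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  h <- (h + as.numeric(index) * 7919) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629 + 1)
}

with_substream <- function(seed, label, index = 0L, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label, index))
  force(code)
}

#' Digest of a configuration object
#'
#' Serializes the object to canonical JSON and returns its MD5 hash, used to
#' stamp datasets, checkpoints and reports with provenance.
#'
#' @param x A list-like configuration object.
#' @return A 32-character hexadecimal string.
#' @export
config_digest <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

stop_invalid <- function(...) {
  stop(structure(class = c("gaitssl_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schema <- function(...) {
  stop(structure(class = c("gaitssl_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
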