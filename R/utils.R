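# Internal helpers shared across modules.

# Reverse-complement a DNA string (character scalar). Handles ACGTN only,
# which is all the simulator and the TSV read dialect ever emit.
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  ))
}

# Phred+33 encoding helpers.
phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

mean_read_quality <- function(qual_strings) {
  vapply(qual_strings, function(x) mean(utf8ToInt(x)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# Trapezoidal integral of y over x (thin wrapper so callers read clearly).
trapz_area <- function(x, y) pracma::trapz(x, y)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
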