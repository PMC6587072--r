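# Internal helpers shared across modules.

#' Deterministic string fingerprint
#'
#' Polynomial rolling hash (base 131, modulus 2^31 - 1) over the UTF-8 bytes
#' of each input string, rendered as 8 hex digits. Used to mint stable
#' statement identifiers from (subject, relation, object, citation, evidence)
#' so that re-generated sheets and re-parsed documents agree on identity.
#' Arithmetic stays below 2^53 so the result is exact in doubles.
#'
#' @param x character vector
#' @return character vector of 8-hex-digit fingerprints
#' @keywords internal
str_fingerprint <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) s <- ""
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 5381
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", h)
  }, character(1), USE.NAMES = FALSE)
}

# Escape a string for inclusion in a double-quoted BEL Script value.
bel_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  gsub('"', '\\"', s, fixed = TRUE)
}

# Collapse internal whitespace that would break the line-oriented formats
# (TSV sheets, single-line BEL evidence strings).
flatten_ws <- function(s) {
  s <- gsub("[\t\r\n]+", " ", s)
  trimws(s)
}

# Empty data frame with the given character columns; list columns are
# created for names ending in "_list".
empty_df <- function(cols) {
  out <- lapply(cols, function(nm) {
    if (grepl("_list$", nm)) I(list()) else character(0)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Run an expression with a private RNG stream so generators are pure
# functions of (config, seed) and never disturb the caller's RNG state.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
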