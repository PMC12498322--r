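# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so package functions never disturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero. An epsilon guard absorbs binary representation
# error on grid fractions (e.g. 0.05 * 170 = 8.499999...).
round_half_away <- function(x) {
  stopifnot(all(x >= 0))
  floor(x + 0.5 + 1e-9)
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Stable polynomial string hash (mod 2^31 - 1) so that grid cells keep
#' their seeds under partial re-runs and reordering of the grid.
#'
#' @param master integer master seed.
#' @param ... key components (coerced to character).
#' @return an integer between 0 and 2^31 - 2.
#' @keywords internal
#' @noRd
derive_seed <- function(master, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.numeric(p)) sprintf("%.6f", p) else as.character(p)
  }, character(1))
  key <- paste(c(sprintf("%d", as.integer(master)), parts), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Population standard deviation (n denominator); 0 for n = 1.
sd_pop <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Read a TSV with character columns preserved; small files only.
read_tsv_strict <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
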