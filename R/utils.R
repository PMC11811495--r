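# internal helpers shared across modules

# Read a TSV file into a character matrix, skipping blank lines and
# '#'-prefixed comments.  No quoting: fields are split on literal tabs.
read_tsv_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], rows = which(keep))
}

split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

stop_parse <- function(file, row, msg) {
  stop(sprintf("%s (row %d of %s)", msg, row, file), call. = FALSE)
}

# Evaluate `expr` under an explicit Mersenne-Twister seed without
# clobbering the caller's random state.  All generators in the package
# route their randomness through this helper.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

# Render a numeric/integer value as a TSV cell with literal "NA".
na_cell <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                formatC(x, digits = digits, format = "g")))
}
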