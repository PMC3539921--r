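#' @importFrom stats quantile p.adjust setNames
#' @importFrom utils head combn
NULL

# Internal logging: all diagnostics go to stderr so stdout stays clean for data.
.log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Derive a reproducible child seed from a master seed and a stable label
#'
#' Every stochastic generator in the package draws from its own stream,
#' derived from the master seed and a fixed label, so that adding a new
#' generator never perturbs the output of existing ones.
#'
#' @param seed master integer seed.
#' @param label character label naming the stream.
#' @return an integer seed below 2^31.
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 100003L
  as.integer((abs(as.numeric(seed)) * 131 + h) %% (.Machine$integer.max - 1))
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical unordered pair key.
.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# Escape a literal string for use inside a regular expression.
.rxEscape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Format a numeric column for TSV output: 6 significant digits,
# p-values in scientific notation.
.fmtNum <- function(x, scientific = FALSE) {
  ifelse(is.na(x), "NA",
         format(signif(x, 6), scientific = scientific, trim = TRUE))
}

# Write a data.frame as UTF-8/LF TSV with stable column order.
.writeTSV <- function(df, path, pcols = character()) {
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]))
      out[[cl]] <- .fmtNum(out[[cl]], scientific = cl %in% pcols)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
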