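# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(sprintf(...), call. = FALSE)

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @keywords internal
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

# run expr under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation calls do not perturb
# user code
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

read_tsv_strict <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_ctx("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_ctx("%s: missing required column(s): %s", path,
             paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
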