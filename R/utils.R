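# Internal helpers shared across modules.

# Amino-acid alphabet: the 20 standard residues plus X (unknown). X never
# satisfies a ligand slot and is rejected by the physicochemical calculators.
AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_STANDARD, "X")

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# Average mass of one water molecule (Da); subtracted once per peptide bond.
WATER_MASS <- 18.01524

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Percentage with half-up rounding at one decimal
#'
#' Computes `100 * count / denominator` rounded half-up to one decimal place,
#' the convention used for every percentage the family census reports (e.g.
#' 59 of 75 prints as 78.7). Note this differs from [round()], which rounds
#' half to even.
#'
#' @param count Non-negative integer, at most `denominator`.
#' @param denominator Positive integer.
#' @return A numeric percentage with one decimal.
#' @examples
#' census_percentage(59, 75)   # 78.7
#' census_percentage(129, 138) # 93.5
#' @export
census_percentage <- function(count, denominator) {
  if (length(denominator) != 1L || !is.finite(denominator) || denominator <= 0)
    stop("denominator must be a positive number")
  if (any(count < 0) || any(count > denominator))
    stop("count must satisfy 0 <= count <= denominator")
  v <- 100 * count / denominator
  floor(v * 10 + 0.5 + 1e-9) / 10
}

validate_sequence <- function(seq, alphabet, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  ch <- seq_chars(seq)
  bad <- which(!(ch %in% alphabet))
  if (length(bad))
    stop(sprintf("invalid character '%s' in %s at position %d",
                 ch[bad[1]], what, bad[1]))
  invisible(ch)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ringzf", mustWork = FALSE)
  if (!nzchar(path)) {
    # during in-source development (pkgload) inst/ may still be on disk
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("cannot locate packaged data file: ", file)
  path
}
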