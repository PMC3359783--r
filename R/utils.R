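# Shared constants and small helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues, in the fixed internal order used by all scoring
#' matrices, plus the ambiguity code `X` (scored 0 in every profile column).
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues that are mapped to X on input (ambiguity codes / stops)
AA_NONSTANDARD <- c("B", "Z", "U", "J", "O", "*")

#' Uniform background frequencies
#'
#' Default background: 0.05 for each of the 20 standard residues.  Uniform
#' background keeps the log-odds arithmetic exact for the synthetic
#' benchmarks; published amino-acid frequencies can be passed anywhere a
#' `background` argument is accepted.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_STANDARD)
}

#' Round half away from zero
#'
#' Census percentages are reported with half-up rounding (0.005 rounds to
#' 0.01), matching the formatting of published kinome distribution tables,
#' rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
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

# encode residues as integer codes into the score-matrix columns
# (1..20 standard order, 21 = X)
encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, c(AA_STANDARD, "X"))
  if (anyNA(idx)) {
    stop("residues contain characters outside the amino-acid alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
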