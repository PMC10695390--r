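# internal string helpers shared across modules

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is how sequences travel inside this package.
#'
#' @param x character vector of DNA sequences over `A,C,G,T,N`.
#' @return character vector of reverse complements, same length as `x`.
#' @export
#' @examples
#' reverse_complement("AAAACGT")
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# number of mismatching positions between two equal-length strings
str_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(toupper(a)) != charToRaw(toupper(b)))
}

# run code with a temporarily seeded RNG, restoring any prior state;
# keeps simulators pure functions of their seed without clobbering the
# caller's random stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# validate a DNA string over the permitted alphabet (ambiguity codes other
# than N are rejected on input by design)
check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ",")),
         call. = FALSE)
  }
  toupper(x)
}

random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- if (identical(alphabet, c("A", "C", "G", "T"))) {
    c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  } else {
    rep(1 / length(alphabet), length(alphabet))
  }
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}
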