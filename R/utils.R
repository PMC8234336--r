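#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed percentage shares in survey reports. Base R `round()` uses
#' banker's rounding, which renders 69.415 as 69.41 or 69.42 depending on
#' binary representation; half-up is deterministic.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.2965, 3)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# split a nucleotide string into codon triplets
split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3 != 0) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# standard genetic code (code table 1) keyed by DNA codon
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
}

# translate a codon character vector; stop codon -> "*"
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

# translate a CDS string, dropping one terminal stop codon if present;
# errors on internal stops (names the first offending codon index)
cds_to_protein <- function(cds) {
  cod <- split_codons(cds)
  aa <- translate_codons(cod)
  if (anyNA(aa)) {
    stop("non-standard codon at position ", which(is.na(aa))[1])
  }
  n <- length(aa)
  if (aa[n] == "*") {
    aa <- aa[-n]
    cod <- cod[-n]
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon index ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

# natural sort order for chromosome labels: "Chr2" before "Chr10"
natural_order <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", x)))
  pre <- gsub("[0-9]", "", x)
  order(pre, num, x, method = "radix", na.last = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
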