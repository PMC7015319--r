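#' Codon utilities
#'
#' The simulator works on RNA codons (alphabet A, C, G, U). Codons are
#' indexed internally by the code `16*b1 + 4*b2 + b3` with A=0, C=1, G=2, U=3;
#' all user-facing interfaces use codon strings.
#'
#' @name codons
NULL

.CODON_BASES <- c("A", "C", "G", "U")

.all_codons <- function() {
  b <- .CODON_BASES
  as.vector(vapply(b, function(x) vapply(b, function(y)
    paste0(x, y, rep(b, 1L)), character(4L)), matrix("", 4L, 4L)))
}

# fixed lookup table, built once at load time
.CODONS <- {
  b <- .CODON_BASES
  out <- character(64)
  for (i in 0:63)
    out[i + 1L] <- paste0(b[i %/% 16 + 1L], b[(i %/% 4) %% 4 + 1L], b[i %% 4 + 1L])
  out
}

#' @describeIn codons the three stop codons.
#' @export
stop_codons <- function() c("UAA", "UAG", "UGA")

#' @describeIn codons the 61 sense codons, in lexicographic (A<C<G<U) order.
#' @export
sense_codons <- function() setdiff(.CODONS, stop_codons())

#' Convert codon strings to internal 0-based codes and back
#'
#' @param codon character vector of three-letter RNA codons.
#' @param code integer vector of codes in 0..63.
#' @return `codon_code()` returns integer codes; `codon_string()` returns
#'   codon strings.
#' @keywords internal
codon_code <- function(codon) {
  codon <- toupper(gsub("T", "U", codon))
  idx <- match(codon, .CODONS)
  if (anyNA(idx)) {
    bad <- unique(codon[is.na(idx)])
    stop("unknown codon symbol(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' @rdname codon_code
#' @keywords internal
codon_string <- function(code) {
  stopifnot(all(code >= 0L & code <= 63L))
  .CODONS[code + 1L]
}
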