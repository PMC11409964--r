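#' @keywords internal
"_PACKAGE"

## The 20 standard one-letter amino-acid codes. Everything downstream of the
## readers assumes sequences are drawn from this alphabet.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Test whether strings use only the 20 standard amino-acid letters
#'
#' @param x character vector of (already uppercased) sequences.
#' @return logical vector, one element per input string.
#' @keywords internal
is_standard_aa <- function(x) {
  !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), x)
}

## First offending offset within a sequence, NA if clean. Used for error
## messages that name the record and position.
first_bad_offset <- function(seq) {
  m <- regexpr(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), seq)
  if (m < 0L) NA_integer_ else as.integer(m)
}

assert_hla_class <- function(hla_class) {
  if (!is.character(hla_class) || length(hla_class) != 1L ||
      !hla_class %in% c("I", "II")) {
    stop("hla_class must be \"I\" or \"II\"", call. = FALSE)
  }
  hla_class
}

#' Peptide length bounds for an HLA class
#'
#' MHC-I ligands are counted at 8-12 residues and MHC-II ligands at 10-25
#' residues, the conventional bounds for eluted-ligand datasets.
#'
#' @param hla_class `"I"` or `"II"`.
#' @return integer vector `c(min, max)`.
#' @export
#' @examples
#' class_length_bounds("I")   # 8 12
#' class_length_bounds("II")  # 10 25
class_length_bounds <- function(hla_class) {
  assert_hla_class(hla_class)
  if (hla_class == "I") c(8L, 12L) else c(10L, 25L)
}
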