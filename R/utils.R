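#' @keywords internal
"_PACKAGE"

# Isotype vocabulary: the 20 amino acids plus initiator Met and suppressor.
AA_CODES <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "fMet", "Sup"
)

# Three-letter -> one-letter amino-acid code (cusp-style tables use one letter).
AA_THREE2ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", fMet = "M", Sup = "*"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Typed conditions so callers can distinguish bad files from bad arguments.
acn_stop <- function(msg, class, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "acn_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

stop_format     <- function(msg, ...) acn_stop(msg, "acn_format_error", ...)
stop_validation <- function(msg, ...) acn_stop(msg, "acn_validation_error", ...)
stop_argument   <- function(msg, ...) acn_stop(msg, "acn_argument_error", ...)
stop_degenerate <- function(msg, ...) acn_stop(msg, "acn_degenerate_error", ...)
stop_input      <- function(msg, ...) acn_stop(msg, "acn_input_error", ...)

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()]. Input is
#' uppercased first; output is uppercase DNA.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @examples
#' revcomp(c("TTT", "gct"))
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  ok <- nzchar(x) & is_dna(x)
  if (!all(ok)) stop_argument("revcomp(): input must be non-empty DNA strings")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All 1-based start positions of `pattern` in `x`, including overlapping
# occurrences (gregexpr would miss the second AGA in "AGAGA").
find_all_occurrences <- function(x, pattern) {
  n <- nchar(x); k <- nchar(pattern)
  if (k > n) return(integer())
  starts <- seq_len(n - k + 1L)
  starts[substring(x, starts, starts + k - 1L) == pattern]
}

# Deterministic 31-bit sub-seed from a master seed and a stable text label.
# Keeps independent streams for host genes / phages / CDS records so that
# extending a scenario does not perturb earlier draws.
derive_seed <- function(seed, label) {
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + (seed %% 50021) * 40503 + seed %% 997) %% 2147483647)
}
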