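# IUPAC nucleotide code tables shared across modules.

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- c(names(IUPAC_SETS), "-")

# bitmask encoding A=1 C=2 G=4 T=8; gap/N treated as missing (all states)
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

iupac_bits <- function(chars) {
  out <- integer(length(chars))
  for (i in seq_along(chars)) {
    s <- IUPAC_SETS[[chars[i]]]
    out[i] <- if (is.null(s)) 15L else sum(BASE_BITS[s])
  }
  out[chars == "-"] <- 15L
  out
}

is_unambiguous <- function(chars) chars %in% BASES

# complement preserving degeneracy
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

revcomp <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

normalize_seq <- function(seq) {
  s <- toupper(seq)
  gsub("U", "T", s, fixed = TRUE)
}
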