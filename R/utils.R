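#' @importFrom stringi stri_reverse stri_rand_strings stri_sub stri_sub<-
#'   stri_count_charclass stri_count_fixed stri_locate_first_fixed stri_detect_regex
#' @importFrom stats rgamma rlnorm rnorm runif rbinom optimize cor hclust
#'   cutree as.dist dist pbinom phyper dnbinom dbinom quantile p.adjust
#'   rmultinom setNames complete.cases ave sd
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", stri_reverse(x))
}

.randSeq <- function(n, len, seed = NULL) {
  stri_rand_strings(n, len, "[ACGT]")
}

# Deterministic sub-seed derivation; stays below 2^31.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483587) + 1L
}

# Sample a long random chromosome sequence quickly.
.randChromosome <- function(len) {
  codes <- c(65L, 67L, 71L, 84L)[sample.int(4L, len, replace = TRUE)]
  intToUtf8(codes)
}

# Hamming distances between equal-width character vectors and one reference
# sequence, via a character matrix.
.hammingToRef <- function(seqs, ref) {
  w <- nchar(ref)
  stopifnot(all(nchar(seqs) == w))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = w)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  colSums(m != r)
}

# Mutate one base at `pos` of each sequence to `to`.
.substituteAt <- function(seqs, pos, to) {
  stri_sub(seqs, pos, pos) <- to
  seqs
}
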