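## k-mer composition features: the classifier's input space.
## Each sequence becomes a concatenation of per-k blocks (k = 4, 5, 6 by
## default); each block is the relative frequency of the k-mers among the
## valid windows, so composition is comparable across fragment lengths.

.kmer_env <- new.env(parent = emptyenv())

## all 4^k words in Biostrings column order, and the canonical (reverse
## complement collapsed) grouping; cached per (k, rc_collapse)
.kmer_table <- function(k, rc_collapse) {
  key <- paste0(k, if (rc_collapse) "c" else "r")
  hit <- .kmer_env[[key]]
  if (!is.null(hit)) return(hit)
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  if (rc_collapse) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
    canon <- ifelse(words <= rc, words, rc)
    keys <- unique(canon[order(canon)])
    group <- match(canon, keys)
  } else {
    keys <- words
    group <- seq_along(words)
  }
  res <- list(words = words, keys = keys, group = group)
  .kmer_env[[key]] <- res
  res
}

#' Featurizer specification
#'
#' Describes the k-mer composition input space: which k values are counted
#' and whether a k-mer and its reverse complement are collapsed to one
#' canonical feature. Collapsing is the default because metagenome fragments
#' arrive on an arbitrary strand; it makes the representation strand
#' symmetric. Each k contributes one block of relative frequencies.
#'
#' @param k Strictly increasing positive integers (default `c(4, 5, 6)`).
#' @param rc_collapse Collapse reverse-complement pairs (default `TRUE`).
#' @return An object of class `"featurizer_spec"`.
#' @examples
#' feature_dimension(featurizer_spec())            # 2728
#' feature_dimension(featurizer_spec(rc_collapse = FALSE))  # 5376
#' @export
featurizer_spec <- function(k = c(4, 5, 6), rc_collapse = TRUE) {
  k <- as.integer(k)
  if (!length(k) || anyNA(k) || any(k < 1L) || any(diff(k) <= 0L)) {
    stop("'k' must be strictly increasing positive integers")
  }
  stopifnot(is.logical(rc_collapse), length(rc_collapse) == 1L)
  structure(list(k = k, rc_collapse = rc_collapse), class = "featurizer_spec")
}

#' @export
print.featurizer_spec <- function(x, ...) {
  cat("k-mer featurizer: k = {", paste(x$k, collapse = ", "), "}, ",
      if (x$rc_collapse) "canonical (reverse-complement collapsed)" else "raw strands",
      ", dimension ", feature_dimension(x), "\n", sep = "")
  invisible(x)
}

#' Dimension of the feature space
#'
#' With raw strands each k contributes `4^k` features; with canonical
#' collapsing each k contributes the number of reverse-complement
#' equivalence classes, `(4^k + 4^(k/2)) / 2` for even k (palindromes are
#' their own class) and `4^k / 2` for odd k.
#'
#' @param spec A [featurizer_spec()].
#' @return Positive integer.
#' @export
feature_dimension <- function(spec) {
  stopifnot(inherits(spec, "featurizer_spec"))
  per_k <- vapply(spec$k, function(k) {
    if (!spec$rc_collapse) return(4^k)
    if (k %% 2L == 0L) (4^k + 4^(k / 2)) / 2 else 4^k / 2
  }, numeric(1))
  as.integer(sum(per_k))
}

## normalize raw character input: uppercase, U -> T
.as_dna <- function(seq) {
  if (inherits(seq, "DNAStringSet")) return(seq)
  if (inherits(seq, "DNAString")) return(Biostrings::DNAStringSet(seq))
  nm <- names(seq)
  seq <- chartr("u", "T", toupper(as.character(seq)))
  out <- Biostrings::DNAStringSet(chartr("U", "T", seq))
  names(out) <- nm
  out
}

#' Count k-mers in a sequence
#'
#' Counts all windows of length `k` consisting only of A/C/G/T; windows
#' covering any other symbol (N and other IUPAC ambiguity codes) are
#' skipped. With `rc_collapse`, a window and its reverse complement
#' increment the same canonical key. Input is case insensitive and U is
#' read as T.
#'
#' @param seq A DNA string (character, `DNAString`, or a length-1
#'   `DNAStringSet`).
#' @param k Window length, >= 1. Windows longer than the sequence yield all
#'   zero counts.
#' @param rc_collapse Collapse reverse-complement pairs (default `TRUE`).
#' @return Named integer vector over all (canonical) k-mers.
#' @examples
#' count_kmers("AAAA", 4)["AAAA"]
#' @export
count_kmers <- function(seq, k, rc_collapse = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  dna <- .as_dna(seq)
  if (length(dna) != 1L) stop("'seq' must be a single sequence")
  tab <- .kmer_table(k, rc_collapse)
  if (Biostrings::width(dna)[1L] < k) {
    counts <- integer(length(tab$keys))
  } else {
    raw <- Biostrings::oligonucleotideFrequency(dna[[1L]], width = k)
    counts <- as.integer(rowsum(as.numeric(raw), tab$group))
  }
  names(counts) <- tab$keys
  counts
}

#' Convert sequences to composition feature vectors
#'
#' For each k in the spec, k-mer counts are divided by the number of valid
#' windows so the block is a probability vector (this is the length
#' normalization: composition, not raw counts). Blocks are concatenated in
#' k order. A block with no valid window (e.g. all-N stretch shorter than k)
#' is all zeros.
#'
#' @param seqs Character vector or `DNAStringSet` of DNA sequences; a single
#'   string is accepted.
#' @param spec A [featurizer_spec()].
#' @return Numeric matrix, one row per sequence, `feature_dimension(spec)`
#'   columns named by k-mer. For a single input sequence the matrix has one
#'   row.
#' @examples
#' x <- featurize("ACGTACGT", featurizer_spec(k = 2))
#' rowSums(x)  # each k block sums to 1
#' @export
featurize <- function(seqs, spec = featurizer_spec()) {
  stopifnot(inherits(spec, "featurizer_spec"))
  dna <- .as_dna(seqs)
  w <- Biostrings::width(dna)
  if (length(dna) && all(w < min(spec$k))) stop("sequence too short to featurize")
  blocks <- lapply(spec$k, function(k) {
    tab <- .kmer_table(k, spec$rc_collapse)
    raw <- Biostrings::oligonucleotideFrequency(dna, width = k, simplify.as = "matrix")
    if (length(dna) == 0L) raw <- matrix(0, 0L, 4^k)
    cnt <- t(rowsum(t(raw), tab$group))  # collapse columns to canonical keys
    colnames(cnt) <- tab$keys
    tot <- rowSums(cnt)
    cnt[tot > 0, ] <- cnt[tot > 0, , drop = FALSE] / tot[tot > 0]
    cnt
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- names(dna)
  x
}

#' Reverse complement of DNA strings
#'
#' @param seq Character vector of DNA.
#' @return Character vector.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(.as_dna(seq)))
}
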