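## Reference data handling: labelled genome collections, the clade-inclusion
## rule for generic models, non-overlapping fragment sampling, and pooling of
## user-supplied sample-specific sequences.

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Labelled reference sequence collection
#'
#' A set of sequences (typically genomes, draft assemblies or long contigs)
#' each mapped to the lowest corresponding node of a model taxonomy.
#' Provenance distinguishes public reference genomes from user-supplied
#' sample-specific sequences, which are treated preferentially by the
#' clade-inclusion rule and when pooling.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of DNA sequences (or `DNAStringSet`).
#' @param taxa Integer vector of taxonomy node identifiers.
#' @param provenance `"generic-reference"` or `"sample-specific"`; scalar or
#'   per-record vector.
#' @param tree Optional `taxonomy` to validate labels against.
#' @return An object of class `"reference_collection"`.
#' @export
reference_collection <- function(ids, seqs, taxa,
                                 provenance = "generic-reference", tree = NULL) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- as.character(ids)
  taxa <- as.integer(taxa)
  n <- length(ids)
  stopifnot(length(seqs) == n, length(taxa) == n)
  if (anyDuplicated(ids)) stop("duplicate sequence_id: ", ids[which(duplicated(ids))[1L]])
  provenance <- rep_len(match.arg(provenance,
                                  c("generic-reference", "sample-specific"),
                                  several.ok = TRUE), n)
  if (!is.null(tree)) .tax_index(tree, taxa)
  structure(list(ids = ids, seqs = unname(as.character(seqs)), taxa = taxa,
                 provenance = provenance),
            class = "reference_collection")
}

#' @export
print.reference_collection <- function(x, ...) {
  cat("Reference collection:", length(x$ids), "sequences,",
      sum(nchar(x$seqs)), "bp,", length(unique(x$taxa)), "taxa",
      sprintf("(%d sample-specific)\n", sum(x$provenance == "sample-specific")))
  invisible(x)
}

#' @export
length.reference_collection <- function(x) length(x$ids)

#' Select clades for a generic model
#'
#' Applies the inclusion rule for generic models: a taxonomy node is
#' modelled when its subtree contains at least `min_genomes` distinct
#' reference genomes. Sample-specific clades (and their ancestors) are
#' always included regardless of genome count, since the user asserts their
#' presence in the sample.
#'
#' @param refs A [reference_collection()]; each record counts as one genome.
#' @param tree The model `taxonomy`.
#' @param min_genomes Minimum distinct genomes in the subtree (default 3).
#' @return Sorted integer vector of selected node identifiers.
#' @export
select_model_clades <- function(refs, tree, min_genomes = 3L) {
  stopifnot(inherits(refs, "reference_collection"), inherits(tree, "taxonomy"))
  if (!length(refs$ids)) stop("empty reference collection")
  .tax_index(tree, refs$taxa)
  counts <- integer(length(tree$id))
  names(counts) <- tree$id
  ss_nodes <- integer(0)
  for (i in seq_along(refs$ids)) {
    lin <- lineage(tree, refs$taxa[i])
    counts[as.character(lin)] <- counts[as.character(lin)] + 1L
    if (refs$provenance[i] == "sample-specific") ss_nodes <- c(ss_nodes, lin)
  }
  sel <- tree$id[counts >= min_genomes]
  sort(unique(c(sel, ss_nodes)))
}

#' Sample non-overlapping fragments from a sequence
#'
#' Training data are equal amounts of non-overlapping fragments per taxon.
#' Fragment positions come from a maximal non-overlapping tiling of the
#' sequence, shuffled reproducibly under `rng_seed`, of which up to `budget`
#' tiles are taken. Sequences shorter than `fragment_length` yield an empty
#' result.
#'
#' @param seq A DNA string.
#' @param fragment_length Fragment length in bp.
#' @param budget Maximum number of fragments.
#' @param rng_seed Integer seed controlling the placement.
#' @return Character vector of fragments (possibly fewer than `budget`),
#'   with the 1-based start offsets as the `"start"` attribute.
#' @export
sample_fragments <- function(seq, fragment_length, budget, rng_seed = 1L) {
  fragment_length <- as.integer(fragment_length)
  stopifnot(fragment_length >= 1L, budget >= 0L)
  seq <- as.character(seq)
  L <- nchar(seq)
  n_tiles <- L %/% fragment_length
  if (n_tiles == 0L || budget == 0L) {
    out <- character(0)
    attr(out, "start") <- integer(0)
    return(out)
  }
  starts <- (seq_len(n_tiles) - 1L) * fragment_length + 1L
  starts <- with_seed(rng_seed, sample(starts))
  starts <- starts[seq_len(min(budget, n_tiles))]
  out <- substring(seq, starts, starts + fragment_length - 1L)
  attr(out, "start") <- starts
  out
}

## deepest selected clade on the lineage of each record's taxon, NA if none
.lowest_selected <- function(tree, taxa, clades) {
  vapply(taxa, function(v) {
    lin <- lineage(tree, v)
    hit <- lin[lin %in% clades]
    if (length(hit)) hit[length(hit)] else NA_integer_
  }, integer(1))
}

#' Build training sets at each fragment length
#'
#' For every training-fragment length, samples non-overlapping fragments
#' from the reference sequences of each selected clade — aiming at
#' `per_taxon_bp` bases per clade, equalized across clades — and featurizes
#' them. Each record contributes to the deepest selected clade on its
#' taxon's lineage. Clades whose sequences cannot host a single fragment at
#' some length are dropped from that length's set with a warning.
#'
#' @param refs A [reference_collection()].
#' @param clades Selected node identifiers (see [select_model_clades()]).
#' @param tree The model `taxonomy`.
#' @param spec A [featurizer_spec()].
#' @param lengths Training-fragment lengths in bp (default 1, 3, 5, 10, 15,
#'   50 kb).
#' @param per_taxon_bp Target sampled bases per clade and length (default
#'   100 kb, the amount found sufficient to model a sample population).
#' @param rng_seed Integer seed; fragment placement is reproducible from it.
#' @return List of `"training_set"` objects, one per length, each with
#'   elements `fragment_length`, `x` (feature matrix), `y` (clade labels)
#'   and `spec`.
#' @export
build_training_sets <- function(refs, clades, tree, spec = featurizer_spec(),
                                lengths = c(1000, 3000, 5000, 10000, 15000, 50000),
                                per_taxon_bp = 1e5, rng_seed = 1L) {
  stopifnot(inherits(refs, "reference_collection"), per_taxon_bp > 0)
  clades <- as.integer(clades)
  .tax_index(tree, clades)
  assigned <- .lowest_selected(tree, refs$taxa, clades)
  usable <- which(!is.na(assigned))
  if (!length(usable)) stop("no reference sequence maps to a selected clade")
  lengths <- sort(as.integer(lengths))
  lapply(lengths, function(flen) {
    budget_frags <- max(1L, per_taxon_bp %/% flen)
    frag_seqs <- character(0)
    frag_lab <- integer(0)
    for (cl in sort(unique(assigned[usable]))) {
      rec <- usable[assigned[usable] == cl]
      ## deterministic per-clade record order, then fill the budget
      rec <- rec[order(refs$ids[rec])]
      got <- character(0)
      for (ri in rec) {
        need <- budget_frags - length(got)
        if (need <= 0L) break
        fr <- sample_fragments(refs$seqs[ri], flen, need,
                               rng_seed = rng_seed + 7L * ri + flen %% 7919L)
        got <- c(got, fr)
      }
      if (!length(got)) {
        warning("clade ", cl, " has no usable sequence at fragment length ",
                flen, " bp; dropped from that training set")
        next
      }
      frag_seqs <- c(frag_seqs, got)
      frag_lab <- c(frag_lab, rep(cl, length(got)))
    }
    x <- featurize(frag_seqs, spec)
    rownames(x) <- NULL
    structure(list(fragment_length = flen, x = x, y = frag_lab, spec = spec),
              class = "training_set")
  })
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", nrow(x$x), "fragments of", x$fragment_length, "bp,",
      length(unique(x$y)), "clades\n")
  invisible(x)
}

#' Pool sample-specific sequences with generic reference data
#'
#' Sample-specific model construction pools the user's labelled sequences
#' (roughly 100 kb per expected population) with the generic reference
#' collection. User records win conflicts: a `sequence_id` present in both
#' collections keeps the user's record, with a warning when the labels
#' disagree; identical duplicate records collapse silently. The same
#' identifier carrying two different sequences is an error.
#'
#' @param generic_refs,user_refs [reference_collection()]s; `user_refs`
#'   records are marked `"sample-specific"`.
#' @return A pooled `reference_collection`.
#' @export
pool_sample_specific <- function(generic_refs, user_refs) {
  stopifnot(inherits(generic_refs, "reference_collection"),
            inherits(user_refs, "reference_collection"))
  if (!length(user_refs$ids)) return(generic_refs)
  both <- intersect(generic_refs$ids, user_refs$ids)
  for (id in both) {
    gi <- match(id, generic_refs$ids)
    ui <- match(id, user_refs$ids)
    if (!identical(generic_refs$seqs[gi], user_refs$seqs[ui])) {
      stop("sequence_id '", id, "' carries different sequences in the two collections")
    }
    if (generic_refs$taxa[gi] != user_refs$taxa[ui]) {
      warning("sequence_id '", id, "' relabelled ", generic_refs$taxa[gi],
              " -> ", user_refs$taxa[ui], " by sample-specific data")
    }
  }
  keep <- !(generic_refs$ids %in% both)
  reference_collection(
    ids = c(generic_refs$ids[keep], user_refs$ids),
    seqs = c(generic_refs$seqs[keep], user_refs$seqs),
    taxa = c(generic_refs$taxa[keep], user_refs$taxa),
    provenance = c(generic_refs$provenance[keep],
                   rep("sample-specific", length(user_refs$ids))))
}
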