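## User-facing file contracts: FASTA input with a size cap, "label:X"
## headers for sample-specific training data, the assignment TSV, multiplex
## merging, and rank-level abundance summaries.

#' Read a multi-FASTA query file
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header and must be unique. A configurable size cap (100 Mb by default,
#' matching the upload limit the assignment service enforces) guards
#' against oversized submissions; raise it for local use.
#'
#' @param path FASTA file.
#' @param max_mb Size cap in megabytes (default 100).
#' @return A `DNAStringSet` named by sequence identifier.
#' @export
read_fasta <- function(path, max_mb = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path) / 1e6
  if (sz > max_mb) {
    stop(sprintf("FASTA file is %.1f Mb, above the %g Mb cap", sz, max_mb))
  }
  dna <- Biostrings::readDNAStringSet(path)
  if (!length(dna)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dna))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[which(duplicated(ids))[1L]])
  }
  attr(dna, "headers") <- names(dna)
  names(dna) <- ids
  dna
}

#' Extract taxon labels from sample-specific FASTA headers
#'
#' Sample-specific training sequences declare their taxon in the header as
#' the literal token `label:X` with `X` a node identifier of the model
#' taxonomy. Every header must carry exactly one such token.
#'
#' @param headers Character vector of full FASTA headers.
#' @param tree Optional `taxonomy`; labels are then validated against it.
#' @return Named integer vector: sequence identifier (first header token)
#'   to node identifier.
#' @export
parse_sample_labels <- function(headers, tree = NULL) {
  ids <- sub("\\s.*$", "", headers)
  out <- integer(length(headers))
  for (i in seq_along(headers)) {
    m <- regmatches(headers[i], gregexpr("label:[^ \t]*", headers[i]))[[1L]]
    if (length(m) == 0L) stop("missing 'label:X' token in header: ", headers[i])
    if (length(m) > 1L) stop("multiple 'label:' tokens in header: ", headers[i])
    x <- sub("^label:", "", m)
    if (!grepl("^[0-9]+$", x)) {
      stop("label is not a non-negative integer in header: ", headers[i])
    }
    out[i] <- as.integer(x)
  }
  if (!is.null(tree)) {
    bad <- !(out %in% tree$id)
    if (any(bad)) {
      stop("label ", out[bad][1L], " not in the model taxonomy (header: ",
           headers[bad][1L], ")")
    }
  }
  stats::setNames(out, ids)
}

#' Read a labelled sample-specific FASTA into a reference collection
#'
#' @param path FASTA whose headers carry `label:X` tokens.
#' @param tree The model `taxonomy`.
#' @param max_mb Size cap passed to [read_fasta()].
#' @return A [reference_collection()] with provenance `"sample-specific"`.
#' @export
read_labeled_fasta <- function(path, tree, max_mb = 100) {
  dna <- read_fasta(path, max_mb = max_mb)
  labels <- parse_sample_labels(attr(dna, "headers"), tree)
  reference_collection(names(dna), as.character(dna), unname(labels),
                       provenance = "sample-specific", tree = tree)
}

#' Write or read an assignment table
#'
#' The assignment TSV is the tool's primary output: one row per assigned
#' input sequence with columns `sequence_id`, `length_bp`, `predicted_node`,
#' `predicted_rank`, `lineage` (root-to-node identifiers, semicolon-joined)
#' and `score`, preceded by a `#fingerprint=` comment line recording the
#' model that produced it. The written file re-parses to identical records.
#'
#' @param assignments A `"phylosvm_assignments"` data frame.
#' @param path Output TSV path.
#' @return `write_assignments` returns `path` invisibly; `read_assignments`
#'   the assignment data frame with the fingerprint attribute restored.
#' @export
write_assignments <- function(assignments, path) {
  fp <- attr(assignments, "fingerprint")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fingerprint=", if (is.null(fp)) "" else fp), con)
  utils::write.table(as.data.frame(assignments), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  first <- readLines(path, n = 1L)
  fp <- if (startsWith(first, "#fingerprint=")) sub("^#fingerprint=", "", first) else NULL
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character", "numeric"))
  attr(out, "fingerprint") <- fp
  class(out) <- c("phylosvm_assignments", "data.frame")
  out
}

#' Read a two-column truth TSV
#'
#' @param path TSV with columns sequence_id and node identifier (no header).
#' @param lengths Optional named vector of sequence lengths; otherwise a
#'   third column is expected.
#' @return A [truth_table()].
#' @export
read_truth_tsv <- function(path, lengths = NULL) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(lengths) && ncol(tb) < 3L) {
    stop("truth TSV has no length column and no 'lengths' were supplied")
  }
  len <- if (!is.null(lengths)) unname(lengths[as.character(tb[[1L]])]) else tb[[3L]]
  truth_table(tb[[1L]], tb[[2L]], len)
}

#' Merge assignment tables from a multiplex sample
#'
#' Large samples are submitted as multiple non-overlapping FASTA batches
#' classified with the same model; this utility merges the per-batch
#' assignment tables into one. Tables produced by different models (by
#' fingerprint) or sharing sequence identifiers are refused.
#'
#' @param paths Character vector of assignment TSV paths (or a list of
#'   assignment data frames).
#' @return One merged `"phylosvm_assignments"` data frame.
#' @export
combine_multiplex <- function(paths) {
  tabs <- if (is.character(paths)) lapply(paths, read_assignments) else paths
  if (!length(tabs)) stop("nothing to combine")
  fps <- vapply(tabs, function(t) {
    fp <- attr(t, "fingerprint")
    if (is.null(fp)) NA_character_ else fp
  }, "")
  if (anyNA(fps) || length(unique(fps)) != 1L) {
    stop("model fingerprint mismatch across batches; all batches must be ",
         "classified with the same model")
  }
  ids <- unlist(lapply(tabs, `[[`, "sequence_id"))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence_id across batches: ", ids[which(duplicated(ids))[1L]])
  }
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  attr(out, "fingerprint") <- fps[1L]
  class(out) <- c("phylosvm_assignments", "data.frame")
  out
}

#' Rank-level abundance summary
#'
#' Maps every assignment to the requested rank and tallies sequences and
#' bases per clade. Sequences that were declined or assigned above the
#' requested rank fall into the `"Other"` bucket, so the totals over clades
#' plus Other always equal the totals over inputs (a conservation law, per
#' rank).
#'
#' @param assignments A `"phylosvm_assignments"` data frame.
#' @param tree The model `taxonomy`.
#' @param rank One of [major_ranks()].
#' @return `data.frame` with columns `clade` (node identifier as character,
#'   or `"Other"`), `n_sequences`, `n_bases`.
#' @export
summarize_abundance <- function(assignments, tree, rank) {
  if (!nrow(assignments)) stop("empty assignment set")
  mapped <- rep(NA_integer_, nrow(assignments))
  ok <- !is.na(assignments$predicted_node)
  mapped[ok] <- map_to_rank(tree, assignments$predicted_node[ok], rank)
  key <- ifelse(is.na(mapped), "Other", as.character(mapped))
  agg <- stats::aggregate(
    cbind(n_sequences = rep(1L, length(key)),
          n_bases = assignments$length_bp),
    by = list(clade = key), FUN = sum)
  oth <- agg$clade == "Other"
  agg <- rbind(agg[!oth, , drop = FALSE][order(-agg$n_bases[!oth]), , drop = FALSE],
               agg[oth, , drop = FALSE])
  rownames(agg) <- NULL
  agg
}
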