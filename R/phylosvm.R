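#' Fit a hierarchical taxonomic classifier
#'
#' Fits the full composition-based taxonomic assignment model: an ensemble
#' of linear structured-output SVMs over a shared taxonomy, one member per
#' training-fragment length (1, 3, 5, 10, 15 and 50 kb by default). For a
#' generic model, clades with at least `min_genomes` reference genomes in
#' their subtree are modelled; for a sample-specific model, pool the user's
#' labelled sequences with [pool_sample_specific()] first — their clades are
#' always modelled. Equal amounts (about `per_taxon_bp`) of non-overlapping
#' fragments per clade are sampled at each length, featurized as
#' length-normalized k-mer composition (k = 4, 5, 6), and each member is
#' trained by margin-rescaling cutting planes with the geodesic taxonomy
#' distance as the loss. Default parameters are used for training; no
#' hyperparameter cross-validation is performed.
#'
#' @param refs A [reference_collection()] of labelled sequences.
#' @param tree The model `taxonomy`.
#' @param lengths Training-fragment lengths in bp.
#' @param spec A [featurizer_spec()].
#' @param per_taxon_bp Sampled bases per clade and length (default 100 kb).
#' @param min_genomes Clade-inclusion threshold for generic reference data
#'   (default 3 genomes).
#' @param reg_C Regularization constant of each member SVM (default 1000,
#'   matched to the small norms of L1-normalized composition vectors).
#' @param tol,max_iter Cutting-plane termination controls.
#' @param max_models_per_query At prediction time a query uses at most this
#'   many members (default 3), those trained at the query's length or longer.
#' @param seed Integer seed for fragment placement; given the seed the whole
#'   fit is deterministic.
#' @return An object of class `"phylosvm"`: a list with `members` (one
#'   `"structured_model"` per length), `tree`, `spec`, the selected
#'   `clades`, and a model `fingerprint` used to guard multiplex merges.
#' @seealso [predict.phylosvm()], [evaluate_assignments()], [make_benchmark()]
#' @examples
#' bench <- make_benchmark(tree_shape = c(2, 2), genome_length = 5e4,
#'                         n_test_fragments = 20, seed = 1)
#' fit <- phylosvm(bench$refs, bench$tree, lengths = c(1000, 3000),
#'                 per_taxon_bp = 2e4, seed = 1)
#' head(predict(fit, bench$test))
#' @export
phylosvm <- function(refs, tree,
                     lengths = c(1000, 3000, 5000, 10000, 15000, 50000),
                     spec = featurizer_spec(), per_taxon_bp = 1e5,
                     min_genomes = 3L, reg_C = 1000, tol = 1e-3,
                     max_iter = 1000L, max_models_per_query = 3L, seed = 1L) {
  stopifnot(inherits(refs, "reference_collection"), inherits(tree, "taxonomy"))
  lengths <- sort(unique(as.integer(lengths)))
  clades <- select_model_clades(refs, tree, min_genomes = min_genomes)
  clades <- setdiff(clades, tree$root)
  if (length(clades) < 2L) {
    stop("fewer than two modelled clades; provide more reference data or lower 'min_genomes'")
  }
  sets <- build_training_sets(refs, clades, tree, spec = spec,
                              lengths = lengths, per_taxon_bp = per_taxon_bp,
                              rng_seed = seed)
  members <- lapply(sets, train_structured, tree = tree, reg_C = reg_C,
                    tol = tol, max_iter = max_iter)
  names(members) <- vapply(members, function(m) as.character(m$training_length), "")
  obj <- structure(
    list(members = members, tree = tree, spec = spec, clades = clades,
         lengths = lengths, max_models_per_query = as.integer(max_models_per_query),
         per_taxon_bp = per_taxon_bp, reg_C = reg_C, seed = as.integer(seed),
         format_version = 1L),
    class = "phylosvm")
  obj$fingerprint <- model_fingerprint(obj)
  obj
}

#' Model fingerprint
#'
#' A short deterministic signature of a fitted model (taxonomy, feature
#' space, training lengths and weights), recorded in every assignment table
#' so that multiplex batches classified with different models are refused at
#' merge time.
#'
#' @param object A `"phylosvm"` model.
#' @return Character scalar.
#' @export
model_fingerprint <- function(object) {
  sums <- vapply(object$members, function(m) {
    w <- m$weights
    sum(w * rep_len(seq_len(7L), length(w)))
  }, numeric(1))
  paste0("psvm1-", length(object$tree$id), "-",
         paste(object$lengths, collapse = "."), "-",
         format(sum(abs(sums)) + sum(sums^2) %% 1e6, digits = 15))
}

#' @export
print.phylosvm <- function(x, ...) {
  cat("Hierarchical taxonomic classifier (structured SVM ensemble)\n")
  cat("  taxonomy: ", length(x$tree$id), " nodes, ", length(x$clades),
      " modelled clades\n", sep = "")
  cat("  features: k = {", paste(x$spec$k, collapse = ","), "}, dimension ",
      feature_dimension(x$spec), "\n", sep = "")
  cat("  members:  ", paste0(x$lengths / 1000, " kb", collapse = ", "),
      " (<= ", x$max_models_per_query, " per query)\n", sep = "")
  invisible(x)
}

#' @method summary phylosvm
#' @export
summary.phylosvm <- function(object, ...) {
  tab <- data.frame(
    training_length = object$lengths,
    n_train = vapply(object$members, function(m) as.integer(m$n_train), 1L),
    rounds = vapply(object$members, function(m) as.integer(m$n_iter), 1L),
    objective = vapply(object$members, function(m) m$objective, 1),
    row.names = NULL)
  structure(list(model = object, members = tab), class = "summary.phylosvm")
}

#' @export
print.summary.phylosvm <- function(x, ...) {
  print(x$model)
  cat("Member training summary:\n")
  print(x$members, row.names = FALSE)
  invisible(x)
}

#' @method coef phylosvm
#' @export
coef.phylosvm <- function(object, ...) {
  lapply(object$members, function(m) m$weights)
}

#' Predict taxonomic assignments for query fragments
#'
#' Classifies each query sequence with the (up to) three ensemble members
#' trained at its length or longer ([select_models_for_length()]), averaging
#' the joint lineage scores over the selected members and assigning the
#' arg-max node; ties break toward the root, then the smaller identifier.
#' With `margin > 0` an assignment is moved up to the deepest ancestor whose
#' score lead over the best node outside that ancestor's subtree is at least
#' `margin`, so low-confidence fragments are assigned at a higher level.
#'
#' Sequences shorter than `min_length` are declined (returned with `NA`
#' assignment) with a warning; assignments for sequences under 1000 bp are
#' accepted but a warning notes their lower expected accuracy.
#'
#' @param object A fitted `"phylosvm"` model.
#' @param newdata Named character vector of DNA sequences, a `DNAStringSet`,
#'   or a FASTA file path.
#' @param margin Non-negative score margin for the move-up rule (default 0,
#'   pure arg-max).
#' @param min_length Minimum query length in bp (default 100).
#' @param ... Unused.
#' @return A `data.frame` of class `"phylosvm_assignments"` with columns
#'   `sequence_id`, `length_bp`, `predicted_node`, `predicted_rank`,
#'   `lineage` (root-to-node identifiers, semicolon-joined) and `score`
#'   (ensemble-averaged joint score; `NA` throughout for declined
#'   sequences). The model fingerprint is attached as an attribute.
#' @export
predict.phylosvm <- function(object, newdata, margin = 0, min_length = 100L, ...) {
  if (is.character(newdata) && length(newdata) == 1L && file.exists(newdata) &&
      !grepl("^[ACGTUNacgtun]+$", newdata)) {
    newdata <- read_fasta(newdata)
  }
  dna <- .as_dna(newdata)
  if (is.null(names(dna)) || !all(nzchar(names(dna)))) {
    names(dna) <- paste0("seq", seq_along(dna))
  }
  w <- Biostrings::width(dna)
  declined <- w < max(min_length, min(object$spec$k))
  if (all(declined) && length(dna)) stop("all query sequences are below the minimum length")
  if (any(declined)) {
    warning(sum(declined), " sequence(s) below ", min_length,
            " bp were declined (unassigned)")
  }
  if (any(!declined & w < 1000L)) {
    warning("assignments for sequences shorter than 1000 bp are less accurate")
  }
  tree <- object$tree
  ids <- tree$id
  pred <- rep(NA_integer_, length(dna))
  score <- rep(NA_real_, length(dna))

  keep <- which(!declined)
  if (length(keep)) {
    X <- featurize(dna[keep], object$spec)
    sel <- vapply(w[keep], function(L) {
      paste(select_models_for_length(object, L), collapse = ",")
    }, "")
    for (grp in unique(sel)) {
      rows <- which(sel == grp)
      lens <- as.integer(strsplit(grp, ",")[[1L]])
      ## scores are computed one sequence at a time so that results do not
      ## depend on how a sample is batched (multiplex merges must reproduce
      ## the unsplit run exactly)
      S <- t(vapply(rows, function(r) {
        s <- 0
        for (l in lens) {
          mem <- object$members[[as.character(l)]]
          wal <- mem$weights[colnames(mem$A), , drop = FALSE]
          s <- s + as.vector(mem$A %*% (wal %*% X[r, ]))
        }
        s / length(lens)
      }, numeric(length(ids))))
      colnames(S) <- ids
      p <- .argmax_labels(tree, S)
      if (margin > 0) {
        for (r in seq_along(rows)) {
          p[r] <- .apply_margin(tree, S[r, ], p[r], margin)
        }
      }
      pi <- .tax_index(tree, p)
      pred[keep[rows]] <- p
      score[keep[rows]] <- S[cbind(seq_along(rows), pi)]
    }
  }
  out <- data.frame(
    sequence_id = names(dna),
    length_bp = w,
    predicted_node = pred,
    predicted_rank = ifelse(is.na(pred), NA_character_,
                            tree$rank[match(pred, tree$id)]),
    lineage = vapply(pred, function(p) {
      if (is.na(p)) NA_character_ else paste(lineage(tree, p), collapse = ";")
    }, ""),
    score = score,
    stringsAsFactors = FALSE)
  attr(out, "fingerprint") <- object$fingerprint
  class(out) <- c("phylosvm_assignments", "data.frame")
  out
}

## move an assignment up to the deepest ancestor whose lead over the best
## node outside its subtree is >= margin; the root always qualifies
.apply_margin <- function(tree, s, pred, margin) {
  lin <- rev(lineage(tree, pred))          # pred ... root
  smax <- s[match(pred, tree$id)]
  for (a in lin) {
    inside <- vapply(tree$id, function(v) a %in% lineage(tree, v), logical(1))
    if (all(inside)) return(a)             # root: nothing outside
    lead <- smax - max(s[!inside])
    if (lead >= margin) return(a)
  }
  tree$root
}

#' Save or load a fitted model archive
#'
#' The archive is a single RDS file holding the taxonomy, featurizer
#' specification, per-length weight matrices and training metadata, tagged
#' with a format version (`format_version = 1`).
#'
#' @param object A `"phylosvm"` model.
#' @param path File path.
#' @return `write_phylosvm` returns `path` invisibly; `read_phylosvm`
#'   returns the model.
#' @export
write_phylosvm <- function(object, path) {
  stopifnot(inherits(object, "phylosvm"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_phylosvm
#' @export
read_phylosvm <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "phylosvm")) stop("not a phylosvm model archive")
  if (is.null(obj$format_version) || obj$format_version > 1L) {
    stop("unsupported model archive version")
  }
  obj
}
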