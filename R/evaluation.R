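## Binning evaluation statistics: consistency (fragment- and base-pair
## weighted), taxonomic distance, per-rank accuracy, and the grouped report
## with micro and macro averages.

#' Truth table for evaluation
#'
#' @param sequence_id Character vector of fragment identifiers.
#' @param node Integer vector of correct taxonomy nodes.
#' @param length_bp Positive fragment lengths in bp.
#' @param tree Optional `taxonomy` to validate nodes against.
#' @return `data.frame` of class `"truth_table"`.
#' @export
truth_table <- function(sequence_id, node, length_bp, tree = NULL) {
  stopifnot(length(sequence_id) == length(node),
            length(sequence_id) == length(length_bp), all(length_bp > 0))
  if (!is.null(tree)) .tax_index(tree, node)
  out <- data.frame(sequence_id = as.character(sequence_id),
                    node = as.integer(node),
                    length_bp = as.integer(length_bp),
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

## align assignments with truth; drops declined (NA) assignments, errors on
## fragments missing from the truth table
.align_truth <- function(assignments, truth) {
  a <- assignments[!is.na(assignments$predicted_node), , drop = FALSE]
  if (!nrow(a)) stop("no assigned fragments to evaluate")
  hit <- match(a$sequence_id, truth$sequence_id)
  if (anyNA(hit)) {
    stop("no truth entry for: ", paste(utils::head(a$sequence_id[is.na(hit)], 5L),
                                       collapse = ", "))
  }
  data.frame(sequence_id = a$sequence_id,
             predicted = a$predicted_node,
             true = truth$node[hit],
             length_bp = truth$length_bp[hit],
             stringsAsFactors = FALSE)
}

#' Consistency of one assignment
#'
#' An assignment is consistent when the predicted node is the correct clade
#' itself or one of its parental clades. Because the root is an ancestor of
#' everything, consistency is a deliberately coarse measure and is read
#' together with the taxonomic distance.
#'
#' @param tree A `taxonomy`.
#' @param true_node,predicted_node Node identifiers (recycled pairwise).
#' @return Logical vector.
#' @export
is_consistent <- function(tree, true_node, predicted_node) {
  k <- max(length(true_node), length(predicted_node))
  true_node <- rep_len(as.integer(true_node), k)
  predicted_node <- rep_len(as.integer(predicted_node), k)
  vapply(seq_len(k), function(i) {
    .tax_index(tree, c(true_node[i], predicted_node[i]))
    predicted_node[i] %in% lineage(tree, true_node[i])
  }, logical(1))
}

#' Consistency score over an assignment set
#'
#' The fraction of sequence fragments (`weight = "fragments"`, Const_n_scaff)
#' or of base pairs (`weight = "bp"`, Const_n_bp) assigned consistently,
#' over the assigned fragments only. Higher base-pair than fragment
#' consistency indicates that longer sequences are classified more
#' consistently than short ones.
#'
#' @param assignments A `"phylosvm_assignments"` data frame (or any data
#'   frame with `sequence_id` and `predicted_node`).
#' @param truth A [truth_table()].
#' @param tree The evaluation `taxonomy`.
#' @param weight `"fragments"` or `"bp"`.
#' @return Fraction in `[0, 1]`.
#' @export
consistency_scores <- function(assignments, truth, tree,
                               weight = c("fragments", "bp")) {
  weight <- match.arg(weight)
  al <- .align_truth(assignments, truth)
  cons <- is_consistent(tree, al$true, al$predicted)
  if (weight == "fragments") mean(cons) else
    sum(al$length_bp[cons]) / sum(al$length_bp)
}

#' Mean taxonomic distance of assignments
#'
#' The mean geodesic (edge-count) distance between predicted and correct
#' nodes over the assigned fragments: the fine-grained companion to
#' consistency. With `mapped_rank`, both sides are first projected to that
#' rank — predictions already above the rank are compared as-is — and
#' fragments whose truth has no clade at that rank are excluded with a
#' warning.
#'
#' @inheritParams consistency_scores
#' @param mapped_rank Optional rank from [major_ranks()].
#' @return Non-negative mean distance.
#' @export
mean_taxonomic_distance <- function(assignments, truth, tree, mapped_rank = NULL) {
  al <- .align_truth(assignments, truth)
  if (!is.null(mapped_rank)) {
    tm <- map_to_rank(tree, al$true, mapped_rank)
    drop <- is.na(tm)
    if (any(drop)) {
      warning(sum(drop), " fragment(s) excluded: truth has no clade at rank '",
              mapped_rank, "'")
      al <- al[!drop, , drop = FALSE]
      tm <- tm[!drop]
    }
    pm <- map_to_rank(tree, al$predicted, mapped_rank)
    al$true <- tm
    al$predicted <- ifelse(is.na(pm), al$predicted, pm)
  }
  mean(geodesic_distance(tree, al$true, al$predicted))
}

#' Per-rank accuracy table
#'
#' For each of the seven major ranks, both truth and prediction are mapped
#' to that rank; a fragment is correct when both map and the mapped clades
#' coincide. Predictions that do not reach the rank (assigned above it)
#' count as incorrect there — at lower ranks the accuracy drop is then due
#' to unassigned rather than misassigned sequence. Accuracy is therefore
#' non-decreasing from species towards domain.
#'
#' @inheritParams consistency_scores
#' @param weight `"fragments"` or `"bp"`.
#' @return `data.frame` with columns `rank` and `accuracy` (fraction over
#'   all assigned fragments), species first.
#' @export
per_rank_accuracy <- function(assignments, truth, tree,
                              weight = c("fragments", "bp")) {
  weight <- match.arg(weight)
  al <- .align_truth(assignments, truth)
  wts <- if (weight == "fragments") rep(1, nrow(al)) else al$length_bp
  acc <- vapply(rev(MAJOR_RANKS), function(r) {
    tm <- map_to_rank(tree, al$true, r)
    pm <- map_to_rank(tree, al$predicted, r)
    ok <- !is.na(tm) & !is.na(pm) & tm == pm
    sum(wts[ok]) / sum(wts)
  }, numeric(1))
  data.frame(rank = rev(MAJOR_RANKS), accuracy = unname(acc),
             stringsAsFactors = FALSE)
}

#' Grouped evaluation report
#'
#' Emits one row per group (a clade, genome bin or population) with the
#' number of assigned fragments, fragment- and base-pair-weighted
#' consistency and mean taxonomic distance, plus a micro average (over all
#' fragments) and a macro average (unweighted over groups).
#'
#' @inheritParams consistency_scores
#' @param grouping Named vector or two-column data frame mapping
#'   `sequence_id` to a group label; fragments without a group are dropped.
#' @return `data.frame` of class `"evaluation_report"` with columns `group`,
#'   `n_assigned`, `consistency_fragments`, `consistency_bp`, `tax_dist`.
#' @export
grouped_report <- function(assignments, truth, tree, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(as.character(grouping[[2L]]),
                                as.character(grouping[[1L]]))
  }
  al <- .align_truth(assignments, truth)
  al$group <- unname(grouping[al$sequence_id])
  al <- al[!is.na(al$group), , drop = FALSE]
  if (!nrow(al)) stop("no assigned fragment belongs to a group")
  al$cons <- is_consistent(tree, al$true, al$predicted)
  al$dist <- geodesic_distance(tree, al$true, al$predicted)
  row_for <- function(sub, label) {
    data.frame(group = label,
               n_assigned = nrow(sub),
               consistency_fragments = mean(sub$cons),
               consistency_bp = sum(sub$length_bp[sub$cons]) / sum(sub$length_bp),
               tax_dist = mean(sub$dist),
               stringsAsFactors = FALSE)
  }
  groups <- sort(unique(al$group))
  rows <- do.call(rbind, lapply(groups, function(g) {
    row_for(al[al$group == g, , drop = FALSE], g)
  }))
  micro <- row_for(al, "micro_average")
  macro <- data.frame(group = "macro_average",
                      n_assigned = nrow(al),
                      consistency_fragments = mean(rows$consistency_fragments),
                      consistency_bp = mean(rows$consistency_bp),
                      tax_dist = mean(rows$tax_dist),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, micro, macro)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Assignment evaluation (consistency and taxonomic distance):\n")
  y <- x
  for (col in c("consistency_fragments", "consistency_bp", "tax_dist")) {
    y[[col]] <- round(y[[col]], digits)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' One-call evaluation of assignments against truth
#'
#' Convenience wrapper computing the headline statistics: both consistency
#' weightings, mean taxonomic distance, and the per-rank accuracy table in
#' both weightings.
#'
#' @inheritParams consistency_scores
#' @return List with elements `consistency_fragments`, `consistency_bp`,
#'   `mean_tax_dist`, `per_rank_fragments`, `per_rank_bp`, `n_assigned`.
#' @export
evaluate_assignments <- function(assignments, truth, tree) {
  al <- .align_truth(assignments, truth)
  list(
    n_assigned = nrow(al),
    consistency_fragments = consistency_scores(assignments, truth, tree, "fragments"),
    consistency_bp = consistency_scores(assignments, truth, tree, "bp"),
    mean_tax_dist = mean_taxonomic_distance(assignments, truth, tree),
    per_rank_fragments = per_rank_accuracy(assignments, truth, tree, "fragments"),
    per_rank_bp = per_rank_accuracy(assignments, truth, tree, "bp"))
}
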