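## Hierarchical structured SVM.
##
## Output space: all nodes of the taxonomy (internal nodes included, so a
## fragment can be assigned at a higher level). Joint feature map: a weight
## vector per non-root node; the score of label y is the sum of per-node
## linear scores along the lineage of y (path-sum construction), the root
## scoring 0. Training: 1-slack margin-rescaling cutting planes with the
## geodesic tree distance as the loss and exhaustive enumeration over the
## node set as the separation oracle.

## ancestor indicator A: (all nodes) x (non-root nodes); A[y, v] = 1 iff v is
## on lineage(y). Joint scores for all labels = per-node scores %*% t(A).
.ancestor_matrix <- function(tree) {
  ids <- tree$id
  nonroot <- ids[ids != tree$root]
  A <- matrix(0, length(ids), length(nonroot), dimnames = list(ids, nonroot))
  for (y in ids) {
    lin <- setdiff(lineage(tree, y), tree$root)
    if (length(lin)) A[as.character(y), as.character(lin)] <- 1
  }
  A
}

## column order that realizes the tie-break "nearer the root, then smaller
## node id": stable first-max over columns sorted by (depth, id)
.tiebreak_order <- function(tree) order(tree$depth, tree$id)

## argmax over label columns of a score matrix with the canonical tie-break;
## `scores` columns follow tree$id order. Returns node ids.
.argmax_labels <- function(tree, scores, tol = 1e-9) {
  ord <- .tiebreak_order(tree)
  s <- scores[, ord, drop = FALSE]
  ## first column within tol of the row max, in tie-break order
  mx <- apply(s, 1L, max)
  pick <- max.col(s >= mx - tol, ties.method = "first")
  tree$id[ord][pick]
}

#' Joint score of a label for one feature vector
#'
#' The score of assigning label node `y` to feature vector `x` is the sum of
#' the per-node linear scores `w_v . x` over the non-root nodes `v` on the
#' lineage of `y`; the root scores 0. Hierarchical coherence follows:
#' `score(x, child) - score(x, parent) = w_child . x`.
#'
#' @param model A `"structured_model"` (see [train_structured()]).
#' @param x Numeric feature vector of the model's dimension.
#' @param y Label node identifier.
#' @return Numeric scalar.
#' @export
joint_score <- function(model, x, y) {
  stopifnot(inherits(model, "structured_model"))
  if (length(x) != ncol(model$weights)) stop("feature dimension mismatch")
  lin <- setdiff(lineage(model$tree, y), model$tree$root)
  if (!length(lin)) return(0)
  sum(model$weights[as.character(lin), , drop = FALSE] %*% x)
}

## joint scores for all labels: X (n x d) -> (n x n_nodes), columns in
## tree$id order
.joint_scores <- function(model, X) {
  W <- model$weights[colnames(model$A), , drop = FALSE]  # align rows to A
  P <- X %*% t(W)                        # per non-root node scores
  S <- P %*% t(model$A)                  # accumulate along lineages
  colnames(S) <- rownames(model$A)
  S
}

#' Most violated label (separation oracle)
#'
#' For margin rescaling the most violated constraint for an example is the
#' label maximizing `loss(y_true, y) + score(x, y) - score(x, y_true)`,
#' found by exhaustive enumeration over every taxonomy node. Ties break
#' toward the node nearer the root, then toward the smaller identifier.
#'
#' @param model A `"structured_model"`.
#' @param x Feature vector.
#' @param y_true True label node identifier.
#' @return Node identifier of the maximizer.
#' @export
find_most_violated <- function(model, x, y_true) {
  tree <- model$tree
  i_true <- .tax_index(tree, y_true)
  S <- .joint_scores(model, matrix(x, nrow = 1L))
  v <- model$distmat[i_true, ] + S[1L, ] - S[1L, i_true]
  .argmax_labels(tree, matrix(v, nrow = 1L))
}

## deterministic pairwise coordinate ascent for the dual QP
##   min 0.5 a' Q a - b' a   s.t.  a >= 0, sum(a) <= C
## Single-coordinate moves (paired with the slack of the sum constraint),
## plus exchange moves against the steepest-descent coordinate when the sum
## constraint is active. Supports warm starts (`a0`), which makes re-solves
## inside the cutting-plane loop cheap.
.solve_qp_simplex <- function(Q, b, C, a0 = NULL, tol = 1e-8, max_sweeps = 500L) {
  m <- length(b)
  a <- if (is.null(a0)) numeric(m) else pmax(a0, 0)
  if (m == 0L) return(a)
  if (sum(a) > C) a <- a * (C / sum(a))
  Qa <- as.vector(Q %*% a)
  ## exchange a_j -> a_k keeping the sum fixed; returns the largest move
  pairwise_pass <- function() {
    delta <- 0
    for (j in seq_len(m)) {
      for (k in seq_len(m)) {
        if (j == k) next
        h <- Q[j, j] + Q[k, k] - 2 * Q[j, k]
        if (h <= 0) next
        gr_j <- Qa[j] - b[j]
        gr_k <- Qa[k] - b[k]
        t_star <- min(max((gr_j - gr_k) / h, -a[k]), a[j])
        if (t_star != 0) {
          a[j] <<- a[j] - t_star
          a[k] <<- a[k] + t_star
          Qa <<- Qa + t_star * (Q[, k] - Q[, j])
          delta <- max(delta, abs(t_star))
        }
      }
    }
    delta
  }
  eps <- tol * max(1, C)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (Q[j, j] <= 0) next
      room <- C - sum(a) + a[j]
      aj <- min(max(a[j] - (Qa[j] - b[j]) / Q[j, j], 0), room)
      step <- aj - a[j]
      if (step != 0) {
        a[j] <- aj
        Qa <- Qa + step * Q[, j]
        delta <- max(delta, abs(step))
      }
    }
    if (delta < eps) {
      ## only pair exchanges can still improve once singles stall (the sum
      ## constraint couples the coordinates); stop when they stall too
      if (pairwise_pass() < eps) break
    }
  }
  a
}

#' Train one structured SVM
#'
#' Fits the linear structured-output model for one training-fragment length
#' by 1-slack margin-rescaling cutting planes: at each round the separation
#' oracle ([find_most_violated()]) builds one aggregated constraint from the
#' per-example most violated labels; the dual quadratic program over the
#' working set is re-solved (to tolerance 1e-8) and the procedure stops when
#' the newest constraint is violated by less than `tol`. The loss is the
#' geodesic distance on the taxonomy. Training is deterministic: the same
#' training set yields bit-identical weights.
#'
#' @param training_set A `"training_set"` (see [build_training_sets()]), or a
#'   list with elements `x` (feature matrix), `y` (labels) and
#'   `fragment_length`.
#' @param tree The model `taxonomy`.
#' @param reg_C Regularization constant C > 0 (default 1000; no
#'   hyperparameter cross-validation is performed — defaults are used
#'   throughout). The scale suits L1-normalized composition vectors, whose
#'   norms are small (~0.1) while the loss is on the edge-count scale, so
#'   attainable margins require a weight norm well above 1.
#' @param tol Cutting-plane termination tolerance (default 1e-3).
#' @param max_iter Maximum cutting-plane rounds (default 1000).
#' @return An object of class `"structured_model"` with the per-node weight
#'   matrix (`weights`, rows = non-root nodes), the achieved primal
#'   objective, and training metadata.
#' @export
train_structured <- function(training_set, tree, reg_C = 1000, tol = 1e-3,
                             max_iter = 1000L) {
  X <- training_set$x
  y <- as.integer(training_set$y)
  stopifnot(is.matrix(X), nrow(X) == length(y), reg_C > 0, tol > 0)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (length(unique(y)) < 2L) stop("training requires at least two distinct labels")
  n <- nrow(X)
  d <- ncol(X)
  iy <- .tax_index(tree, y)

  nonroot <- tree$id[tree$id != tree$root]
  A <- .ancestor_matrix(tree)
  distmat <- .tax_distmat(tree)
  model <- structure(
    list(tree = tree, weights = matrix(0, length(nonroot), d,
                                       dimnames = list(nonroot, NULL)),
         A = A, distmat = distmat, spec = training_set$spec,
         training_length = training_set$fragment_length,
         reg_C = reg_C, trained = FALSE),
    class = "structured_model")

  ## per-example loss rows and true-label ancestor rows
  L <- distmat[iy, , drop = FALSE]                 # n x nodes
  At <- A[iy, , drop = FALSE]                      # n x nonroot
  XtA <- crossprod(X, At)                          # d x nonroot, reused

  ## working set of cutting planes, preallocated (rows beyond `m` unused)
  p <- length(nonroot) * d
  cap <- 256L
  Gmat <- matrix(0, cap, p)
  Q <- matrix(0, cap, cap)                         # Gram matrix of the planes
  bvec <- numeric(cap)
  alpha <- numeric(0)
  idle <- integer(0)                               # rounds since alpha > 0
  m <- 0L
  objective <- 0
  wvec <- numeric(p)
  for (iter in seq_len(max_iter)) {
    S <- .joint_scores(model, X)                   # n x nodes
    viol <- L + S - S[cbind(seq_len(n), iy)]
    yhat <- .argmax_labels(tree, viol)
    ihat <- .tax_index(tree, yhat)
    ## current slack and the new constraint's violation
    xi <- if (m) max(0, max(bvec[1:m] - Gmat[1:m, , drop = FALSE] %*% wvec)) else 0
    new_viol <- mean(viol[cbind(seq_len(n), ihat)])
    if (new_viol <= xi + tol) break
    ## aggregate constraint: g = mean_i x_i (x) (a(y_i) - a(yhat_i)), loss mean
    Ah <- A[ihat, , drop = FALSE]
    Gnew <- as.vector(crossprod(X, At - Ah)) / n   # d x nonroot, vectorized
    bnew <- mean(L[cbind(seq_len(n), ihat)])
    if (m == cap) {                                # grow the buffers
      cap <- cap * 2L
      G2 <- matrix(0, cap, p); G2[1:m, ] <- Gmat[1:m, ]; Gmat <- G2
      Q2 <- matrix(0, cap, cap); Q2[1:m, 1:m] <- Q[1:m, 1:m]; Q <- Q2
      b2 <- numeric(cap); b2[1:m] <- bvec[1:m]; bvec <- b2
    }
    m <- m + 1L
    Gmat[m, ] <- Gnew
    bvec[m] <- bnew
    cross <- if (m > 1L) as.vector(Gmat[1:(m - 1L), , drop = FALSE] %*% Gnew) else numeric(0)
    Q[m, 1:m] <- c(cross, sum(Gnew * Gnew))
    Q[1:m, m] <- Q[m, 1:m]
    alpha <- .solve_qp_simplex(Q[1:m, 1:m, drop = FALSE], bvec[1:m], reg_C,
                               a0 = c(alpha, 0))
    wvec <- as.vector(crossprod(Gmat[1:m, , drop = FALSE], alpha))
    ## wvec is laid out feature-major (d x nonroot, vectorized)
    model$weights <- t(matrix(wvec, d, length(nonroot)))
    rownames(model$weights) <- nonroot
    xi <- max(0, max(bvec[1:m] - Gmat[1:m, , drop = FALSE] %*% wvec))
    objective <- 0.5 * sum(wvec^2) + reg_C * xi
    ## prune planes whose multiplier has been zero for 50 rounds
    idle <- ifelse(alpha <= 1e-12, c(idle, 0L) + 1L, 0L)
    keep <- idle < 50L
    if (!all(keep)) {
      k <- sum(keep)
      Gmat[1:k, ] <- Gmat[(1:m)[keep], ]
      bvec[1:k] <- bvec[(1:m)[keep]]
      Q[1:k, 1:k] <- Q[(1:m)[keep], (1:m)[keep]]
      alpha <- alpha[keep]
      idle <- idle[keep]
      m <- k
    }
  }
  model$trained <- TRUE
  model$objective <- objective
  model$n_iter <- iter
  model$n_train <- n
  model
}

.vec_w <- function(model) as.vector(model$weights)

#' @export
print.structured_model <- function(x, ...) {
  cat("Structured SVM (", x$training_length, " bp fragments): ",
      nrow(x$weights), " node weight vectors x ", ncol(x$weights),
      " features; C = ", x$reg_C,
      if (isTRUE(x$trained)) paste0("; trained in ", x$n_iter, " rounds") else "; untrained",
      "\n", sep = "")
  invisible(x)
}

#' Select ensemble members for a query length
#'
#' A test fragment is classified by at most `max_models` member SVMs, those
#' built with training fragments of the same length as the query or longer —
#' the closest such lengths. A query longer than every training length falls
#' back to the single longest-fragment member.
#'
#' @param ensemble A `"phylosvm"` model (see [phylosvm()]).
#' @param query_length Query sequence length in bp.
#' @param max_models Maximum members (default the ensemble's setting, 3).
#' @return Integer vector of selected training lengths, shortest first.
#' @examples
#' \dontrun{
#' select_models_for_length(fit, 4000)   # c(5000, 10000, 15000)
#' }
#' @export
select_models_for_length <- function(ensemble, query_length,
                                     max_models = ensemble$max_models_per_query) {
  lens <- sort(unname(vapply(ensemble$members, `[[`, numeric(1), "training_length")))
  elig <- lens[lens >= query_length]
  if (!length(elig)) return(max(lens))
  utils::head(elig, max_models)
}
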