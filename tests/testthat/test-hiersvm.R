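# hand-constructable chain: root 1 -> mid 2 -> leaf 3
chain3 <- function() taxonomy(id = c(1, 2, 3), parent = c(NA, 1, 2))

# model with prescribed weights (rows named by non-root node id)
manual_model <- function(tree, W, spec = NULL) {
  structure(list(tree = tree, weights = W,
                 A = phylosvm:::.ancestor_matrix(tree),
                 distmat = phylosvm:::.tax_distmat(tree),
                 spec = spec, training_length = 1000L, trained = TRUE),
            class = "structured_model")
}

test_that("joint score is the path sum of per-node linear scores", {
  tr <- chain3()
  W <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c(2, 3), NULL))
  m <- manual_model(tr, W)
  x <- c(1, 1)
  expect_equal(joint_score(m, x, 1), 0)               # root scores zero
  expect_equal(joint_score(m, x, 2), 1 + 3)
  expect_equal(joint_score(m, x, 3), (1 + 3) + (2 + 4))
  # zero weights score zero everywhere
  m0 <- manual_model(tr, matrix(0, 2, 2, dimnames = list(c(2, 3), NULL)))
  for (y in tr$id) expect_equal(joint_score(m0, c(5, -2), y), 0)
  expect_error(joint_score(m, c(1, 2, 3), 3), "dimension mismatch")
})

test_that("hierarchical coherence: child minus parent score is the child block", {
  tr <- toy5()
  set.seed(21)
  W <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(c(2, 3, 4, 5), NULL))
  m <- manual_model(tr, W)
  x <- rnorm(3)
  for (v in c(2, 3, 4, 5)) {
    p <- tr$parent[match(v, tr$id)]
    expect_equal(joint_score(m, x, v) - joint_score(m, x, p),
                 sum(W[as.character(v), ] * x))
  }
})

test_that("separation oracle maximizes loss-augmented score with root-first ties", {
  tr <- toy5()
  W0 <- matrix(0, 4, 2, dimnames = list(c(2, 3, 4, 5), NULL))
  m0 <- manual_model(tr, W0)
  # zero weights: argmax of the loss alone = node at maximal distance
  expect_identical(find_most_violated(m0, c(1, 1), 3),
                   bf_argmax(tr, phylosvm:::.tax_distmat(tr)[match(3, tr$id), ]))
  expect_identical(find_most_violated(m0, c(1, 1), 3), 5L)

  # overwhelming true-label score: the oracle returns the true label
  Wbig <- W0; Wbig["3", ] <- 1e6
  mbig <- manual_model(tr, Wbig)
  expect_identical(find_most_violated(mbig, c(1, 1), 3), 3L)
})

test_that("separation oracle agrees with an independent enumerator on random models", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- rand_tree(sample(4:12, 1L), seed + 50)
    d <- sample(2:5, 1L)
    nonroot <- tr$id[tr$id != tr$root]
    W <- matrix(rnorm(length(nonroot) * d), length(nonroot), d,
                dimnames = list(nonroot, NULL))
    m <- manual_model(tr, W)
    D <- phylosvm:::.tax_distmat(tr)
    x <- rnorm(d)
    y_true <- sample(tr$id, 1L)
    scores <- bf_label_scores(tr, W, x)
    aug <- D[match(y_true, tr$id), ] + scores - scores[match(y_true, tr$id)]
    expect_identical(find_most_violated(m, x, y_true), bf_argmax(tr, aug))
  }
})

test_that("training fits separable data to zero empirical loss", {
  # three clades under the root, orthogonal one-hot features
  tr <- taxonomy(id = 1:4, parent = c(NA, 1, 1, 1))
  X <- diag(3)[rep(1:3, each = 6L), ]
  ts <- list(x = X, y = rep(2:4, each = 6L), fragment_length = 1000L, spec = NULL)
  m <- train_structured(ts, tr)
  expect_true(m$trained)
  S <- phylosvm:::.joint_scores(m, X)
  pred <- phylosvm:::.argmax_labels(tr, S)
  expect_identical(pred, ts$y)
  emp_loss <- mean(geodesic_distance(tr, ts$y, pred))
  expect_identical(emp_loss, 0)
})

test_that("contradictory examples terminate with positive training loss", {
  tr <- chain3()
  X <- matrix(1, 4, 2)
  ts <- list(x = X, y = c(2L, 3L, 2L, 3L), fragment_length = 1000L, spec = NULL)
  m <- train_structured(ts, tr, max_iter = 200)
  S <- phylosvm:::.joint_scores(m, X)
  pred <- phylosvm:::.argmax_labels(tr, S)
  expect_gt(mean(geodesic_distance(tr, ts$y, pred)), 0)
})

test_that("vanishing regularization drives weights to zero and ties to the root", {
  tr <- chain3()
  set.seed(31)
  X <- matrix(rnorm(8), 4, 2)
  ts <- list(x = X, y = c(2L, 3L, 2L, 3L), fragment_length = 1000L, spec = NULL)
  m <- train_structured(ts, tr, reg_C = 1e-12, max_iter = 50)
  expect_lt(max(abs(m$weights)), 1e-6)
  S <- phylosvm:::.joint_scores(m, X)
  expect_true(all(phylosvm:::.argmax_labels(tr, S) == tr$root))
})

test_that("training refuses degenerate inputs", {
  tr <- chain3()
  ts1 <- list(x = matrix(1, 3, 2), y = c(2L, 2L, 2L),
              fragment_length = 1000L, spec = NULL)
  expect_error(train_structured(ts1, tr), "two distinct labels")
  ts2 <- list(x = matrix(c(1, NA, 1, 1), 2, 2), y = c(2L, 3L),
              fragment_length = 1000L, spec = NULL)
  expect_error(train_structured(ts2, tr), "non-finite")
})

test_that("training is deterministic: identical input, identical weights", {
  tr <- toy5()
  set.seed(41)
  X <- matrix(rnorm(40), 10, 4)
  ts <- list(x = X, y = sample(c(3L, 4L, 5L), 10, replace = TRUE),
             fragment_length = 1000L, spec = NULL)
  m1 <- train_structured(ts, tr)
  m2 <- train_structured(ts, tr)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$objective, m2$objective)
})

test_that("the dual QP solver matches an interior-point reference", {
  skip_if_not_installed("kernlab")
  qp_value <- function(a, Q, b) 0.5 * sum(a * (Q %*% a)) - sum(b * a)
  for (seed in 1:10) {
    set.seed(seed)
    m <- sample(2:8, 1L)
    M <- matrix(rnorm(m * m), m)
    Q <- crossprod(M) + diag(1e-6, m)
    b <- runif(m, 0, 2)
    C <- runif(1, 0.5, 5)
    mine <- phylosvm:::.solve_qp_simplex(Q, b, C)
    expect_true(all(mine >= -1e-10))
    expect_lte(sum(mine), C + 1e-8)
    ref <- kernlab::primal(kernlab::ipop(
      c = -b, H = Q, A = matrix(1, 1, m), b = 0, l = rep(0, m),
      u = rep(C, m), r = C, sigf = 9))
    # our deterministic solver should be at least as good as the reference
    expect_lte(qp_value(mine, Q, b), qp_value(ref, Q, b) + 1e-6)
  }
})

test_that("achieved objective is non-decreasing in the slack penalty C", {
  tr <- chain3()
  set.seed(51)
  X <- rbind(matrix(rnorm(10, 1), 5, 2), matrix(rnorm(10, -1), 5, 2)) / 3
  ts <- list(x = X, y = rep(c(2L, 3L), each = 5L),
             fragment_length = 1000L, spec = NULL)
  o <- vapply(c(0.1, 1, 10), function(C) {
    train_structured(ts, tr, reg_C = C)$objective
  }, numeric(1))
  expect_true(all(diff(o) >= -1e-8))
})

test_that("ensemble member selection follows the same-length-or-longer rule", {
  fx <- tiny_fit()
  fit <- fx$fit
  # synthetic ensemble with the six default lengths
  fake <- fit
  fake$members <- lapply(c(1000, 3000, 5000, 10000, 15000, 50000),
                         function(l) list(training_length = l))
  names(fake$members) <- vapply(fake$members, function(m) as.character(m$training_length), "")
  expect_identical(select_models_for_length(fake, 4000), c(5000, 10000, 15000))
  expect_identical(select_models_for_length(fake, 1000), c(1000, 3000, 5000))
  expect_identical(select_models_for_length(fake, 60000), 50000)
  expect_identical(select_models_for_length(fake, 15000), c(15000, 50000))
})

test_that("ensemble prediction equals brute-force enumeration of averaged scores", {
  fx <- tiny_fit()
  fit <- fx$fit
  bench <- fx$bench
  qs <- bench$test[1:8]
  asg <- predict(fit, qs)
  X <- featurize(qs, fit$spec)
  for (i in seq_along(qs)) {
    lens <- select_models_for_length(fit, nchar(qs[i]))
    avg <- Reduce(`+`, lapply(as.character(lens), function(l) {
      bf_label_scores(fit$tree, fit$members[[l]]$weights, X[i, ])
    })) / length(lens)
    expect_identical(asg$predicted_node[i], bf_argmax(fit$tree, avg))
  }
})

test_that("single-member and duplicated-member ensembles predict identically", {
  fx <- tiny_fit()
  fit <- fx$fit
  qs <- fx$bench$test[1:5]
  one <- fit
  one$members <- fit$members["3000"]
  one$lengths <- 3000L
  twin <- fit
  m5 <- fit$members[["3000"]]
  m5$training_length <- 5000L
  twin$members <- list(`3000` = fit$members[["3000"]], `5000` = m5)
  twin$lengths <- c(3000L, 5000L)
  p1 <- predict(one, qs)$predicted_node
  p2 <- predict(twin, qs)$predicted_node
  expect_identical(p1, p2)  # averaging identical weights changes nothing
})

test_that("exactly cancelling members tie back to the root", {
  fx <- tiny_fit()
  fit <- fx$fit
  m1 <- fit$members[["3000"]]
  m2 <- m1
  m2$weights <- -m1$weights
  m2$training_length <- 5000L
  opp <- fit
  opp$members <- list(`3000` = m1, `5000` = m2)
  opp$lengths <- c(3000L, 5000L)
  p <- predict(opp, fx$bench$test[1:5])
  expect_true(all(p$predicted_node == fit$tree$root))
})

test_that("prediction enforces the minimum query length", {
  fx <- tiny_fit()
  expect_warning(p <- predict(fx$fit, c(long = strrep("ACGT", 500),
                                        short = "ACGTAC")),
                 "declined")
  expect_true(is.na(p$predicted_node[p$sequence_id == "short"]))
  expect_false(is.na(p$predicted_node[p$sequence_id == "long"]))
  expect_error(suppressWarnings(predict(fx$fit, c(only_short = "ACGT"))),
               "minimum length")
  # short-but-accepted queries warn about reduced accuracy
  expect_warning(predict(fx$fit, c(s = strrep("ACGT", 100))), "less accurate")
})

test_that("margin thresholding moves uncertain assignments toward the root", {
  fx <- tiny_fit()
  qs <- fx$bench$test[1:10]
  p0 <- predict(fx$fit, qs, margin = 0)
  phuge <- predict(fx$fit, qs, margin = 1e9)
  # an extreme margin demands an impossible lead: everything retreats to root
  expect_true(all(phuge$predicted_node == fx$fit$tree$root))
  # margined predictions are always ancestors-or-self of the raw argmax
  pmid <- predict(fx$fit, qs, margin = 0.5)
  for (i in seq_len(nrow(p0))) {
    expect_true(is_ancestor(fx$fit$tree, pmid$predicted_node[i],
                            p0$predicted_node[i]))
  }
})

test_that("model archives round-trip through serialization", {
  fx <- tiny_fit()
  path <- tempfile(fileext = ".rds")
  write_phylosvm(fx$fit, path)
  back <- read_phylosvm(path)
  expect_identical(coef(back), coef(fx$fit))
  expect_identical(model_fingerprint(back), model_fingerprint(fx$fit))
  saveRDS(list(), path)
  expect_error(read_phylosvm(path), "not a phylosvm model")
})
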