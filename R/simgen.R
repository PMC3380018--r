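## Synthetic community generator. Emulates the one property the classifier
## exploits: genomic signatures (k-mer composition) are more conserved
## between close relatives than distant ones. Each taxonomy leaf gets an
## order-3 Markov composition model obtained by perturbing its parent's
## model along every tree edge with Dirichlet noise, so expected
## compositional distance between leaves grows with their geodesic distance.

BASES <- c("A", "C", "G", "T")

#' Build clade-specific Markov composition models
#'
#' Starting from a root chain determined by `base_gc` (contexts are
#' i.i.d.-initialized to the GC-implied base distribution), every edge of
#' the taxonomy perturbs each conditional distribution with Dirichlet noise
#' of concentration `20 / divergence` times the parent probabilities, so a
#' larger `divergence` means noisier inheritance and better-separated
#' leaves; `divergence = 0` copies the parent exactly.
#'
#' @param tree A `taxonomy`.
#' @param base_gc GC content of the root model, in (0, 1).
#' @param divergence Non-negative per-edge perturbation dial (default 0.1).
#' @param order Markov order (default 3, so 4-6-mer features carry signal).
#' @param seed Integer seed; tables are reproducible from it.
#' @return Named list mapping leaf node identifier to an object of class
#'   `"composition_model"` (fields `order`, `transition` — a `4^order` x 4
#'   stochastic matrix — and `node_id`).
#' @export
make_clade_models <- function(tree, base_gc = 0.5, divergence = 0.1,
                              order = 3L, seed = 1L) {
  stopifnot(base_gc > 0, base_gc < 1, divergence >= 0, order >= 1L)
  nctx <- 4L^order
  p0 <- c((1 - base_gc) / 2, base_gc / 2, base_gc / 2, (1 - base_gc) / 2)
  root_tab <- matrix(p0, nctx, 4L, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  kids <- split(tree$id, factor(tree$parent, levels = tree$id))
  leaves <- tree$id[!(tree$id %in% tree$parent)]
  tabs <- list()
  with_seed(seed, {
    walk <- function(node, tab) {
      tabs[[as.character(node)]] <<- tab
      for (ch in sort(kids[[as.character(node)]])) {
        walk(ch, .perturb_table(tab, divergence))
      }
    }
    walk(tree$root, root_tab)
  })
  models <- lapply(as.character(sort(leaves)), function(nd) {
    structure(list(order = as.integer(order), transition = tabs[[nd]],
                   node_id = as.integer(nd)),
              class = "composition_model")
  })
  names(models) <- as.character(sort(leaves))
  models
}

## Dirichlet perturbation of each conditional distribution; concentration
## inversely proportional to divergence
.perturb_table <- function(tab, divergence) {
  if (divergence == 0) return(tab)
  conc <- 20 / divergence
  out <- tab
  for (i in seq_len(nrow(tab))) {
    g <- stats::rgamma(4L, shape = pmax(tab[i, ] * conc, 1e-8))
    out[i, ] <- g / sum(g)
  }
  if (any(!is.finite(out)) || any(out < 0)) stop("invalid perturbed probabilities")
  out
}

#' @export
print.composition_model <- function(x, ...) {
  cat("Markov composition model (order ", x$order, ") for taxon ", x$node_id,
      "; GC ~ ", round(stationary_gc(x), 3), "\n", sep = "")
  invisible(x)
}

#' Stationary GC content of a composition model
#'
#' Computes the stationary distribution over contexts of the order-k chain
#' (by power iteration on the context transition operator) and returns the
#' implied long-run GC fraction.
#'
#' @param model A `"composition_model"`.
#' @return GC fraction in (0, 1).
#' @export
stationary_gc <- function(model) {
  k <- model$order
  nctx <- 4L^k
  ## context c emits base b -> new context (c mod 4^(k-1)) * 4 + b
  pi_ctx <- rep(1 / nctx, nctx)
  for (it in seq_len(1000L)) {
    nxt <- numeric(nctx)
    for (b in 1:4) {
      tgt <- ((seq_len(nctx) - 1L) %% (4L^(k - 1L))) * 4L + b
      contrib <- pi_ctx * model$transition[, b]
      for (i in seq_len(nctx)) nxt[tgt[i]] <- nxt[tgt[i]] + contrib[i]
    }
    done <- max(abs(nxt - pi_ctx)) < 1e-13
    pi_ctx <- nxt
    if (done) break
  }
  ## marginal distribution of the last base of the context
  last <- (seq_len(nctx) - 1L) %% 4L + 1L
  marg <- as.vector(rowsum(pi_ctx, last))
  sum(marg[2:3])
}

#' Generate a genome from a composition model
#'
#' Samples a DNA string of exactly `length` bases from the Markov chain.
#' The first `order` bases are drawn from the mean conditional distribution;
#' the rest follow the chain. Deterministic given the seed.
#'
#' @param model A `"composition_model"`.
#' @param length Genome length in bp, at least `order + 1`.
#' @param seed Integer seed.
#' @return Character scalar over A/C/G/T.
#' @export
generate_genome <- function(model, length, seed = 1L) {
  k <- model$order
  length <- as.integer(length)
  stopifnot(length >= k + 1L)
  cum <- t(apply(model$transition, 1L, cumsum))
  p_init <- colMeans(model$transition)
  with_seed(seed, {
    out <- integer(length)
    out[seq_len(k)] <- sample.int(4L, k, replace = TRUE, prob = p_init)
    ctx <- 0L
    for (i in seq_len(k)) ctx <- ctx * 4L + (out[i] - 1L)
    ctx <- ctx + 1L
    u <- stats::runif(length)
    base_mod <- 4L^(k - 1L)
    for (i in (k + 1L):length) {
      b <- 1L + sum(u[i] > cum[ctx, ])
      if (b > 4L) b <- 4L
      out[i] <- b
      ctx <- ((ctx - 1L) %% base_mod) * 4L + b
    }
    paste(BASES[out], collapse = "")
  })
}

## ranks used for the synthetic taxonomy shape root -> phyla -> genera
.benchmark_tree <- function(n_phyla, genera_per_phylum) {
  ids <- 1L
  parent <- NA_integer_
  rank <- "root"
  nid <- 1L
  for (p in seq_len(n_phyla)) {
    nid <- nid + 1L
    phy <- nid
    ids <- c(ids, phy); parent <- c(parent, 1L); rank <- c(rank, "phylum")
    for (g in seq_len(genera_per_phylum)) {
      nid <- nid + 1L
      ids <- c(ids, nid); parent <- c(parent, phy); rank <- c(rank, "genus")
    }
  }
  taxonomy(id = ids, parent = parent, rank = rank)
}

#' Generate a synthetic benchmark community
#'
#' Builds a toy taxonomy (root, `n_phyla` phyla, `genera_per_phylum` genus
#' leaves each), clade-specific composition models, one genome per leaf,
#' and a disjoint train/test split by genome coordinate: the first 80% of
#' each genome is available as labelled reference sequence, the last 20%
#' supplies the held-out test fragments, so no test base is ever seen in
#' training. Everything (tree, genomes, fragments, truth) is reproducible
#' from `seed`.
#'
#' @param tree_shape Integer pair `(n_phyla, genera_per_phylum)`.
#' @param genome_length Genome length per leaf in bp (default 500 kb).
#' @param n_test_fragments Total test fragments, spread evenly over leaves.
#' @param test_fragment_length Test fragment length in bp (default 5 kb).
#' @param base_gc,divergence,order Passed to [make_clade_models()].
#' @param seed Integer seed.
#' @return List with elements `tree` (`taxonomy`), `models`, `genomes`
#'   (named character), `refs` (a [reference_collection()] of the training
#'   80% of each genome, leaf-labelled), `test` (named character vector of
#'   fragments) and `truth` (a [truth_table()]).
#' @export
make_benchmark <- function(tree_shape = c(2L, 2L), genome_length = 5e5,
                           n_test_fragments = 1000L,
                           test_fragment_length = 5000L,
                           base_gc = 0.5, divergence = 0.1, order = 3L,
                           seed = 1L) {
  stopifnot(length(tree_shape) == 2L, all(tree_shape >= 1L),
            genome_length >= 10 * test_fragment_length)
  tree <- .benchmark_tree(tree_shape[1L], tree_shape[2L])
  models <- make_clade_models(tree, base_gc = base_gc, divergence = divergence,
                              order = order, seed = seed)
  leaves <- as.integer(names(models))
  genomes <- vapply(seq_along(models), function(i) {
    generate_genome(models[[i]], genome_length, seed = seed + 1000L + i)
  }, "")
  names(genomes) <- names(models)
  split_at <- floor(0.8 * genome_length)
  refs <- reference_collection(
    ids = paste0("genome_", leaves),
    seqs = substring(genomes, 1L, split_at),
    taxa = leaves,
    provenance = "generic-reference", tree = tree)
  ## test fragments: random starts within the held-out 20% tail
  test_lo <- split_at + 1L
  test_hi <- genome_length - test_fragment_length + 1L
  if (test_hi < test_lo) stop("genome too short for requested test fragments")
  per_leaf <- diff(round(seq(0, n_test_fragments, length.out = length(leaves) + 1L)))
  frs <- character(0); labs <- integer(0)
  for (i in seq_along(leaves)) {
    st <- with_seed(seed + 2000L + i,
                    sample(test_lo:test_hi, per_leaf[i], replace = TRUE))
    frs <- c(frs, substring(genomes[i], st, st + test_fragment_length - 1L))
    labs <- c(labs, rep(leaves[i], per_leaf[i]))
  }
  names(frs) <- sprintf("test_%05d", seq_along(frs))
  list(tree = tree,
       models = models,
       genomes = genomes,
       refs = refs,
       test = frs,
       truth = truth_table(names(frs), labs, nchar(frs), tree = tree))
}

#' Write a benchmark to standard files
#'
#' Emits the community as the formats the classifier consumes: a Newick
#' taxonomy, a labelled training FASTA (headers carry `label:X`), a plain
#' test FASTA, and a two-column truth TSV.
#'
#' @param bench Result of [make_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "taxonomy.nwk"),
             train = file.path(dir, "train.fasta"),
             test = file.path(dir, "test.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_newick(bench$tree, paths["tree"])
  train <- Biostrings::DNAStringSet(bench$refs$seqs)
  names(train) <- paste0(bench$refs$ids, " label:", bench$refs$taxa)
  Biostrings::writeXStringSet(train, paths["train"])
  test <- Biostrings::DNAStringSet(bench$test)
  Biostrings::writeXStringSet(test, paths["test"])
  utils::write.table(
    data.frame(bench$truth$sequence_id, bench$truth$node),
    paths["truth"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
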