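# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (plain loops, no reuse of package internals) so they stay an
# independent route against the implementation.

toy5 <- function() parse_newick("((3,4)2,5)1;")

# reference table in the style of a taxonomy dump: E. coli-like lineage
ref_table <- function() {
  data.frame(
    id     = c(1L, 2L, 1224L, 1236L, 91347L, 543L, 561L, 562L, 564L, 570L),
    parent = c(1L, 1L, 2L, 1224L, 1236L, 91347L, 543L, 561L, 561L, 543L),
    rank   = c("root", "domain", "phylum", "class", "order", "family",
               "genus", "species", "species", "genus"),
    name   = c("root", "Bacteria", "Proteobacteria", "Gammaproteobacteria",
               "Enterobacterales", "Enterobacteriaceae", "Escherichia",
               "Escherichia coli", "Escherichia fergusonii", "Klebsiella"),
    stringsAsFactors = FALSE)
}

# random rooted tree: node i's parent drawn among nodes 1..i-1
rand_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  taxonomy(id = seq_len(n), parent = parent)
}

# geodesic oracle: breadth-first search on the undirected edge list
bf_geodesic <- function(tree, a, b) {
  n <- length(tree$id)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    p <- match(tree$parent[i], tree$id)
    if (!is.na(p)) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  start <- match(a, tree$id)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  dist[match(b, tree$id)]
}

# k-mer counting oracle: explicit sliding window over the string
bf_count_kmers <- function(seq, k, rc_collapse) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  counts <- list()
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (length(chars) >= k) {
    for (i in seq_len(length(chars) - k + 1L)) {
      win <- chars[i:(i + k - 1L)]
      if (!all(win %in% c("A", "C", "G", "T"))) next
      w <- paste(win, collapse = "")
      if (rc_collapse) {
        rc <- revcomp(w)
        if (rc < w) w <- rc
      }
      counts[[w]] <- (counts[[w]] %||% 0L) + 1L
    }
  }
  unlist(counts) %||% integer(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DNA with optional N contamination
rand_dna <- function(len, n_frac = 0) {
  alph <- c("A", "C", "G", "T")
  s <- sample(alph, len, replace = TRUE)
  if (n_frac > 0) {
    k <- max(1L, round(n_frac * len))
    s[sample.int(len, k)] <- "N"
  }
  paste(s, collapse = "")
}

# independent label scorer: walks parent pointers, no package matrix path
bf_label_scores <- function(tree, W, x) {
  vapply(tree$id, function(y) {
    s <- 0
    v <- y
    while (!is.na(v)) {
      if (v != tree$root) s <- s + sum(W[as.character(v), ] * x)
      v <- tree$parent[match(v, tree$id)]
    }
    s
  }, numeric(1))
}

# independent argmax with the documented tie-break (nearer root, smaller id)
bf_argmax <- function(tree, values, tol = 1e-9) {
  ord <- order(tree$depth, tree$id)
  v <- values[ord]
  tree$id[ord][which(v >= max(v) - tol)[1L]]
}

# small trained ensemble on a fast synthetic community, memoized per session
.fixture_env <- new.env()
tiny_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    bench <- make_benchmark(tree_shape = c(2L, 2L), genome_length = 6e4,
                            n_test_fragments = 40L, test_fragment_length = 3000L,
                            divergence = 0.3, seed = 11)
    fit <- phylosvm(bench$refs, bench$tree, lengths = c(1000L, 3000L),
                    per_taxon_bp = 1.5e4, min_genomes = 1L, seed = 11)
    .fixture_env$bench <- bench
    .fixture_env$fit <- fit
  }
  list(fit = .fixture_env$fit, bench = .fixture_env$bench)
}
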