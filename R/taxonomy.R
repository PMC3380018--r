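## The seven major ranks, most to least inclusive. "root" and "no_rank" are
## allowed on nodes but are not major ranks.
MAJOR_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Seven major taxonomic ranks
#'
#' Returns the major ranks modelled by the classifier, ordered from most
#' inclusive (domain) to least inclusive (species).
#'
#' @return Character vector of length 7.
#' @export
major_ranks <- function() MAJOR_RANKS

## specificity index: root < domain < ... < species; no_rank has none (NA)
.rank_level <- function(rank) {
  lev <- match(rank, MAJOR_RANKS)
  lev[rank == "root"] <- 0L
  lev
}

#' Construct a taxonomy tree
#'
#' A taxonomy is a rooted tree of taxon nodes identified by non-negative
#' integers. Each node optionally carries one of the seven major ranks
#' (`"domain"` ... `"species"`), `"root"`, or `"no_rank"`. Ranks, where
#' present, must be consistent with the topology: a node's rank is never more
#' inclusive than an ancestor's (a genus never ancestors a phylum).
#'
#' @param id Integer vector of unique non-negative node identifiers.
#' @param parent Integer vector, same length: parent identifier of each node,
#'   `NA` for the single root.
#' @param rank Optional character vector of ranks (default `"no_rank"`).
#' @param name Optional character vector of scientific names.
#' @return An object of class `"taxonomy"`.
#' @examples
#' tr <- taxonomy(id = c(1, 2, 3), parent = c(NA, 1, 2),
#'                rank = c("root", "genus", "species"))
#' lineage(tr, 3)
#' @export
taxonomy <- function(id, parent, rank = NULL, name = NULL) {
  id <- as.integer(id)
  parent <- as.integer(parent)
  n <- length(id)
  if (n == 0L) stop("taxonomy must contain at least one node")
  if (length(parent) != n) stop("'id' and 'parent' must have equal length")
  if (anyNA(id) || any(id < 0L)) stop("node identifiers must be non-negative integers")
  if (anyDuplicated(id)) {
    stop("duplicate node identifier: ", id[which(duplicated(id))[1L]])
  }
  if (is.null(rank)) rank <- rep("no_rank", n)
  if (is.null(name)) name <- rep(NA_character_, n)
  rank <- as.character(rank)
  name <- as.character(name)
  bad <- !(rank %in% c(MAJOR_RANKS, "root", "no_rank"))
  if (any(bad)) stop("unknown rank: ", rank[bad][1L])

  is_root <- is.na(parent)
  if (sum(is_root) != 1L) stop("taxonomy must have exactly one root (one NA parent)")
  pidx <- match(parent, id)
  if (anyNA(pidx[!is_root])) {
    stop("parent identifier not in tree: ", parent[!is_root][is.na(pidx[!is_root])][1L])
  }

  ## depth by walking up; also detects cycles / disconnection
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    path <- i
    j <- i
    while (is.na(depth[j])) {
      j <- pidx[j]
      if (is.na(j) || j %in% path) stop("taxonomy contains a cycle or is disconnected")
      path <- c(path, j)
    }
    d <- depth[j]
    for (k in rev(path[-length(path)])) {
      d <- d + 1L
      depth[k] <- d
    }
  }

  obj <- structure(
    list(id = id, parent = parent, rank = rank, name = name,
         root = id[is_root], depth = depth),
    class = "taxonomy")

  ## rank monotonicity along every lineage
  lev <- .rank_level(rank)
  for (i in seq_len(n)) {
    if (is.na(lev[i])) next
    j <- pidx[i]
    while (!is.na(j)) {
      if (!is.na(lev[j]) && lev[j] >= lev[i]) {
        stop("rank of node ", id[i], " (", rank[i], ") is not below ancestor ",
             id[j], " (", rank[j], ")")
      }
      j <- pidx[j]
    }
  }
  obj
}

#' @export
print.taxonomy <- function(x, ...) {
  nr <- table(factor(x$rank, levels = c("root", MAJOR_RANKS, "no_rank")))
  cat("Taxonomy with", length(x$id), "nodes (root:", x$root,
      ", max depth:", max(x$depth), ")\n")
  nr <- nr[nr > 0]
  cat("  ranks:", paste(names(nr), nr, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @method format taxonomy
#' @export
format.taxonomy <- function(x, ...) {
  paste0("<taxonomy: ", length(x$id), " nodes>")
}

## resolve ids to indices, erroring on unknown nodes
.tax_index <- function(tree, nodes) {
  idx <- match(as.integer(nodes), tree$id)
  if (anyNA(idx)) stop("unknown taxon: ", nodes[is.na(idx)][1L])
  idx
}

#' Number of nodes in a taxonomy
#' @param tree A `taxonomy`.
#' @return Integer.
#' @export
n_taxa <- function(tree) length(tree$id)

#' Lineage of a node
#'
#' The ordered path of node identifiers from the root down to `node`.
#'
#' @param tree A `taxonomy`.
#' @param node A node identifier present in `tree`.
#' @return Integer vector; first element is the root, last is `node`.
#' @export
lineage <- function(tree, node) {
  i <- .tax_index(tree, node)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(tree$id[i], path)
    i <- match(tree$parent[i], tree$id)
  }
  path
}

#' Test ancestry
#'
#' @param tree A `taxonomy`.
#' @param ancestor,node Node identifiers.
#' @param strict If `TRUE`, a node is not its own ancestor.
#' @return Logical.
#' @export
is_ancestor <- function(tree, ancestor, node, strict = FALSE) {
  .tax_index(tree, c(ancestor, node))
  lin <- lineage(tree, node)
  if (strict) lin <- lin[-length(lin)]
  as.integer(ancestor) %in% lin
}

#' Geodesic distance between taxonomy nodes
#'
#' The number of edges on the unique path between two nodes, i.e. through
#' their lowest common ancestor. This is the taxonomic distance used both as
#' the training loss of the structured classifier and as the fine-grained
#' evaluation measure. It is a metric on the node set.
#'
#' @param tree A `taxonomy`.
#' @param a,b Node identifiers (vectors are recycled pairwise).
#' @return Non-negative integer vector of edge counts.
#' @examples
#' tr <- parse_newick("((3,4)2,5)1;")
#' geodesic_distance(tr, 3, 5)  # 3 -> 2 -> 1 -> 5
#' @export
geodesic_distance <- function(tree, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  k <- max(length(a), length(b))
  a <- rep_len(a, k); b <- rep_len(b, k)
  vapply(seq_len(k), function(i) {
    la <- lineage(tree, a[i])
    lb <- lineage(tree, b[i])
    m <- min(length(la), length(lb))
    common <- sum(cumprod(la[seq_len(m)] == lb[seq_len(m)]))
    as.integer((length(la) - common) + (length(lb) - common))
  }, integer(1))
}

## full pairwise distance matrix over all nodes (used by the training loss);
## rows/cols in tree$id order, dimnames are the ids
.tax_distmat <- function(tree) {
  n <- length(tree$id)
  lins <- lapply(tree$id, function(v) lineage(tree, v))
  D <- matrix(0L, n, n, dimnames = list(tree$id, tree$id))
  for (i in seq_len(n)) {
    la <- lins[[i]]
    for (j in seq_len(n)) {
      if (j >= i) {
        lb <- lins[[j]]
        m <- min(length(la), length(lb))
        common <- sum(cumprod(la[seq_len(m)] == lb[seq_len(m)]))
        D[i, j] <- D[j, i] <- as.integer((length(la) - common) + (length(lb) - common))
      }
    }
  }
  D
}

#' Map a node to an ancestor at a fixed rank
#'
#' Projects a node to its unique ancestor-or-self carrying the requested
#' major rank, as done when assignments made at mixed depths are compared at
#' one rank. Returns `NA` when the lineage skips the rank (some taxa have no
#' defined parental clade at, e.g., the genus or family rank).
#'
#' @param tree A `taxonomy`.
#' @param node Node identifier(s).
#' @param rank One of [major_ranks()].
#' @return Integer vector of node identifiers, `NA` where unmapped.
#' @export
map_to_rank <- function(tree, node, rank) {
  rank <- match.arg(rank, MAJOR_RANKS)
  vapply(as.integer(node), function(v) {
    lin <- lineage(tree, v)
    hit <- lin[tree$rank[.tax_index(tree, lin)] == rank]
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}

#' Parse a plain-text taxon identifier list into a taxonomy
#'
#' One model-building input is a plain text file listing the integer
#' identifiers of the clades to be modelled, one per line (`#` comments
#' allowed), resolved against a reference taxonomy table such as the NCBI
#' taxonomy dump. The returned tree is the induced subtree: the listed taxa
#' plus all their ancestors, with intermediate non-major ranks (suborder,
#' species group, ...) contracted so that only the seven major ranks, the
#' root, and the listed nodes themselves remain.
#'
#' @param text Character scalar (the file content) or vector of lines, or a
#'   file path to read.
#' @param reference Reference table: a `data.frame` with columns `id`,
#'   `parent`, `rank` and optionally `name` (see [read_ncbi_taxonomy()]).
#' @return A `taxonomy`.
#' @export
parse_taxid_list <- function(text, reference) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty taxon identifier list")
  bad <- grep("^[0-9]+$", lines, invert = TRUE)
  if (length(bad)) stop("not a non-negative integer identifier: '", lines[bad[1L]], "'")
  ids <- unique(as.integer(lines))

  stopifnot(is.data.frame(reference), all(c("id", "parent", "rank") %in% names(reference)))
  rid <- as.integer(reference$id)
  rparent <- as.integer(reference$parent)
  rrank <- as.character(reference$rank)
  rname <- if ("name" %in% names(reference)) as.character(reference$name) else rep(NA_character_, length(rid))

  miss <- setdiff(ids, rid)
  if (length(miss)) stop("unknown taxon: ", miss[1L])

  ## collect lineages up to root (parent == id or parent NA marks the root)
  keep <- integer(0)
  for (v in ids) {
    j <- match(v, rid)
    repeat {
      keep <- c(keep, rid[j])
      p <- rparent[j]
      if (is.na(p) || p == rid[j]) break
      j <- match(p, rid)
      if (is.na(j)) stop("unknown taxon: ", p)
    }
  }
  keep <- unique(keep)
  kidx <- match(keep, rid)
  is_root <- is.na(rparent[kidx]) | rparent[kidx] == keep
  root_id <- keep[is_root]
  if (length(root_id) != 1L) stop("reference table must contain a single root")

  ## retain root, major-rank nodes, and the listed nodes; contract the rest
  retain <- keep[is_root | rrank[kidx] %in% MAJOR_RANKS | keep %in% ids]
  up <- function(v) { # nearest retained proper ancestor
    j <- match(v, rid)
    repeat {
      p <- rparent[j]
      if (is.na(p) || p == rid[j]) return(NA_integer_)
      if (p %in% retain) return(p)
      j <- match(p, rid)
    }
  }
  parent_out <- vapply(retain, up, integer(1))
  ridx <- match(retain, rid)
  rk <- rrank[ridx]
  rk[!(rk %in% MAJOR_RANKS)] <- "no_rank"
  rk[retain == root_id] <- "root"
  taxonomy(id = retain, parent = parent_out, rank = rk, name = rname[ridx])
}

#' Read NCBI-taxonomy-dump-style tables
#'
#' Loads the `nodes.dmp` / `names.dmp` dialect (fields separated by
#' `\t|\t`, rows terminated by `\t|`) into the reference table consumed by
#' [parse_taxid_list()]. Only scientific names are kept from `names.dmp`.
#' Fetching the dump is the caller's job.
#'
#' @param nodes_path Path to `nodes.dmp` (fields: id, parent id, rank, ...).
#' @param names_path Optional path to `names.dmp`.
#' @return `data.frame` with columns `id`, `parent`, `rank`, `name`.
#' @export
read_ncbi_taxonomy <- function(nodes_path, names_path = NULL) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  rows <- parse_dmp(nodes_path)
  id <- as.integer(vapply(rows, `[[`, "", 1L))
  parent <- as.integer(vapply(rows, `[[`, "", 2L))
  rank <- vapply(rows, `[[`, "", 3L)
  rank <- gsub(" ", "_", trimws(rank))
  rank[rank == "superkingdom"] <- "domain"  # NCBI dialect for the domain rank
  out <- data.frame(id = id, parent = parent, rank = rank, name = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(names_path)) {
    nrows <- parse_dmp(names_path)
    cls <- vapply(nrows, function(r) if (length(r) >= 4L) trimws(r[[4L]]) else "", "")
    sci <- nrows[cls == "scientific name"]
    nm_id <- as.integer(vapply(sci, `[[`, "", 1L))
    nm <- trimws(vapply(sci, `[[`, "", 2L))
    out$name[match(nm_id, out$id)] <- nm
  }
  out
}

#' Parse a rooted Newick tree with integer node names
#'
#' The second accepted taxonomy encoding is a rooted Newick string in which
#' every node (internal and leaf) is named by a unique non-negative integer.
#' Branch lengths, if present, are ignored: the tree metric used throughout
#' is the edge count. Ranks are `"no_rank"` unless a rank map is supplied,
#' in which case rank-mapped reports become available for the model.
#'
#' @param text Newick string, or path to a file containing one.
#' @param ranks Optional named character vector mapping node identifier to
#'   rank (names are the identifiers).
#' @return A `taxonomy`.
#' @examples
#' parse_newick("((3,4)2,5)1;")
#' @export
parse_newick <- function(text, ranks = NULL) {
  if (length(text) == 1L && !grepl(";", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: not a valid rooted tree")
  labs <- c(phy$tip.label, if (!is.null(phy$node.label)) phy$node.label else character(0))
  ntot <- length(phy$tip.label) + phy$Nnode
  if (length(labs) != ntot || any(!nzchar(labs))) {
    stop("Newick parse error: every node must carry a name")
  }
  bad <- grep("^[0-9]+$", labs, invert = TRUE)
  if (length(bad)) {
    stop("Newick parse error: node name '", labs[bad[1L]],
         "' is not a non-negative integer (node ", bad[1L], ")")
  }
  ids <- as.integer(labs)
  if (anyDuplicated(ids)) {
    stop("Newick parse error: duplicate node name ", ids[which(duplicated(ids))[1L]])
  }
  parent <- rep(NA_integer_, ntot)
  parent[phy$edge[, 2L]] <- ids[phy$edge[, 1L]]
  rk <- NULL
  if (!is.null(ranks)) {
    rk <- rep("no_rank", ntot)
    hit <- match(as.character(ids), names(ranks))
    rk[!is.na(hit)] <- unname(ranks[hit[!is.na(hit)]])
  }
  taxonomy(id = ids, parent = parent, rank = rk)
}

#' Write a taxonomy as a Newick string
#'
#' Inverse of [parse_newick()]; ranks and names are not representable in
#' Newick and are dropped.
#'
#' @param tree A `taxonomy`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  kids <- split(tree$id, factor(tree$parent, levels = tree$id))
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch) || !length(ch)) return(as.character(v))
    paste0("(", paste(vapply(sort(ch), rec, ""), collapse = ","), ")", v)
  }
  nw <- paste0(rec(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nw, path)
    return(invisible(nw))
  }
  nw
}
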