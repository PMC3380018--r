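# taxonomy used throughout: root 1 -> family 10 -> genera {20, 21} -> species
fam_tree <- function() {
  taxonomy(id = c(1, 10, 20, 21, 30, 31, 32),
           parent = c(NA, 1, 10, 10, 20, 20, 21),
           rank = c("root", "family", "genus", "genus",
                    "species", "species", "species"))
}

test_that("clade selection requires min_genomes per subtree", {
  tr <- fam_tree()
  set.seed(1)
  refs <- reference_collection(
    ids = c("g1", "g2", "g3"),
    seqs = replicate(3, rand_dna(2000)),
    taxa = c(30, 30, 31), tree = tr)
  sel <- select_model_clades(refs, tr, min_genomes = 3)
  # 3 genomes under genus 20 and all its ancestors; nothing under 21
  expect_setequal(sel, c(1L, 10L, 20L))

  # 2 genomes in genus 20, 1 in sibling genus 21: only the family qualifies
  refs2 <- reference_collection(
    ids = c("g1", "g2", "g3"),
    seqs = replicate(3, rand_dna(2000)),
    taxa = c(30, 31, 32), tree = tr)
  sel2 <- select_model_clades(refs2, tr, min_genomes = 3)
  expect_true(10L %in% sel2)
  expect_false(any(c(20L, 21L) %in% sel2))

  # min_genomes = 1 selects every taxon with any genome
  sel3 <- select_model_clades(refs2, tr, min_genomes = 1)
  expect_setequal(sel3, c(1L, 10L, 20L, 21L, 30L, 31L, 32L))

  expect_error(select_model_clades(
    reference_collection(character(0), character(0), integer(0)), tr),
    "empty")
})

test_that("sample-specific clades are always modelled", {
  tr <- fam_tree()
  set.seed(2)
  refs <- reference_collection(
    ids = c("g1", "u1"),
    seqs = replicate(2, rand_dna(2000)),
    taxa = c(30, 32),
    provenance = c("generic-reference", "sample-specific"), tree = tr)
  sel <- select_model_clades(refs, tr, min_genomes = 3)
  expect_true(all(c(32L, 21L, 10L, 1L) %in% sel))  # user clade + ancestors
  expect_false(30L %in% sel)                        # 1 generic genome only
})

test_that("fragment sampling tiles without overlap and respects budgets", {
  set.seed(3)
  seq10k <- rand_dna(10000)
  fr <- sample_fragments(seq10k, 1000, 10, rng_seed = 1)
  expect_length(fr, 10L)
  expect_true(all(nchar(fr) == 1000L))
  st <- attr(fr, "start")
  expect_identical(sort(st), seq(1L, 9001L, by = 1000L))

  expect_length(sample_fragments(rand_dna(900), 1000, 10, rng_seed = 1), 0L)

  fr2 <- sample_fragments(rand_dna(5000), 2000, 5, rng_seed = 2)
  expect_length(fr2, 2L)
  st2 <- sort(attr(fr2, "start"))
  expect_true(all(diff(st2) >= 2000L))

  # non-overlap on random cases
  for (s in 1:5) {
    L <- sample(3000:20000, 1L)
    fl <- sample(c(500L, 700L, 1500L), 1L)
    fr3 <- sample_fragments(rand_dna(L), fl, 50, rng_seed = s)
    st3 <- sort(attr(fr3, "start"))
    if (length(st3) > 1L) expect_true(all(diff(st3) >= fl))
  }

  # reproducible placement
  expect_identical(sample_fragments(seq10k, 1000, 5, rng_seed = 9),
                   sample_fragments(seq10k, 1000, 5, rng_seed = 9))
})

test_that("training sets equalize sampled bases across clades", {
  tr <- fam_tree()
  set.seed(4)
  refs <- reference_collection(
    ids = c("a", "b"),
    seqs = c(rand_dna(150000), rand_dna(150000)),
    taxa = c(30, 32), tree = tr)
  sets <- build_training_sets(refs, c(20L, 21L), tr,
                              spec = featurizer_spec(k = c(2, 3)),
                              lengths = c(1000, 3000), per_taxon_bp = 1e5,
                              rng_seed = 1)
  expect_length(sets, 2L)
  s1 <- sets[[1L]]
  expect_identical(s1$fragment_length, 1000L)
  expect_identical(as.integer(table(s1$y)), c(100L, 100L))  # equal amounts
  expect_identical(nrow(s1$x), 200L)
  expect_identical(sort(unique(s1$y)), c(20L, 21L))  # lowest selected clades
  expect_identical(as.integer(table(sets[[2L]]$y)), c(33L, 33L))

  # reproducibility under the seed
  sets2 <- build_training_sets(refs, c(20L, 21L), tr,
                               spec = featurizer_spec(k = c(2, 3)),
                               lengths = c(1000, 3000), per_taxon_bp = 1e5,
                               rng_seed = 1)
  expect_identical(sets, sets2)
})

test_that("clades short of sequence contribute what they have or drop out", {
  tr <- fam_tree()
  set.seed(5)
  refs <- reference_collection(
    ids = c("big", "small"),
    seqs = c(rand_dna(60000), rand_dna(30000)),
    taxa = c(30, 32), tree = tr)
  expect_warning(
    sets <- build_training_sets(refs, c(20L, 21L), tr,
                                spec = featurizer_spec(k = 2),
                                lengths = c(1000, 50000), per_taxon_bp = 1e5,
                                rng_seed = 1),
    "dropped")
  # 60 kb genome hosts exactly one 50 kb fragment; 30 kb clade drops out
  s50 <- sets[[2L]]
  expect_identical(as.integer(table(s50$y)), 1L)
  expect_identical(unique(s50$y), 20L)
  # both clades present at 1 kb
  expect_setequal(unique(sets[[1L]]$y), c(20L, 21L))
})

test_that("pooling user data keeps user labels and resolves duplicates", {
  tr <- fam_tree()
  set.seed(6)
  generic <- reference_collection(
    ids = c("r1", "r2"), seqs = c(rand_dna(5000), rand_dna(5000)),
    taxa = c(30, 31), tree = tr)

  # empty user data reproduces the generic collection exactly
  empty <- reference_collection(character(0), character(0), integer(0),
                                provenance = "sample-specific")
  expect_identical(pool_sample_specific(generic, empty), generic)

  # five user populations of ~70-100 kb each all appear in the pool
  amd_sizes <- c(70000, 100000, 100000, 100000, 70000)
  user <- reference_collection(
    ids = paste0("amd", 1:5),
    seqs = vapply(amd_sizes, rand_dna, ""),
    taxa = c(30, 30, 31, 32, 32),
    provenance = "sample-specific", tree = tr)
  pooled <- pool_sample_specific(generic, user)
  expect_length(pooled, 7L)
  expect_identical(sum(pooled$provenance == "sample-specific"), 5L)
  expect_setequal(pooled$taxa[pooled$provenance == "sample-specific"],
                  c(30L, 31L, 32L))

  # identical duplicate collapses to a single record
  dup <- reference_collection("r1", generic$seqs[1], 30,
                              provenance = "sample-specific")
  pooled2 <- pool_sample_specific(generic, dup)
  expect_length(pooled2, 2L)
  expect_identical(sum(pooled2$ids == "r1"), 1L)

  # same id with a different sequence is contradictory
  bad <- reference_collection("r1", rand_dna(5000), 30,
                              provenance = "sample-specific")
  expect_error(pool_sample_specific(generic, bad), "different sequences")

  # same id, same sequence, new label: user wins with a warning
  relab <- reference_collection("r1", generic$seqs[1], 31,
                                provenance = "sample-specific")
  expect_warning(pooled3 <- pool_sample_specific(generic, relab), "relabelled")
  expect_identical(pooled3$taxa[pooled3$ids == "r1"], 31L)
})
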