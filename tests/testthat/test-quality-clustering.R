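make_quality_record <- function(id, comp, cont) {
  structure(list(genome_id = id, contigs = c(c1 = "ACGT"),
                 features = data.frame(), proteins = data.frame(),
                 metadata = NULL,
                 quality = list(completeness = comp, contamination = cont)),
            class = "genome_record")
}

test_that("quality gate uses strict inequalities on both cutoffs", {
  recs <- list(make_quality_record("a", 85, 3),    # inside
               make_quality_record("b", 80, 3),    # boundary completeness
               make_quality_record("c", 95, 5),    # boundary contamination
               make_quality_record("d", 79.9, 0))  # below
  kept <- quality_filter(recs, 80, 5)
  expect_equal(vapply(kept, `[[`, "", "genome_id"), "a")
  # stricter 97/2 gate
  recs2 <- list(make_quality_record("e", 97.5, 1.5),
                make_quality_record("f", 97, 1.5),
                make_quality_record("g", 98, 2))
  expect_equal(vapply(quality_filter(recs2, 97, 2), `[[`, "", "genome_id"),
               "e")
})

test_that("survivor count on a planted-quality cohort matches a direct scan", {
  truth <- draw_cohort_truth(cohort_config(n_species = 40L, seed = 5L))
  tt <- truth_trait_table(truth)
  expected <- sum(tt$completeness > 80 & tt$contamination < 5)
  expect_equal(nrow(quality_filter_table(tt)), expected)
  expect_equal(expected, sum(truth$genomes$passes_quality))
  expect_true(expected < nrow(tt))  # the gate actually removes genomes
})

test_that("midpoint rule is the arithmetic midpoint and rejects bad ranges", {
  expect_equal(midpoint_ph(2, 6), 4)
  expect_equal(midpoint_ph(3, 3), 3)
  expect_equal(midpoint_ph(0.5, 1.5), 1.0)
  expect_error(midpoint_ph(5, 2), "exceeds")
})

test_that("ANI estimate matches the Mash formula on an exact-Jaccard oracle", {
  set.seed(101)
  k <- 21L
  base <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                collapse = "")
  mutate_at <- function(s, rate) {
    chars <- strsplit(s, "")[[1L]]
    pos <- which(runif(length(chars)) < rate)
    chars[pos] <- vapply(chars[pos], function(c0)
      sample(setdiff(c("A", "C", "G", "T"), c0), 1L), "")
    paste(chars, collapse = "")
  }
  mut <- mutate_at(base, 0.05)
  est <- estimate_ani(c(x = base), c(x = mut), k = k)
  # independent exact-Jaccard computation (forward + reverse complement)
  canon <- function(s) {
    n <- nchar(s)
    f <- substring(s, 1:(n - k + 1L), k:n)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    r <- rev(substring(rc, 1:(n - k + 1L), k:n))
    unique(pmin(f, r))
  }
  A <- canon(base); B <- canon(mut)
  j <- length(intersect(A, B)) / length(union(A, B))
  expect_equal(est, 100 * (1 + log(2 * j / (1 + j)) / k), tolerance = 1e-10)
  expect_true(abs(est - 95) <= 1)
  # identity and undetected extremes
  expect_equal(estimate_ani(c(x = base), c(x = base), k = k), 100)
  other <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                 collapse = "")
  expect_true(is.na(estimate_ani(c(x = base), c(x = other), k = k)))
  expect_error(estimate_ani(c(x = base), c(x = base), k = 9L), "unreliable")
})

test_that("ANI estimate is symmetric and monotone in substitution rate", {
  set.seed(102)
  base <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  mutate_at <- function(s, rate) {
    chars <- strsplit(s, "")[[1L]]
    pos <- which(runif(length(chars)) < rate)
    chars[pos] <- vapply(chars[pos], function(c0)
      sample(setdiff(c("A", "C", "G", "T"), c0), 1L), "")
    paste(chars, collapse = "")
  }
  rates <- c(0, 0.02, 0.04, 0.06, 0.08, 0.10)
  ests <- vapply(rates, function(r) {
    m <- mutate_at(base, r)
    a <- estimate_ani(c(x = base), c(x = m))
    expect_equal(a, estimate_ani(c(x = m), c(x = base)))
    a
  }, numeric(1))
  expect_true(all(diff(ests) <= 0))
})

test_that("species clustering is single linkage over the ANI graph", {
  ids <- c("A", "B", "C", "D")
  ani <- data.frame(genome_a = c("A", "B", "A"),
                    genome_b = c("B", "C", "C"),
                    ani_percent = c(96, 96, 94))
  memb <- cluster_species(ids, ani, 95)
  expect_equal(memb$cluster_id[memb$genome_id %in% c("A", "B", "C")],
               rep("A", 3))  # chained through B despite A-C below cutoff
  expect_equal(memb$cluster_id[memb$genome_id == "D"], "D")
  # brute-force component oracle agrees
  edges <- ani[ani$ani_percent >= 95, ]
  comps <- oracle_components(ids, edges$genome_a, edges$genome_b)
  expect_equal(unname(sort(lengths(comps))), c(1L, 3L))
  # empty edge set -> all singletons; threshold boundary is inclusive
  memb0 <- cluster_species(ids, ani[0, ], 95)
  expect_equal(memb0$cluster_id, ids)
  memb95 <- cluster_species(c("A", "B"),
                            data.frame(genome_a = "A", genome_b = "B",
                                       ani_percent = 95), 95)
  expect_equal(unique(memb95$cluster_id), "A")
})

test_that("clustering is invariant to input order", {
  set.seed(103)
  truth <- draw_cohort_truth(cohort_config(n_species = 20L, seed = 6L))
  ids <- truth$genomes$genome_id
  m1 <- cluster_species(ids, truth$ani)
  m2 <- cluster_species(rev(ids), truth$ani)
  m2 <- m2[match(m1$genome_id, m2$genome_id), ]
  expect_equal(m1$cluster_id, m2$cluster_id)
})

test_that("cluster aggregation takes arithmetic means and labels groups", {
  traits <- data.frame(genome_id = c("a", "b", "c"),
                       genome_size_mb = c(3, 4, 5),
                       ph_opt = c(3, 4, 6.5),
                       stringsAsFactors = FALSE)
  memb <- data.frame(genome_id = c("a", "b", "c"),
                     cluster_id = c("a", "a", "c"))
  cl <- aggregate_clusters(traits, memb)
  expect_equal(cl$genome_size_mb, c(3.5, 5))
  expect_equal(cl$ph_opt, c(3.5, 6.5))
  expect_equal(cl$group, c("acidophile", "non_acidophile"))
  # single member passes through unchanged
  expect_equal(cl$genome_size_mb[cl$cluster_id == "c"], 5)
  # 10-member mean equals independent accumulation
  set.seed(104)
  v <- runif(10, 2, 6)
  tr10 <- data.frame(genome_id = sprintf("g%02d", 1:10),
                     genome_size_mb = v, ph_opt = runif(10, 1, 8))
  mb10 <- data.frame(genome_id = tr10$genome_id, cluster_id = "g01")
  acc <- 0; for (x in v) acc <- acc + x
  expect_equal(aggregate_clusters(tr10, mb10)$genome_size_mb, acc / 10)
  expect_error(aggregate_clusters(tr10, mb10[0, ]))
})

test_that("filter + cluster + aggregate preserves the planted species count", {
  truth <- draw_cohort_truth(cohort_config(n_species = 30L, seed = 8L))
  tt <- truth_trait_table(truth)
  kept <- quality_filter_table(tt)
  memb <- cluster_species(kept$genome_id, truth$ani)
  cl <- aggregate_clusters(kept, memb)
  surviving_species <- length(unique(
    truth$genomes$species_id[truth$genomes$genome_id %in% kept$genome_id]))
  expect_equal(nrow(cl), surviving_species)
})
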