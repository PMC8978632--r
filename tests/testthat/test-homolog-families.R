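test_that("local alignment scores match the DP oracle on random peptides", {
  set.seed(31)
  S <- blosum62_for_tests()
  # the classic worked pair first
  a <- align_pair("HEAGAWGHEE", "PAWHEAE")
  expect_equal(a$score, oracle_sw_score("HEAGAWGHEE", "PAWHEAE", S))
  for (i in 1:20) {
    p <- random_peptide(sample(20:45, 1))
    q <- random_peptide(sample(20:45, 1))
    expect_equal(align_pair(p, q)$score, oracle_sw_score(p, q, S),
                 info = paste("pair", i))
  }
})

test_that("identical proteins align at full identity and coverage", {
  set.seed(32)
  p <- random_peptide(100)
  a <- align_pair(p, p)
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 100)
  expect_error(align_pair("ACGTX*", p), "non-amino-acid")
})

test_that("unrelated homopolymers produce no reportable hit", {
  hits <- all_vs_all_search(c(a = strrep("A", 50), w = strrep("W", 50)),
                            prescreen = FALSE)
  expect_equal(nrow(hits), 0L)
})

test_that("the search reports both orientations with query-side coverage", {
  set.seed(33)
  long <- random_peptide(200)
  short <- substring(long, 1, 100)  # perfect half-length fragment
  hits <- all_vs_all_search(c(L = long, S = short))
  expect_setequal(hits$query_id, c("L", "S"))
  cov_L <- hits$coverage[hits$query_id == "L"]
  cov_S <- hits$coverage[hits$query_id == "S"]
  expect_equal(cov_L, 50)
  expect_equal(cov_S, 100)
})

test_that("cutoffs are inclusive and equal an independent predicate scan", {
  set.seed(34)
  hits <- data.frame(
    query_id = "q", subject_id = letters[1:4],
    score = c(100, 100, 100, 100),
    identity = c(49.9, 50.0, 80, 80),
    coverage = c(90, 50.0, 49.9, 80),
    evalue = c(1e-20, 1e-5, 1e-20, 2e-5), stringsAsFactors = FALSE)
  kept <- apply_cutoffs(hits)
  expect_equal(kept$subject_id, "b")  # boundary row kept, others fail one
  big <- random_hits_table(sprintf("p%02d", 1:15))
  kept2 <- apply_cutoffs(big)
  manual <- big[big$coverage >= 50 & big$identity >= 50 &
                  big$evalue <= 1e-5, ]
  expect_equal(kept2, manual)
})

test_that("family construction equals the brute-force component oracle", {
  set.seed(35)
  for (rep in 1:25) {
    ids <- sprintf("p%02d", 1:20)
    hits <- random_hits_table(ids)
    fams <- build_families(ids, apply_cutoffs(hits))
    edges <- oracle_rbh_edges(ids, hits)
    comps <- oracle_components(ids, edges$a, edges$b)
    # same partition: members grouped identically
    got <- unname(lapply(split(fams$protein_id, fams$family_id), sort))
    want <- unname(lapply(comps, sort))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    expect_equal(sum(fams$family_size[!duplicated(fams$family_id)]),
                 length(ids))  # partition invariant
  }
})

test_that("best-of-only edges join families (one-sided best-hit rule)", {
  # A<->B reciprocal best; C's best is B but B's best is A; D isolated
  hits <- data.frame(
    query_id = c("A", "B", "B", "C"),
    subject_id = c("B", "A", "C", "B"),
    score = c(300, 300, 200, 200),
    identity = 90, coverage = 90, evalue = 1e-30,
    stringsAsFactors = FALSE)
  fams <- build_families(c("A", "B", "C", "D"), hits)
  expect_equal(unique(fams$family_id[fams$protein_id %in% c("A", "B", "C")]),
               "A")
  expect_equal(fams$family_size[fams$protein_id == "D"], 1L)
  expect_false(fams$is_paralog_family[fams$protein_id == "D"])
})

test_that("duplicated genes form a paralog family of size two", {
  set.seed(36)
  p <- random_peptide(150)
  fams <- build_families(c("x", "y"),
                         apply_cutoffs(all_vs_all_search(c(x = p, y = p))))
  expect_equal(fams$family_size, c(2L, 2L))
  expect_true(all(fams$is_paralog_family))
  # three mutually dissimilar proteins -> singletons
  trio <- c(a = random_peptide(120), b = random_peptide(120),
            c = random_peptide(120))
  fams3 <- build_families(names(trio),
                          apply_cutoffs(all_vs_all_search(trio)))
  expect_equal(fams3$family_size, rep(1L, 3))
})

test_that("paralog fraction counts proteins in families of size >= 2", {
  fams <- data.frame(
    protein_id = sprintf("p%02d", 1:10),
    family_id = c("f1", "f1", "f1", "f2", "f2", "f3", "f4", "f5", "f6",
                  "f7"),
    family_size = c(3L, 3L, 3L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),
    is_paralog_family = c(rep(TRUE, 5), rep(FALSE, 5)),
    stringsAsFactors = FALSE)
  prots <- data.frame(protein_id = sprintf("p%02d", 1:10),
                      cog_category = c("L", "L", "T", "T", NA, "L", "T",
                                       NA, NA, "L"),
                      stringsAsFactors = FALSE)
  expect_equal(paralog_fraction(fams, prots), 50)
  expect_equal(paralog_fraction(fams, prots, "L"), 100 * 2 / 4)
  expect_equal(paralog_fraction(fams, prots, "T"), 100 * 2 / 3)
  expect_true(is.na(paralog_fraction(fams, prots, "Z")))
  all_single <- fams
  all_single$is_paralog_family <- FALSE
  expect_equal(paralog_fraction(all_single, prots), 0)
  one_fam <- fams
  one_fam$is_paralog_family <- TRUE
  expect_equal(paralog_fraction(one_fam, prots), 100)
})

test_that("planted duplications are recovered as paralog families", {
  gen <- cached_desk_cohort()
  rec <- gen$records[[1L]]
  fams <- proteome_families(rec)
  expect_equal(sum(fams$family_size[!duplicated(fams$family_id)]),
               nrow(rec$proteins))
  dup <- gen$truth$dup_map[gen$truth$dup_map$genome_id == rec$genome_id, ]
  for (i in seq_len(nrow(dup))) {
    expect_equal(fams$family_id[fams$protein_id == dup$source[i]],
                 fams$family_id[fams$protein_id == dup$copy[i]])
  }
  # the overall paralog percentage sits in the observed 2-20% envelope
  pct <- paralog_fraction(fams, rec$proteins)
  expect_gte(pct, 2)
  expect_lte(pct, 20)
})

test_that("external tabular hits are ingested equivalently", {
  set.seed(37)
  p <- random_peptide(150)
  tab <- data.frame(q = c("x", "y"), s = c("y", "x"), pident = 100,
                    len = 150, mm = 0, go = 0, qs = 1, qe = 150, ss = 1,
                    se = 150, ev = 1e-50, bits = 300)
  f <- tempfile()
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  hits <- read_tabular_hits(f, c(x = 150L, y = 150L))
  expect_equal(hits$coverage, c(100, 100))
  fams <- build_families(c("x", "y"), apply_cutoffs(hits))
  expect_true(all(fams$is_paralog_family))
})
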