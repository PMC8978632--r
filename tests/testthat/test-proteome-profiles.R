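make_profile_fixture <- function(locs, cats, sigs = NULL, fam = NULL,
                                 pfam = NULL) {
  n <- length(locs)
  if (is.null(sigs)) sigs <- rep(FALSE, n)
  if (is.null(fam)) fam <- sprintf("f%02d", seq_len(n))
  prots <- data.frame(protein_id = sprintf("p%02d", seq_len(n)),
                      cog_id = ifelse(is.na(cats), NA_character_, "COG1"),
                      cog_category = cats,
                      location = locs, has_signal_peptide = sigs,
                      stringsAsFactors = FALSE)
  prots$pfam_ids <- if (is.null(pfam))
    replicate(n, data.frame(pfam_id = character(), start = integer(),
                            evalue = numeric()), simplify = FALSE)
  else pfam
  sizes <- table(fam)
  fams <- data.frame(protein_id = prots$protein_id, family_id = fam,
                     family_size = as.integer(sizes[fam]),
                     is_paralog_family = as.integer(sizes[fam]) >= 2L,
                     stringsAsFactors = FALSE)
  list(proteins = prots, families = fams)
}

test_that("family location is majority vote with ties to unknown", {
  expect_equal(family_location("cytoplasmic", FALSE)$location, "cytoplasmic")
  expect_equal(family_location(c("inner_membrane", "inner_membrane",
                                 "unknown"), rep(FALSE, 3))$location,
               "inner_membrane")
  expect_equal(family_location(c("exported", "cytoplasmic"),
                               c(TRUE, FALSE))$location, "unknown")
  # signal flag needs a strict majority
  expect_false(family_location(c("exported", "cytoplasmic"),
                               c(TRUE, FALSE))$has_signal_peptide)
  expect_true(family_location(c("exported", "exported", "cytoplasmic"),
                              c(TRUE, TRUE, FALSE))$has_signal_peptide)
})

test_that("location percentages are over all families incl. unknowns", {
  fx <- make_profile_fixture(
    locs = c(rep("cytoplasmic", 4), rep("inner_membrane", 2),
             "periplasmic", "exported", rep("unknown", 2)),
    cats = rep(NA_character_, 10))
  pr <- proteome_profile(fx$proteins, fx$families)
  expect_equal(pr$pct_families_cytoplasmic, 40)
  expect_equal(pr$pct_families_inner_membrane, 20)
  expect_equal(pr$pct_families_peri_out_wall_exported, 20)
  expect_equal(pr$pct_families_signal_peptide, 0)
  all_unknown <- make_profile_fixture(rep("unknown", 5),
                                      rep(NA_character_, 5))
  pr0 <- proteome_profile(all_unknown$proteins, all_unknown$families)
  expect_equal(pr0$pct_families_cytoplasmic, 0)
  expect_equal(pr0$pct_families_inner_membrane, 0)
  expect_equal(pr0$pct_families_peri_out_wall_exported, 0)
  expect_equal(pr0$pct_families_signal_peptide, 0)
})

test_that("annotation coverage is any-member at family level", {
  pf <- list(data.frame(pfam_id = "PF1", start = 1L, evalue = 1e-9),
             data.frame(pfam_id = character(), start = integer(),
                        evalue = numeric()),
             data.frame(pfam_id = character(), start = integer(),
                        evalue = numeric()))
  fx <- make_profile_fixture(rep("cytoplasmic", 3),
                             c("L", NA, NA), fam = c("f1", "f1", "f2"),
                             pfam = pf)
  pr <- proteome_profile(fx$proteins, fx$families)
  # f1 has a COG via p01 and a Pfam via p01; f2 has neither
  expect_equal(pr$pct_families_with_cog, 50)
  expect_equal(pr$pct_families_with_pfam, 50)
  full <- make_profile_fixture(rep("cytoplasmic", 2), c("L", "T"),
                               pfam = list(pf[[1]], pf[[1]]))
  prf <- proteome_profile(full$proteins, full$families)
  expect_equal(prf$pct_families_with_cog, 100)
  expect_equal(prf$pct_families_with_pfam, 100)
  none <- make_profile_fixture(rep("cytoplasmic", 2), c(NA, NA))
  prn <- proteome_profile(none$proteins, none$families)
  expect_equal(prn$pct_families_with_cog, 0)
  expect_equal(prn$pct_families_with_pfam, 0)
})

test_that("category representativity uses family majority with tie rule", {
  fx <- make_profile_fixture(
    rep("cytoplasmic", 7),
    cats = c("L", "L", "T", "L", "L", NA, "T"),
    fam = c("f1", "f1", "f1", "f2", "f3", "f4", "f5"))
  pr <- proteome_profile(fx$proteins, fx$families)
  cats <- pr$pct_families_by_cog_category[[1]]
  # f1 {L,L,T} -> L; f2 L; f3 L; f4 unannotated; f5 T: 5 families total
  expect_equal(cats$L, 100 * 3 / 5)
  expect_equal(cats$T, 100 * 1 / 5)
  expect_true(sum(unlist(cats)) <= 100)
  # tie between two letters resolves alphabetically
  tie <- make_profile_fixture(rep("cytoplasmic", 2), c("T", "L"),
                              fam = c("f1", "f1"))
  prt <- proteome_profile(tie$proteins, tie$families)
  expect_equal(names(prt$pct_families_by_cog_category[[1]]), "L")
})

test_that("random toy tables equal a brute-force tally", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 30
    cats <- sample(c("C", "L", "T", NA), n, replace = TRUE)
    fam <- sample(sprintf("f%02d", 1:12), n, replace = TRUE)
    fx <- make_profile_fixture(
      sample(c("cytoplasmic", "inner_membrane", "unknown"), n, TRUE),
      cats, fam = fam)
    pr <- proteome_profile(fx$proteins, fx$families)
    got <- pr$pct_families_by_cog_category[[1]]
    # brute force: per family, majority category with alphabetical ties
    tally <- c(C = 0, L = 0, T = 0)
    for (f in unique(fam)) {
      cc <- cats[fam == f]
      cc <- cc[!is.na(cc)]
      if (!length(cc)) next
      tb <- table(cc)
      tally[names(tb)[which.max(tb)]] <- tally[names(tb)[which.max(tb)]] + 1
    }
    tally <- 100 * tally / length(unique(fam))
    for (L in names(tally)[tally > 0])
      expect_equal(got[[L]], unname(tally[L]), info = L)
  }
})

test_that("profiles are invariant to protein input order", {
  gen <- cached_desk_cohort()
  r <- gen$records[[2L]]
  fams <- proteome_families(r)
  pr1 <- proteome_profile(r$proteins, fams)
  perm <- sample(nrow(r$proteins))
  pr2 <- proteome_profile(r$proteins[perm, ], fams)
  expect_equal(pr1$pct_families_cytoplasmic, pr2$pct_families_cytoplasmic)
  expect_equal(pr1$pct_families_with_cog, pr2$pct_families_with_cog)
  expect_equal(pr1$paralog_pct_overall, pr2$paralog_pct_overall)
})

test_that("all profile percentages are bounded in [0, 100]", {
  gen <- cached_desk_cohort()
  flat <- flatten_profiles(cohort_profiles(gen$records[1:4]))
  nums <- flat[, vapply(flat, is.numeric, TRUE)]
  nums <- nums[, !(names(nums) %in% c("ph_opt", "n_families"))]
  vals <- unlist(nums)
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 100))
})
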