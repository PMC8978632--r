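make_screen_table <- function(pfams, cluster_ids, present, lens,
                              copies = NULL, arch = NULL) {
  rows <- list()
  for (i in seq_along(pfams)) {
    for (j in seq_along(cluster_ids)) {
      if (!present[[i]][j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        pfam_id = pfams[i], cluster_id = cluster_ids[j],
        n_carriers = if (is.null(copies)) 1L else copies[[i]][j],
        n_genomes = 1L,
        mean_len = lens[[i]][j],
        architectures = I(list(if (is.null(arch)) {
          t <- table(pfams[i]); t
        } else arch[[i]][[j]])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("conservation selection applies strict fraction and span rules", {
  ph <- stats::setNames(seq(1, 8, length.out = 10), sprintf("c%02d", 1:10))
  everywhere <- rep(TRUE, 10)
  half <- c(rep(TRUE, 5), rep(FALSE, 5))
  nine <- c(rep(TRUE, 9), FALSE)  # carrier span 1-7.2, still >= 6 units
  tbl <- make_screen_table(
    c("PFall", "PFhalf", "PFnine"), names(ph),
    list(everywhere, half, nine),
    list(rep(300, 10), rep(300, 10), rep(300, 10)))
  expect_equal(select_conserved(tbl, ph), "PFall")  # 90.0% excluded (strict)
  expect_equal(select_conserved(tbl, ph, min_species_frac = 0.85),
               c("PFall", "PFnine"))
  # span below 6 pH units excludes even ubiquitous pfams
  ph_narrow <- stats::setNames(seq(3, 7, length.out = 10), names(ph))
  expect_equal(select_conserved(tbl, ph_narrow), character())
})

test_that("single-copy / dominant-architecture restriction works", {
  ph <- stats::setNames(seq(1, 8, length.out = 10), sprintf("c%02d", 1:10))
  all10 <- rep(TRUE, 10)
  single_arch <- lapply(1:10, function(i) table("PFa"))
  mixed_arch <- lapply(1:10, function(i) {
    if (i <= 4) table("PFb") else table("PFb+PFx")  # 40/60 split
  })
  even_arch <- lapply(1:10, function(i) {
    if (i <= 5) table("PFc") else table("PFc+PFx")  # exactly 50/50
  })
  tbl <- make_screen_table(
    c("PFa", "PFb", "PFc", "PFd"), names(ph),
    list(all10, all10, all10, all10),
    list(rep(300, 10), rep(300, 10), rep(300, 10), rep(300, 10)),
    copies = list(rep(1L, 10), rep(1L, 10), rep(1L, 10), rep(2L, 10)),
    arch = list(single_arch, mixed_arch, even_arch, single_arch))
  kept <- select_single_copy_single_arch(c("PFa", "PFb", "PFc", "PFd"), tbl)
  expect_true("PFa" %in% kept)
  expect_true("PFb" %in% kept)    # 60% > 50% dominance
  expect_false("PFc" %in% kept)   # 50% is not > 50%
  expect_false("PFd" %in% kept)   # mean 2 copies/genome >= 1.1
})

test_that("per-pfam trends recover planted slopes and exclude degenerates", {
  set.seed(61)
  ph <- stats::setNames(runif(40, 1, 8), sprintf("c%02d", 1:40))
  lens_up <- round(300 + 5 * (ph - 7) + rnorm(40, 0, 2))
  tbl <- make_screen_table("PFup", names(ph), list(rep(TRUE, 40)),
                           list(lens_up))
  tr <- per_pfam_trend("PFup", tbl, ph)
  expect_gt(tr$pearson_r, 0.9)
  expect_lt(tr$p_value, 1e-10)
  # constant lengths are excluded, as are < 3 species
  tbl_const <- make_screen_table("PFc", names(ph)[1:5], list(rep(TRUE, 5)),
                                 list(rep(300, 5)))
  expect_null(per_pfam_trend("PFc", tbl_const, ph))
  tbl_two <- make_screen_table("PFt", names(ph)[1:2], list(rep(TRUE, 2)),
                               list(c(280, 300)))
  expect_null(per_pfam_trend("PFt", tbl_two, ph))
})

test_that("null planted slopes stay nonsignificant at q = 0.05", {
  set.seed(62)
  nonsig <- vapply(1:20, function(rep) {
    ph <- stats::setNames(runif(40, 1, 8), sprintf("c%02d", 1:40))
    lens <- round(rnorm(40, 300, 4))
    tbl <- make_screen_table("PF0", names(ph), list(rep(TRUE, 40)),
                             list(lens))
    scr <- screen_pfam_trends(tbl, ph, min_species_frac = 0,
                              min_ph_span = 0)
    scr$sign == "nonsignificant"
  }, TRUE)
  expect_gte(mean(nonsig), 0.9)
})

test_that("census counts, ratio and sign test follow the stated conventions", {
  trends <- data.frame(sign = c(rep("positive", 10), rep("negative", 10)))
  cen <- trend_census(trends)
  expect_equal(cen$ratio, 1)
  expect_equal(cen$binomial_p, oracle_binom_enum(10, 20, 0.5))
  none <- trend_census(data.frame(sign = rep("nonsignificant", 5)))
  expect_equal(none$n_positive, 0L)
  expect_true(is.na(none$ratio))
  expect_true(is.na(none$binomial_p))
})

test_that("the screen recovers planted sign counts on the default cohort", {
  truth <- draw_cohort_truth(cohort_config(seed = 77L))
  tbl <- draw_pfam_screen_table(truth)
  ph <- stats::setNames(truth$species$ph_opt, truth$species$species_id)
  scr <- screen_pfam_trends(tbl, ph)
  n_pos <- sum(scr$sign == "positive")
  n_neg <- sum(scr$sign == "negative")
  cfg <- truth$config
  expect_lte(abs(n_pos - cfg$n_pfam_shrink), 5)
  expect_lte(abs(n_neg - cfg$n_pfam_grow), 5)
  cen <- trend_census(scr)
  expect_gt(cen$ratio, 1)
  # sign convention: shrinking-at-low-pH plants have positive r
  shrink_ids <- truth$pfams$pfam_id[truth$pfams$len_slope > 0]
  got <- scr[scr$pfam_id %in% shrink_ids & scr$sign != "nonsignificant", ]
  expect_true(all(got$pearson_r > 0))
})

test_that("screen on the realized desk cohort matches planted pfams", {
  gen <- cached_desk_cohort()
  recs <- gen$records
  memb <- data.frame(
    genome_id = vapply(recs, `[[`, "", "genome_id"),
    cluster_id = sub("G\\d+$", "", vapply(recs, `[[`, "", "genome_id")))
  tbl <- pfam_species_table(recs, memb)
  ph <- stats::setNames(gen$truth$species$ph_opt,
                        gen$truth$species$species_id)
  scr <- screen_pfam_trends(tbl, ph)
  # only planted (conserved) pfams survive selection; fillers are too rare
  expect_true(all(scr$pfam_id %in% gen$truth$pfams$pfam_id))
  expect_gt(nrow(scr), 5)
  # the BH family is the screened set, applied once
  expect_equal(scr$q_value, bh_fdr(scr$p_value)$q_value)
})
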