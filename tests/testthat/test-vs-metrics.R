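# Build a screen table directly from vectors.
tab_from <- function(ids, role, pharm = NULL, scores, chem = NULL) {
  screen_table(tibble::tibble(
    id = ids, role = role,
    pharmacology = pharm %||% ifelse(role == "active", "agonist", "none"),
    chemotype = chem %||% NA_character_, score_1 = scores))
}

test_that("best_of_repeats picks the most favourable repeat", {
  t1 <- screen_table(tibble::tibble(
    id = c("a", "b", "c"), role = c("active", "active", "decoy"),
    pharmacology = c("agonist", "agonist", "none"),
    score_1 = c(-32.1, -10.0, -5), score_2 = c(-30.5, NA, -5),
    score_3 = c(-33.4, NA, -5)))
  out <- best_of_repeats(t1)
  expect_equal(out$best_score, c(-33.4, -10.0, -5))
  # permutation invariance over repeat order
  t2 <- t1
  t2$score_1 <- t1$score_3; t2$score_3 <- t1$score_1
  expect_equal(best_of_repeats(t2)$best_score, out$best_score)
  # higher-is-better polarity flips the aggregation
  expect_equal(best_of_repeats(t1, lower_is_better = FALSE)$best_score,
               c(-30.5, -10.0, -5))
  t_bad <- t1; t_bad$score_1[2] <- NA
  expect_error(best_of_repeats(t_bad), regexp = "b", class = "data_error")
})

test_that("recovery ROC endpoints, perfect and random orderings behave", {
  tab <- tab_from(sprintf("c%02d", 1:10),
                  rep(c("active", "decoy"), each = 5),
                  scores = c(1:5, 6:10))  # all actives first
  roc <- roc_recovery(tab)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(roc_auc(roc), 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  # alternating A,D,A,D,A,D matches brute-force confusion counting
  tab3 <- tab_from(sprintf("c%d", 1:6),
                   rep(c("active", "decoy"), times = 3),
                   scores = 1:6)
  roc3 <- roc_recovery(tab3)
  expect_equal(roc_auc(roc3), mann_whitney_auc(c(1, 3, 5), c(2, 4, 6)))
  expect_error(roc_recovery(tab_from("x", "active", scores = 1)),
               class = "class_error")
})

test_that("recovery AUC equals the exhaustive Mann-Whitney U oracle", {
  set.seed(5)
  for (n in c(6, 8)) {
    scores <- sort(round(rnorm(n), 3))  # distinct, ranked order = index
    for (mask in 1:(2^n - 2)) {
      is_act <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
      if (!any(is_act) || all(is_act)) next
      tab <- tab_from(sprintf("c%02d", seq_len(n)),
                      ifelse(is_act, "active", "decoy"), scores = scores)
      expect_equal(roc_auc(roc_recovery(tab)),
                   mann_whitney_auc(which(is_act), which(!is_act)))
    }
  }
})

test_that("selectivity ROC uses actives only and errors when a class is absent", {
  tab <- screen_table(tibble::tibble(
    id = sprintf("c%d", 1:9),
    role = c(rep("active", 8), "decoy"),
    pharmacology = c(rep("agonist", 4), rep("inhibitor", 4), "none"),
    score_1 = c(1:4, 5:8, 0.5)))
  roc <- roc_selectivity(tab, positive = "agonist")
  expect_equal(roc_auc(roc), 1)  # agonists all rank above inhibitors
  # mixed 4+4 ordering against the pairwise oracle
  tab2 <- tab
  tab2$score_1 <- c(1, 3, 5, 7, 2, 4, 6, 8, 0.1)
  expect_equal(roc_auc(roc_selectivity(tab2, positive = "agonist")),
               mann_whitney_auc(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  no_ag <- tab
  no_ag$pharmacology[no_ag$pharmacology == "agonist"] <- "inhibitor"
  expect_error(roc_selectivity(no_ag, positive = "agonist"),
               class = "class_error")
})

test_that("NSQ_AUC anchors: perfect 100, diagonal ~0, reversed -50", {
  n_act <- 50; n_dec <- 450
  perfect <- tab_from(sprintf("c%03d", 1:(n_act + n_dec)),
                      c(rep("active", n_act), rep("decoy", n_dec)),
                      scores = 1:(n_act + n_dec))
  expect_equal(nsq_auc(roc_recovery(perfect)), 100, tolerance = 1e-9)
  reversed <- perfect
  reversed$score_1 <- rev(reversed$score_1)
  expect_equal(nsq_auc(roc_recovery(reversed)), -50, tolerance = 0.5)
  # exact centred interleaving lies on the diagonal
  n <- 1010; act_pos <- seq(51, n, by = 101)
  role <- rep("decoy", n); role[act_pos] <- "active"
  inter <- tab_from(sprintf("c%04d", 1:n), role, scores = 1:n)
  expect_equal(nsq_auc(roc_recovery(inter)), 0, tolerance = 1.5)
})

test_that("NSQ_AUC endpoints hold for every seeded generated table", {
  for (s in 1:5) {
    tab <- make_screen_table(screen_spec(n_agonists = 10, n_inhibitors = 10,
                                         n_decoys = 180, seed = s))
    n_act <- sum(tab$role == "active")
    tab$score_1 <- ifelse(tab$role == "active", -100, 0) + seq_len(nrow(tab)) * 1e-3
    tab$score_2 <- tab$score_3 <- tab$score_1
    expect_equal(nsq_auc(roc_recovery(tab)), 100, tolerance = 1e-9)
    tab$score_1 <- -tab$score_1
    tab$score_2 <- tab$score_3 <- tab$score_1
    expect_lt(nsq_auc(roc_recovery(tab)), -45)
  }
})

test_that("ranking-derived metrics are invariant under monotone score transforms", {
  tab <- make_screen_table(screen_spec(n_agonists = 15, n_inhibitors = 10,
                                       n_decoys = 75, seed = 3))
  tab <- best_of_repeats(tab)
  base_roc <- roc_recovery(tab)
  base_ef <- enrichment_factors(tab)
  for (f in list(function(x) 2 * x + 7, function(x) x^3,
                 function(x) -exp(-x / 50))) {
    t2 <- tab
    for (cn in c("score_1", "score_2", "score_3", "best_score")) {
      t2[[cn]] <- f(t2[[cn]])
    }
    expect_equal(roc_auc(roc_recovery(t2)), roc_auc(base_roc))
    expect_equal(nsq_auc(roc_recovery(t2)), nsq_auc(base_roc))
    expect_equal(enrichment_factors(t2)$ef, base_ef$ef)
  }
})

test_that("enrichment factors hit their closed forms", {
  n <- 1000
  # cluster of 50 actives; 5 of them inside the top 1% (10 compounds)
  chem <- rep(NA_character_, n)
  role <- rep("decoy", n)
  cluster_pos <- c(1:5, seq(100, 144))  # 5 early, 45 later
  role[cluster_pos] <- "active"; chem[cluster_pos] <- "CL"
  tab <- tab_from(sprintf("c%04d", 1:n), role, scores = 1:n, chem = chem)
  ef <- enrichment_factors(tab, fractions = 0.01)
  expect_equal(ef$ef[ef$chemotype == "CL"], (5 / 10) / (50 / 1000))  # = 10
  expect_equal(ef$n_top[1], 10)
  # all top-1% slots filled by cluster members -> EF = 1/f = 20
  chem2 <- rep(NA_character_, n); role2 <- rep("decoy", n)
  pos2 <- c(1:10, seq(100, 139))
  role2[pos2] <- "active"; chem2[pos2] <- "CL"
  tab2 <- tab_from(sprintf("c%04d", 1:n), role2, scores = 1:n, chem = chem2)
  ef2 <- enrichment_factors(tab2, fractions = 0.01)
  expect_equal(ef2$ef[ef2$chemotype == "CL"], 20)
  # the union of all compounds has EF exactly 1 at every fraction
  ef_all <- enrichment_factors(tab, fractions = c(0.01, 0.05, 0.1))
  expect_true(all(ef_all$ef[ef_all$chemotype == "all"] == 1))
  # uniformly spread cluster stays near EF 1
  chem3 <- rep(NA_character_, n); role3 <- rep("decoy", n)
  pos3 <- seq(5, n, by = 20)
  role3[pos3] <- "active"; chem3[pos3] <- "CL"
  tab3 <- tab_from(sprintf("c%04d", 1:n), role3, scores = 1:n, chem = chem3)
  ef3 <- enrichment_factors(tab3, fractions = c(0.05, 0.10))
  expect_true(all(abs(ef3$ef[ef3$chemotype == "CL"] - 1) < 0.35))
  # empty cluster flagged, not an error
  ef4 <- enrichment_factors(tab, fractions = 0.01, clusters = c("CL", "ZZ"))
  expect_true(ef4$undefined[ef4$chemotype == "ZZ"])
  expect_true(is.na(ef4$ef[ef4$chemotype == "ZZ"]))
  # EF never exceeds 1/fraction
  expect_true(all(ef_all$ef <= 1 / ef_all$fraction + 1e-12, na.rm = TRUE))
})

test_that("refinement ligand rank and percentile", {
  tab <- tab_from(sprintf("c%03d", 1:200),
                  rep(c("active", "decoy"), 100), scores = 1:200)
  expect_equal(refinement_ligand_rank(tab, "c001"),
               list(rank = 1, percentile = 1 / 200))
  expect_equal(refinement_ligand_rank(tab, "c101")$percentile, 0.505)
  expect_error(refinement_ligand_rank(tab, "zzz"), class = "id_error")
})

test_that("screen CSV round-trips through the readers", {
  tab <- make_screen_table(screen_spec(n_agonists = 5, n_inhibitors = 5,
                                       n_decoys = 20, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_screen_csv(tab, path)
  back <- read_screen_csv(path)
  expect_equal(back$id, tab$id)
  expect_equal(back$score_2, tab$score_2)
  expect_s3_class(autoplot(roc_recovery(best_of_repeats(back))), "ggplot")
})
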