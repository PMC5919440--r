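test_that("overlap summary counts common edges and averages gold scores", {
  gold <- scored_edges(edges_df(c("a", "b"), c("c", "d"), c("e", "f")),
                       score = c(1, 2, 3))
  same <- overlap_summary(gold, gold, top_k = 3)
  expect_equal(same$n_common, 3L)
  expect_equal(same$mean_common, 2)
  expect_equal(same$mean_top, 2)

  other <- scored_edges(edges_df(c("x", "y")), score = 9)
  disj <- overlap_summary(other, gold, top_k = 5)
  expect_equal(disj$n_common, 0L)
  expect_true(is.na(disj$mean_common))
  expect_true(is.na(disj$mean_top))
  expect_equal(disj$top_shortfall, 5L)

  # five common edges with gold scores 1..5; the top 3 by predicted score
  # carry gold scores 5, 4, 3
  pred <- scored_edges(edges_df(c("a", "b"), c("c", "d"), c("e", "f"),
                                c("g", "h"), c("i", "j")),
                       score = c(10, 20, 30, 40, 50))
  gold5 <- scored_edges(edges_df(c("a", "b"), c("c", "d"), c("e", "f"),
                                 c("g", "h"), c("i", "j")),
                        score = 1:5)
  top3 <- overlap_summary(pred, gold5, top_k = 3)
  expect_equal(top3$mean_top, 4)
  expect_equal(top3$mean_common, 3)
  # the alternative averaging uses the predicted scores instead
  expect_equal(overlap_summary(pred, gold5, top_k = 3,
                               average = "predicted")$mean_top, 40)
})

test_that("score combination is the weighted sum with identity at zero", {
  expect_equal(combine_scores(5, 3, 0), 3)
  expect_equal(combine_scores(2, 3, 0.5), 4)
  expect_equal(combine_scores(1344, 0, 1), 1344)
  expect_equal(combine_scores(c(1, 2), c(10, 20), 2), c(12, 24))
})

test_that("combining scored sets uses union-of-edges semantics", {
  g <- scored_edges(edges_df(c("a", "b"), c("c", "d")), score = c(2, 1))
  e <- scored_edges(edges_df(c("c", "d"), c("e", "f")), score = c(10, 20))
  comb <- combine_scored_sets(g, e, spe = 0.5)
  expect_equal(nrow(comb), 3L)
  key <- paste(comb$protein_a, comb$protein_b)
  expect_equal(comb$score[key == "a b"], 1)    # S_e absent contributes 0
  expect_equal(comb$score[key == "c d"], 10.5)
  expect_equal(comb$score[key == "e f"], 20)   # S_g absent contributes 0
})

test_that("confusion criteria match hand-computed cases", {
  uni <- pair_universe(c("a", "b", "c", "d"))  # 6 pairs
  pred <- edges_df(c("a", "b"), c("a", "c"))
  gold <- edges_df(c("a", "b"), c("b", "c"))
  met <- confusion_metrics(pred, gold, uni)
  expect_equal(unname(met$counts), c(1L, 1L, 3L, 1L))  # TP FP TN FN
  expect_equal(met$recall, 0.5)
  expect_equal(met$precision, 0.5)
  expect_equal(met$specificity, 0.75)
  expect_equal(met$accuracy, 4 / 6)
  expect_equal(met$f_measure, 0.5)
  expect_equal(met$mcc, (1 * 3 - 1 * 1) / sqrt(2 * 2 * 4 * 4))

  # TP = FP = TN = FN = 1 has zero correlation
  uni4 <- pair_universe(c("p", "q", "r", "s"))[1:4, ]
  met0 <- confusion_metrics(uni4[1:2, ], uni4[c(1, 3), ], uni4)
  expect_equal(met0$mcc, 0)
})

test_that("zero-denominator criteria are undefined, never silently zero", {
  uni <- pair_universe(c("a", "b", "c"))
  all_pos <- confusion_metrics(uni, uni, uni)
  expect_equal(all_pos$recall, 1)
  expect_equal(all_pos$precision, 1)
  expect_equal(all_pos$accuracy, 1)
  expect_true(is.na(all_pos$specificity))  # no negatives exist

  none <- confusion_metrics(uni[0, ], uni[1, ], uni)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))       # no positive predictions

  expect_error(confusion_metrics(edges_df(c("x", "y")), uni[1, ], uni),
               "universe")
})

test_that("confusion identities hold on random prediction sets", {
  withr::with_seed(7, {
    uni <- pair_universe(sprintf("g%02d", 1:8))
    for (rep in 1:5) {
      pred <- uni[sample(nrow(uni), 10), ]
      gold <- uni[sample(nrow(uni), 12), ]
      met <- confusion_metrics(pred, gold, uni)
      cc <- met$counts
      expect_equal(sum(cc), nrow(uni))
      expect_equal(met$recall + cc[["FN"]] / (cc[["TP"]] + cc[["FN"]]), 1)
      if (!is.na(met$f_measure))
        expect_equal(met$f_measure,
                     2 / (1 / met$precision + 1 / met$recall))
    }
  })
})

test_that("AUC handles separation, ties, and midrank counting", {
  perfect <- data.frame(score = c(5, 4, 1, 0),
                        label = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(perfect), 1)
  flat <- data.frame(score = rep(2, 6),
                     label = rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(flat), 0.5)
  # two positives (3, 1) vs one negative (2): one comparison won, one lost
  expect_equal(roc_auc(data.frame(score = c(3, 1, 2),
                                  label = c(TRUE, TRUE, FALSE))), 0.5)
  # positives (3, 2.5) vs negatives (2, 1): all four comparisons won
  expect_equal(roc_auc(data.frame(score = c(3, 2.5, 2, 1),
                                  label = c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_error(roc_auc(data.frame(score = 1:3, label = rep(TRUE, 3))),
               "positive and one negative")
})

test_that("AUC is invariant under monotone transforms and matches pROC", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      sc <- round(stats::rnorm(40), 2)
      lab <- stats::runif(40) < 0.4
      if (!any(lab) || all(lab)) next
      d <- data.frame(score = sc, label = lab)
      a <- roc_auc(d)
      expect_equal(roc_auc(transform(d, score = exp(score / 2))), a)
      expect_equal(roc_auc(transform(d, score = rank(score))), a)
      ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(a, ref)
    }
  })
})

test_that("zero-weight combination leaves the external AUC unchanged", {
  withr::with_seed(13, {
    prot <- sprintf("y%02d", 1:10)
    uni <- pair_universe(prot)
    ext <- scored_edges(uni[sample(nrow(uni), 20), ],
                        score = round(stats::runif(20), 3))
    grd <- scored_edges(uni[sample(nrow(uni), 8), ], score = 8:1)
    gold_keys <- sample(paste(uni$protein_a, uni$protein_b), 15)
    lab_of <- function(df) paste(df$protein_a, df$protein_b) %in% gold_keys
    ext$label <- lab_of(ext)
    base_auc <- roc_auc(ext)
    comb <- combine_scored_sets(grd, ext, spe = 0)
    comb$label <- lab_of(comb)
    # restrict to the external edges: spe = 0 must reproduce S_e exactly
    keep <- paste(comb$protein_a, comb$protein_b) %in%
      paste(ext$protein_a, ext$protein_b)
    expect_equal(roc_auc(comb[keep, ]), base_auc)
  })
})
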