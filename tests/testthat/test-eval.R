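test_that("AUC is the Mann-Whitney statistic with half-credit ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  expect_equal(auc(rep(2, 6), c(-1, 1, -1, 1, -1, 1)), 0.5)
  # 4-point example against the exhaustive pair-count oracle
  s <- c(0.1, 0.8, 0.5, 0.8); y <- c(-1, 1, -1, 1)
  pairs <- expand.grid(p = which(y == 1), n = which(y == -1))
  manual <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(auc(s, y), manual)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # invariance under strictly monotone transforms
  set.seed(51)
  s <- rnorm(60); y <- sample(c(-1, 1), 60, replace = TRUE)
  expect_equal(auc(s, y), auc(exp(s), y))
  expect_equal(auc(s, y), auc(atan(2 * s + 1), y))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  s <- rnorm(80); y <- sample(c(-1, 1), 80, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c(-1, 1), direction = "<",
                                        quiet = TRUE)))
  expect_equal(auc(s, y), ref, tolerance = 1e-12)
})

test_that("scores are carried to cutoff times with carry-back at the start", {
  tab <- data.frame(embryo_id = rep("e1", 3), t_hours = c(40, 60, 80),
                    score = c(1, 2, 3))
  expect_equal(unname(score_at_time(tab, 70)), 2)   # latest at/before t
  expect_equal(unname(score_at_time(tab, 60)), 2)
  expect_equal(unname(score_at_time(tab, 35)), 1)   # documented carry-back
  # constant scores give a flat AUC curve
  tab2 <- data.frame(embryo_id = rep(c("p", "n"), each = 3),
                     t_hours = rep(c(40, 60, 80), 2),
                     score = rep(c(2, 1), each = 3))
  labs <- c(p = 1, n = -1)
  curve <- auc_over_time(tab2, labs, c(45, 65, 85))
  expect_equal(curve$auc, rep(1, 3))
  expect_error(auc_over_time(tab2, labs, numeric(0)), "empty")
})

test_that("age-binned AUC partitions correctly and flags empty bins", {
  set.seed(53)
  n <- 120
  ages <- runif(n, 26, 44)
  y <- sample(c(-1, 1), n, replace = TRUE)
  s <- rnorm(n) + 0.8 * y
  # one bin spanning everything equals the global AUC
  one <- auc_by_age(s, y, ages, c(20, 50))
  expect_equal(one$auc, auc(s, y))
  # the clinical report layout: 2-year bins centred 27..43 -> 9 bins
  edges <- seq(26, 44, by = 2)
  tab <- auc_by_age(s, y, ages, edges)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$ok))
  # an empty bin is flagged, not dropped
  tab2 <- auc_by_age(s, y, ages, c(0, 5, 50))
  expect_false(tab2$ok[1]); expect_true(is.na(tab2$auc[1]))
  expect_equal(nrow(tab2), 2L)
})

test_that("threshold selection minimizes FP + FN with smallest-tH ties", {
  rep0 <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(-1, -1, 1, 1))
  expect_equal(rep0$FP + rep0$FN, 0)
  expect_gt(rep0$tH, 0.2); expect_lte(rep0$tH, 0.8)
  # degenerate single-class input: sentinel threshold, zero FN
  rep1 <- select_threshold(c(0.3, 0.6), c(1, 1))
  expect_lt(rep1$tH, 0.3)
  expect_equal(rep1$FN, 0)
  # report fields are coherent rates
  set.seed(54)
  s <- rnorm(40); y <- sample(c(-1, 1), 40, replace = TRUE)
  rp <- select_threshold(s, y)
  expect_true(all(c(rp$FP, rp$FN, rp$accuracy_01) >= 0 &
                    c(rp$FP, rp$FN, rp$accuracy_01) <= 1))
  cnt <- rp$counts
  expect_equal(rp$PPV, cnt["TP"] / (cnt["TP"] + cnt["FP"]),
               ignore_attr = TRUE)
  expect_equal(rp$NPV, cnt["TN"] / (cnt["TN"] + cnt["FN"]),
               ignore_attr = TRUE)
  # 100 random instances against the exhaustive sweep oracle
  for (r in 1:100) {
    n <- sample(4:50, 1)
    s <- round(rnorm(n), 2)  # duplicated scores exercise tie handling
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) == 1) y[1] <- -y[1]
    got <- select_threshold(s, y)
    expect_equal(sum(y == -1 & s >= got$tH) + sum(y == 1 & s < got$tH),
                 oracle_threshold(s, y))
  }
})

test_that("the per-stage report mirrors the clinical evaluation layout", {
  set.seed(55)
  ids <- sprintf("e%02d", 1:40)
  emb <- data.frame(
    embryo_id = ids, clinic = "c", oocyte_age_years = runif(40, 27, 43),
    kid_tag = rep(c("KIDp", "KIDn", "notKID", "notKID"), 10),
    ploidy_tag = rep(c("none", "aneuploid", "none", "none"), 10),
    hard_discarded = rep(c(FALSE, FALSE, FALSE, TRUE), 10),
    split = "test", n_frames = 2
  )
  quality <- ifelse(emb$kid_tag == "KIDp", 1.5,
                    ifelse(emb$hard_discarded, -1.5, 0)) + rnorm(40, sd = 0.3)
  tabs <- lapply(setNames(nm = c("A", "B", "C", "D", "E", "F")), function(st) {
    data.frame(embryo_id = rep(ids, each = 2), t_hours = rep(c(72, 114), 40),
               score = rep(quality, each = 2))
  })
  for (neg in c("KIDn", "aneuploid", "discarded", "hard_discarded")) {
    repn <- score_report(tabs, emb, negatives = neg)
    expect_equal(nrow(repn), 12L)  # 6 stages x 2 days
    expect_true(all(repn$auc >= 0 & repn$auc <= 1))
  }
  # hard-discarded embryos are a subset of discarded: with scores that rank
  # them lowest, the subset task is at least as easy
  a_disc <- score_report(tabs["F"], emb, "discarded")$auc[2]
  a_hard <- score_report(tabs["F"], emb, "hard_discarded")$auc[2]
  expect_gte(a_hard, a_disc - 1e-9)
  expect_error(score_report(tabs, emb[emb$kid_tag != "KIDn", ], "KIDn"),
               "empty")
})
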