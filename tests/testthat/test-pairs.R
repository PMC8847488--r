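test_that("pair score is the antisymmetric student difference", {
  expect_equal(pair_score(0.7, 0.2), 0.5)
  expect_equal(pair_score(1.3, 1.3), 0)
  set.seed(41)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pair_score(a, b), -pair_score(b, a))
})

test_that("pseudo labels gate on the teacher gap and protect KIDp", {
  expect_equal(pair_label(0.9, 0.5, "notKID", "notKID", 0.2), 1)
  expect_equal(pair_label(0.9, 0.5, "notKID", "KIDp", 0.2), 0)  # protected
  expect_equal(pair_label(0.6, 0.5, "KIDu", "KIDn", 0.2), 0)    # gap <= theta
  # exhaustive truth table: all tag pairs x gap signs x theta
  tags <- c("KIDp", "KIDn", "KIDu", "notKID")
  for (ti in tags) for (tj in tags) {
    for (gap in c(-1, -0.1, 0, 0.1, 1)) {
      for (theta in c(0, 0.5)) {
        y <- pair_label(gap, 0, ti, tj, theta)
        # antisymmetry under swapping the pair
        expect_identical(y, -pair_label(0, gap, tj, ti, theta))
        # KIDp never loses
        if (y == 1) expect_false(tj == "KIDp")
        if (y == -1) expect_false(ti == "KIDp")
        # the gate is strict
        if (abs(gap) <= theta) expect_identical(y, 0)
      }
    }
  }
})

test_that("the oocyte-age gate compares absolute gaps", {
  expect_true(valid_pair(31.0, 32.5, 2))
  expect_false(valid_pair(31.0, 34.0, 2))
  expect_true(valid_pair(40, 40, 0))
  expect_true(valid_pair(34.0, 31.0, 2) == valid_pair(31.0, 34.0, 2))
})

test_that("theta estimation follows the matched-bin histogram rule", {
  set.seed(42)
  pos <- rnorm(400, 1, 0.7)
  # identical score multisets: every matched bin cancels
  expect_equal(estimate_theta(pos, pos), 0)
  # an elementwise shift is recovered exactly by matched bins
  for (delta in c(0.25, 1, 3)) {
    expect_equal(estimate_theta(pos, pos - delta), delta, tolerance = 1e-9)
  }
  # disjoint degenerate distributions fall back to the mean difference
  expect_equal(estimate_theta(rep(1, 10), rep(0, 10)), 1)
  # the gate is clamped at zero when the classes are inverted
  expect_equal(estimate_theta(pos - 5, pos), 0)
  expect_error(estimate_theta(numeric(0), pos), "both classes")
})

test_that("batch pair enumeration gates, labels and drops zeros", {
  set.seed(43)
  batch <- data.frame(
    embryo_id = sprintf("e%02d", 1:24),
    teacher_score = rnorm(24, sd = 2),
    kid_tag = sample(c("KIDp", "KIDn", "KIDu", "notKID"), 24, replace = TRUE),
    oocyte_age_years = runif(24, 28, 38)
  )
  cfg <- pairing_config(theta = 0.5, theta_o = 2)
  pairs <- build_batch_pairs(batch, cfg)
  expect_lte(nrow(pairs), choose(24, 2))  # at most 276 candidates
  expect_true(all(pairs$y %in% c(-1, 1)))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    expect_lte(abs(batch$oocyte_age_years[i] - batch$oocyte_age_years[j]), 2)
    expect_gt(abs(batch$teacher_score[i] - batch$teacher_score[j]), 0.5)
    if (pairs$y[k] == 1) expect_false(batch$kid_tag[j] == "KIDp")
    if (pairs$y[k] == -1) expect_false(batch$kid_tag[i] == "KIDp")
  }
  # same ages + confident teacher + no KIDp: every age-valid pair labeled
  b2 <- data.frame(embryo_id = c("a", "b", "c"),
                   teacher_score = c(0, 10, 20),
                   kid_tag = "notKID", oocyte_age_years = 30)
  expect_equal(nrow(build_batch_pairs(b2, pairing_config(theta = 1))), 3L)
  # an infinite gate closes everything
  expect_equal(nrow(build_batch_pairs(b2, pairing_config(theta = Inf))), 0L)
  # all-KIDp batches can never label a pair (both sides protected)
  b3 <- b2; b3$kid_tag <- "KIDp"
  expect_equal(nrow(build_batch_pairs(b3, pairing_config(theta = 1))), 0L)
  # an unlabeled embryo takes part whenever teacher gaps permit
  expect_true(any(c(pairs$i, pairs$j) %in%
                    which(batch$kid_tag %in% c("KIDu", "notKID"))))
})

test_that("pair loss sums soft hinges over labeled pairs and matches the oracle", {
  cfg <- pairing_config(theta = 0)
  one <- data.frame(i = 1L, j = 2L, y = 1)
  expect_equal(pair_loss(one, c(1.5, 0.5), cfg), log(2))  # s_ij = m
  expect_equal(pair_loss(one[0, ], numeric(0), cfg), 0)
  expect_error(pair_loss(one, c(1, NA), cfg), "missing")
  # sign symmetry: flipping labels and negating scores leaves the loss fixed
  set.seed(44)
  s <- rnorm(10); pr <- data.frame(i = sample(10, 8, TRUE),
                                   j = sample(10, 8, TRUE),
                                   y = sample(c(-1, 1), 8, TRUE))
  pr <- pr[pr$i != pr$j, ]
  flipped <- pr; flipped$y <- -flipped$y
  expect_equal(pair_loss(pr, s, cfg), pair_loss(flipped, -s, cfg))
  # brute-force enumeration oracle
  manual <- 0
  for (k in seq_len(nrow(pr))) {
    d <- s[pr$i[k]] - s[pr$j[k]]
    manual <- manual + log(1 + exp(1 * (1 - pr$y[k] * d)))
  }
  expect_equal(pair_loss(pr, s, cfg), manual, tolerance = 1e-10)
  # double counting exactly doubles the loss
  expect_equal(pair_loss(pr, s, pairing_config(theta = 0, double_count = TRUE)),
               2 * pair_loss(pr, s, cfg))
})

test_that("pair-loss gradients match numerical differentiation", {
  set.seed(45)
  s <- rnorm(6)
  pr <- data.frame(i = c(1L, 2L, 5L), j = c(3L, 4L, 6L), y = c(1, -1, 1))
  cfg <- pairing_config(theta = 0)
  g <- embryopcl:::pair_loss_grad(pr, s, cfg)
  h <- 1e-6
  for (k in 1:6) {
    sp <- s; sp[k] <- sp[k] + h
    sm <- s; sm[k] <- sm[k] - h
    expect_equal(g[k], (pair_loss(pr, sp, cfg) - pair_loss(pr, sm, cfg)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("a gate wider than the teacher range leaves the student untrained", {
  dir <- tiny_cohort_dir(n = 30, image_size = 48, interval = 360, seed = 101)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  df <- as.data.frame(man)
  cfg <- classifier_config(input_size = 32, pool_size = 8, hidden = 4)
  feat <- frame_features(man, cfg, root = dir, rows = which(df$split == "train"))
  emb <- embryo_table(man)
  emb_tr <- emb[emb$split == "train", ]
  teacher <- rnorm(nrow(emb_tr)); names(teacher) <- emb_tr$embryo_id
  st <- train_student(feat, emb_tr, teacher,
                      pairing_config(theta = 1e6), cfg, steps = 20, seed = 1)
  expect_true(all(st$log$n_pairs == 0))
  # zero-initialized readouts were never updated: all scores identical 0
  expect_true(all(score_frames(st, feat$X, feat$frames$t_hours) == 0))
  # missing teacher coverage is a data error
  expect_error(train_student(feat, emb_tr, teacher[-1],
                             pairing_config(theta = 1), cfg, steps = 5),
               "missing")
})
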