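test_that("entropy hits its closed-form values and matches direct evaluation", {
  expect_identical(entropy(c(4, 0)), 0)
  expect_identical(entropy(c(2, 2)), 1)
  # independent high-precision evaluation of -3/4 log2(3/4) - 1/4 log2(1/4)
  # = 2 - (3/4) log2 3
  expect_equal(entropy(c(3, 1)), 0.8112781244591329, tolerance = 1e-14)
  expect_equal(entropy(c(1, 3)), entropy(c(3, 1)))  # permutation symmetry
  # concave-maximal at even proportions
  for (k in 1:7) expect_lte(entropy(c(k, 8 - k)), 1)
  expect_error(entropy(c(0, 0)), "positive total")
})

test_that("best_split finds the perfect midpoint split and its gain", {
  X <- data.frame(alpha = c(170, 175, 300, 310))
  y <- c(0L, 0L, 1L, 1L)
  sp <- best_split(X, y, features = "alpha")
  expect_equal(sp$feature, "alpha")
  expect_equal(sp$threshold, 237.5)
  expect_equal(sp$gain, 1)
  expect_null(best_split(X, c(0L, 0L, 0L, 0L)))          # single label
  expect_null(best_split(X[1, , drop = FALSE], 0L))      # too small
})

test_that("best_split equals exhaustive enumeration over midpoints", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(6:60, 1)
    X <- as.data.frame(setNames(
      lapply(ANGLE_NAMES, function(a) runif(n, 0, 360)), ANGLE_NAMES))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- best_split(X, y)
    want <- brute_force_split(X, y, ANGLE_NAMES)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("tie-breaks use feature order then smallest threshold", {
  # identical separation available on alpha and zeta: alpha must win
  X <- data.frame(alpha = c(10, 20, 200, 210), beta = 1, gamma = 1, delta = 1,
                  epsilon = 1, zeta = c(10, 20, 200, 210), chi = 1)
  sp <- best_split(X, c(0L, 0L, 1L, 1L))
  expect_equal(sp$feature, "alpha")
  # two equal-gain thresholds on one feature: smaller one wins
  X2 <- data.frame(alpha = c(0, 100, 200, 300))
  y2 <- c(0L, 1L, 0L, 1L)
  sp2 <- best_split(X2, y2, features = "alpha")
  expect_equal(sp2$threshold, 50)
})

test_that("grow_tree handles pure, separable and conflict-free data", {
  pure <- toy_dataset(alpha0 = c(10, 20, 30), alpha1 = numeric(0))
  t1 <- grow_tree(pure)
  expect_equal(n_leaves(t1), 1L)
  expect_equal(predict(t1, pure), rep(0L, 3))

  sep <- toy_dataset(alpha0 = c(170, 175), alpha1 = c(300, 310))
  t2 <- grow_tree(sep)
  expect_equal(n_leaves(t2), 2L)
  expect_equal(tree_depth(t2), 1L)
  expect_equal(t2$threshold, 237.5)
  expect_equal(train_correct(t2, sep), 4L)

  set.seed(5)
  for (i in 1:10) {
    ds <- g4_synthetic(seed = 100 + i, n = c(LHG4 = 40, RHG4 = 40))
    expect_false(any(duplicated(as.data.frame(ds)[, ANGLE_NAMES])))
    tr <- grow_tree(ds)
    expect_equal(train_correct(tr, ds), nrow(ds))  # purity without conflicts
  }
})

test_that("grow_tree matches the brute-force optimal tree of equal depth", {
  set.seed(31)
  checked <- 0
  for (i in 1:30) {
    n <- sample(6:12, 1)
    X <- data.frame(alpha = sample(seq(0, 330, by = 110), n, replace = TRUE) +
                      sample(0:2, n, replace = TRUE),
                    beta = sample(seq(10, 340, by = 110), n, replace = TRUE))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    ds <- data.frame(X, label = y)
    tr <- grow_tree(ds, features = c("alpha", "beta"))
    d <- tree_depth(tr)
    if (d > 3) next
    got <- sum(predict(tr, ds) == y)
    want <- brute_force_tree_correct(X, y, depth = d,
                                     features = c("alpha", "beta"))
    expect_gte(got, want - 0L)
    expect_equal(got, want, label = sprintf("case %d depth %d", i, d))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("information gain is nonnegative at every executed split", {
  ds <- g4_synthetic(seed = 8, n = c(LHG4 = 60, RHG4 = 60))
  walk <- function(node) {
    if (is.null(node$feature)) return(invisible())
    parent <- entropy(node$counts)
    child <- (sum(node$left$counts) * entropy(node$left$counts) +
                sum(node$right$counts) * entropy(node$right$counts)) /
      sum(node$counts)
    expect_gte(parent - child, 0)
    walk(node$left); walk(node$right)
  }
  walk(grow_tree(ds))
})

test_that("pruning limits, idempotence and size reduction behave", {
  ds <- g4_synthetic(seed = 13, n = c(LHG4 = 80, RHG4 = 80))
  full <- grow_tree(ds)
  expect_identical(prune_tree(full, 0), full)                # 0 -> unchanged
  collapsed <- prune_tree(full, Inf)
  expect_equal(n_leaves(collapsed), 1L)                      # Inf -> one leaf
  expect_equal(collapsed$counts, full$counts)
  p <- prune_tree(full, 0.04)
  expect_identical(prune_tree(p, 0.04), p)                   # idempotent
  expect_lte(n_leaves(p), n_leaves(full))
  set.seed(2)
  for (a in c(0.01, 0.1, 0.5)) {
    pa <- prune_tree(full, a)
    expect_identical(prune_tree(pa, a), pa)
  }
})

test_that("pruned trees agree with an rpart entropy-criterion reference", {
  skip_if_not_installed("rpart")
  set.seed(77)
  diffs <- numeric(0)
  for (i in 1:50) {
    ds <- g4_synthetic(seed = 500 + i, n = c(LHG4 = 70, RHG4 = 50))
    sp <- holdout_split(ds, seed = 900 + i)
    tree <- prune_tree(grow_tree(sp$train), 0.04)
    ours <- mean(predict(tree, sp$test) == sp$test$label)
    train_df <- as.data.frame(sp$train)
    train_df$label <- factor(train_df$label, levels = c(0, 1))
    r_root <- min(table(train_df$label)) / nrow(train_df)
    fit <- rpart::rpart(
      label ~ alpha + beta + gamma + delta + epsilon + zeta + chi,
      data = train_df, method = "class",
      parms = list(split = "information"),
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0.04 / r_root,
                                     maxdepth = 30, xval = 0)
    )
    ref <- mean(predict(fit, as.data.frame(sp$test), type = "class") ==
                  sp$test$label)
    diffs <- c(diffs, abs(ours - ref))
  }
  expect_lt(max(diffs), 0.03 + 1e-9)
})

test_that("prediction routes with <= and resolves leaf ties to LH", {
  leafy <- structure(list(counts = c(5L, 1L), feature = NULL, threshold = NULL,
                          left = NULL, right = NULL),
                     class = "id3_tree", features = ANGLE_NAMES)
  ds <- toy_dataset(alpha0 = 100, alpha1 = 200)
  expect_equal(predict(leafy, ds), c(0L, 0L))

  tie <- leafy; tie$counts <- c(3L, 3L)
  expect_equal(predict(tie, ds), c(0L, 0L))

  sep <- toy_dataset(alpha0 = c(170, 175), alpha1 = c(300, 310))
  tr <- grow_tree(sep)
  near <- as.data.frame(sep)[c(1, 1), ]
  near$alpha <- tr$threshold + c(-1e-9, 0)    # on and just under the boundary
  expect_equal(predict(tr, near), c(0L, 0L))
  near$alpha <- tr$threshold + 1e-9           # just over: strictly right
  expect_equal(predict(tr, near[1, ]), 1L)

  expect_error(predict(tr, data.frame(beta = 100)), "missing feature")
})

test_that("a hand-built alpha threshold tree classifies by the 252 rule", {
  tr <- tree_from_json('{"feature":"alpha","threshold":252,
    "counts":[125,88],
    "left":{"counts":[120,5]},"right":{"counts":[5,83]}}')
  expect_equal(predict(tr, toy_dataset(alpha0 = 180, alpha1 = numeric(0))), 0L)
  expect_equal(predict(tr, toy_dataset(alpha0 = numeric(0), alpha1 = 300)), 1L)
})

test_that("the alpha/beta rule reproduces its documented cases", {
  expect_equal(rule_classifier(data.frame(alpha = 180, beta = 200)), 0L)
  expect_equal(rule_classifier(data.frame(alpha = 300, beta = 200)), 1L)
  expect_equal(rule_classifier(data.frame(alpha = 180, beta = 100)), 1L)
  expect_equal(rule_classifier(data.frame(alpha = c(251.9, 252), beta = c(151, 151))),
               c(0L, 1L))
  expect_error(rule_classifier(data.frame(alpha = 180)), "alpha and beta")
  expect_error(rule_classifier(data.frame(alpha = NA, beta = 100)), "alpha and beta")
})

test_that("tree serialization is a lossless fixed point", {
  ds <- g4_synthetic(seed = 55, n = c(LHG4 = 40, RHG4 = 40))
  tr <- prune_tree(grow_tree(ds), 0.04)
  json <- describe(tr)
  back <- tree_from_json(json)
  expect_equal(describe(back), json)
  expect_equal(predict(back, ds), predict(tr, ds))

  leaf <- grow_tree(toy_dataset(alpha0 = c(1, 2), alpha1 = numeric(0)))
  expect_match(describe(leaf), '"counts"')
  expect_equal(tree_from_json(describe(leaf))$counts, c(2L, 0L))

  two <- grow_tree(data.frame(alpha = c(10, 100, 200, 300),
                              beta = c(5, 250, 5, 5),
                              label = c(0L, 0L, 1L, 1L)),
                   features = c("alpha", "beta"))
  json2 <- describe(two)
  expect_equal(describe(tree_from_json(json2, features = c("alpha", "beta"))),
               json2)
})
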