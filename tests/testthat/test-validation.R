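test_that("record filtering retains the designed survivors with the designed tally", {
  fx <- build_filter_fixture()
  out <- filter_records(fx$records, fx$ranges, fx$grid)
  expect_setequal(out$records$record_id, fx$expected_survivors)
  expect_identical(out$tally, fx$expected_tally)
  # species without a supplied range are retained but flagged unchecked
  expect_false(out$records$range_checked[out$records$record_id == "keepNoRange"])
  expect_true(all(out$records$range_checked[out$records$species_id == "spA"]))
  # with no ranges at all, the range rule rejects nothing
  out2 <- filter_records(fx$records, NULL, fx$grid)
  expect_identical(unname(out2$tally["range"]), 0L)
})

striped_map <- function() {
  # columns 1-5 code 106, columns 6-10 code 403-like (404)
  m <- matrix(rep(c(106L, 404L), each = 5)[col(matrix(0, 10, 10))], 10, 10)
  categorical_layer(grid_spec(10, 10, 100), m, "iucn_habitat")
}

test_that("point matching honours lenient and strict modes", {
  map <- striped_map()
  ctr <- cell_center(map$grid, 5, 5)   # on the 106 side, near the boundary
  # buffer within one class -> predicted = expected in both modes
  m0 <- match_point(map, ctr$x, ctr$y, 106L, buffer_m = 0, mode = "strict")
  expect_identical(m0$predicted, 106L)
  # lenient: expected present anywhere in the buffer wins
  ml <- match_point(map, ctr$x, ctr$y, 404L, buffer_m = 300, mode = "lenient")
  expect_identical(ml$predicted, 404L)
  # strict: modal code of the buffer regardless of expectation
  edge <- cell_center(map$grid, 5, 6)  # first 404 column; buffer mostly 404
  ms <- match_point(map, edge$x, edge$y, 106L, buffer_m = 200, mode = "strict")
  expect_identical(ms$predicted, 404L)  # 404 is modal within the buffer
  # lenient never scores worse than strict on the same records
  set.seed(51)
  hits_l <- hits_s <- 0
  for (k in 1:50) {
    r <- sample(10, 1); c0 <- sample(10, 1)
    p <- cell_center(map$grid, r, c0)
    exp_code <- sample(c(106L, 404L), 1)
    hits_l <- hits_l + (match_point(map, p$x, p$y, exp_code, 300, "lenient")$predicted == exp_code)
    hits_s <- hits_s + (match_point(map, p$x, p$y, exp_code, 300, "strict")$predicted == exp_code)
  }
  expect_gte(hits_l, hits_s)
  # empty buffer -> dropped
  na_map <- categorical_layer(map$grid, matrix(NA_integer_, 10, 10), "iucn_habitat")
  expect_true(match_point(na_map, ctr$x, ctr$y, 106L, 300)$dropped)
  off <- match_point(map, -500, -500, 106L, 300)
  expect_true(off$dropped)
})

test_that("polygon matching tests presence of the expected habitat at cell centers", {
  map <- striped_map()
  square <- function(x1, x2, y1, y2)
    cbind(x = c(x1, x2, x2, x1, x1), y = c(y1, y1, y2, y2, y1))
  # polygon over a uniform 106 patch
  expect_true(match_polygon(map, square(50, 350, 550, 950), 106L))
  expect_false(match_polygon(map, square(50, 350, 550, 950), 404L))
  # polygon straddling the class boundary with one 404 cell center inside
  strad <- square(420, 560, 420, 580)   # covers centers at x = 450, 550
  expect_true(match_polygon(map, strad, 404L))
  expect_true(match_polygon(map, strad, 106L))
  expect_error(match_polygon(map, square(5000, 6000, 5000, 6000), 106L),
               "outside")
})

test_that("confusion drops classes under the record threshold and counts pairs", {
  pairs <- data.frame(
    expected = c(rep(1401L, 10), rep(1402L, 10), rep(1403L, 9)),
    predicted = c(rep(1401L, 8), 1402L, 1402L,
                  rep(1402L, 7), rep(1401L, 3), rep(1403L, 9)))
  cm <- confusion(pairs, min_records = 10)
  expect_identical(rownames(cm), c("1401", "1402"))   # 1403 had only 9
  expect_identical(unclass(cm)[cbind(c("1401", "1401", "1402", "1402"),
                                     c("1401", "1402", "1401", "1402"))],
                   c(8L, 2L, 3L, 7L))
  expect_error(confusion(pairs[1:5, ], min_records = 10), "at least 10")
  one <- confusion(data.frame(expected = rep(106L, 12),
                              predicted = rep(106L, 12)), 10)
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(unclass(one)[1, 1], 12L)
})

test_that("metrics reproduce the hand-computed fixtures", {
  cm <- matrix(c(8L, 3L, 2L, 7L), 2, 2,
               dimnames = list(expected = c(101, 104), predicted = c(101, 104)))
  m <- metrics(cm)
  expect_equal(m$overall_accuracy, 0.75)
  expect_equal(m$class_metrics$sensitivity[1], 0.8)
  expect_equal(m$class_metrics$specificity[1], 0.7)
  expect_equal(m$class_metrics$balanced_accuracy[1], 0.75)
  # degenerate column: specificity 0, balanced accuracy 0.5
  cm2 <- matrix(c(10L, 10L, 0L, 0L), 2, 2,
                dimnames = list(expected = c(101, 104), predicted = c(101, 104)))
  m2 <- metrics(cm2)
  expect_equal(m2$class_metrics$sensitivity[1], 1.0)
  expect_equal(m2$class_metrics$specificity[1], 0.0)
  expect_equal(m2$class_metrics$balanced_accuracy[1], 0.5)
  # perfect diagonal
  m3 <- metrics(diag(c(5L, 9L, 4L)))
  expect_equal(m3$overall_accuracy, 1.0)
  expect_true(all(m3$class_metrics$balanced_accuracy == 1.0))
  expect_error(metrics(matrix(0L, 2, 2)), "no observations")
})

test_that("metrics agree with an independent formula implementation on random matrices", {
  set.seed(52)
  for (k in 1:40) {
    d <- sample(2:5, 1)
    cm <- matrix(rpois(d * d, 4), d, d)
    if (sum(cm) == 0) cm[1, 1] <- 1
    dimnames(cm) <- list(expected = seq_len(d) * 100,
                         predicted = seq_len(d) * 100)
    m <- metrics(cm)
    o <- oracle_metrics(cm)
    expect_equal(m$overall_accuracy, o$overall)
    expect_equal(m$class_metrics$sensitivity, o$sensitivity)
    expect_equal(m$class_metrics$specificity, o$specificity)
    expect_equal(m$class_metrics$balanced_accuracy, o$balanced)
  }
})

test_that("metrics agree with caret's one-vs-rest confusionMatrix statistics", {
  skip_if_not_installed("caret")
  cm <- matrix(c(12L, 4L, 1L, 2L, 9L, 3L, 0L, 5L, 11L), 3, 3,
               dimnames = list(expected = c(100, 400, 800),
                               predicted = c(100, 400, 800)))
  m <- metrics(cm)
  # caret expects prediction in rows; transpose ours
  cc <- caret::confusionMatrix(as.table(t(unclass(cm))))
  expect_equal(m$overall_accuracy, unname(cc$overall["Accuracy"]))
  expect_equal(m$class_metrics$sensitivity,
               unname(cc$byClass[, "Sensitivity"]))
  expect_equal(m$class_metrics$specificity,
               unname(cc$byClass[, "Specificity"]))
  expect_equal(m$class_metrics$balanced_accuracy,
               unname(cc$byClass[, "Balanced Accuracy"]))
})

test_that("cross-dataset summaries pool balanced accuracies with sample SD", {
  pairs_a <- data.frame(expected = c(rep(106L, 10), rep(404L, 10)),
                        predicted = c(rep(106L, 8), 404L, 404L,
                                      rep(404L, 8), 106L, 106L))
  s1 <- summarize_validation(list(a = pairs_a), level = 2, min_records = 10)
  expect_equal(nrow(s1$table), 2L)
  expect_true(is.na(s1$sd_balanced_accuracy) || nrow(s1$table) > 1)
  # pooled mean/SD equal the hand formula over the per-class entries
  fake <- list(
    a = data.frame(expected = rep(c(106L, 404L), c(10, 40)),
                   predicted = c(rep(106L, 6), rep(404L, 4), rep(404L, 40))))
  s2 <- summarize_validation(fake, level = 2, min_records = 10)
  ba <- s2$table$balanced_accuracy
  expect_equal(s2$mean_balanced_accuracy, mean(ba))
  expect_equal(s2$sd_balanced_accuracy, sd(ba))
  # Level-1 projection of a perfect Level-2 matcher is perfect
  perfect <- list(p = data.frame(expected = rep(c(106L, 109L), each = 10),
                                 predicted = rep(c(106L, 109L), each = 10)))
  s3 <- summarize_validation(perfect, level = 1, min_records = 10)
  expect_equal(s3$overall_accuracy, 1.0)
})

test_that("Level-1 overall accuracy is never below Level-2 on the same pairs", {
  set.seed(53)
  codes <- c(106L, 109L, 104L, 404L, 400L, 1401L, 1405L)
  for (k in 1:10) {
    n <- 400
    pairs <- data.frame(expected = sample(codes, n, TRUE),
                        predicted = sample(codes, n, TRUE))
    s2 <- summarize_validation(list(x = pairs), level = 2, min_records = 10)
    s1 <- summarize_validation(list(x = pairs), level = 1, min_records = 10)
    expect_gte(s1$overall_accuracy, s2$overall_accuracy)
  }
})
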