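# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorised code paths: window counting, distance
# enumeration, per-cell rule loops and textbook metric formulas, written the
# slow and obvious way.

oracle_modal <- function(codes, r) {
  nr <- nrow(codes); nc <- ncol(codes)
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    win <- codes[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)]
    win <- win[!is.na(win)]
    if (length(win) == 0) next
    vals <- sort(unique(win))
    cnt <- vapply(vals, function(v) sum(win == v), integer(1))
    out[i, j] <- vals[which.max(cnt)]   # first max = smallest code on ties
  }
  out
}

oracle_dilate <- function(flags, radius_m, cell_size) {
  nr <- nrow(flags); nc <- ncol(flags)
  set <- which(flags, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (nrow(set) == 0) return(out)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (set[, 1] - i)^2 + (set[, 2] - j)^2
    out[i, j] <- any(d2 * cell_size^2 <= radius_m^2 + 1e-6)
  }
  out
}

oracle_eval_cell <- function(pred, stack, r, c) {
  switch(pred$atom,
         all = all(vapply(pred$of, oracle_eval_cell, logical(1),
                          stack = stack, r = r, c = c)),
         any = any(vapply(pred$of, oracle_eval_cell, logical(1),
                          stack = stack, r = r, c = c)),
         not = !oracle_eval_cell(pred$of[[1]], stack, r, c),
         code_in = {
           v <- stack[[pred$layer]]$data[r, c]
           !is.na(v) && v %in% pred$codes
         },
         threshold = {
           v <- stack[[pred$layer]]$data[r, c]
           !is.na(v) && do.call(pred$op, list(v, pred$value))
         },
         mask = isTRUE(stack[[pred$layer]]$data[r, c]),
         stop("bad atom"))
}

oracle_classify <- function(stack, rs) {
  g <- stack[[1]]$grid
  out <- matrix(NA_integer_, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    for (rule in rs$rules) {
      if (oracle_eval_cell(rule$when, stack, i, j)) {
        out[i, j] <- rule$target
        break
      }
    }
  }
  out
}

oracle_metrics <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  sens <- spec <- bal <- rep(NA_real_, k)
  for (c0 in seq_len(k)) {
    tp <- cm[c0, c0]
    fn <- sum(cm[c0, ]) - tp
    fp <- sum(cm[, c0]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn > 0) sens[c0] <- tp / (tp + fn)
    if (tn + fp > 0) spec[c0] <- tn / (tn + fp)
    if (!is.na(sens[c0]) && !is.na(spec[c0])) bal[c0] <- (sens[c0] + spec[c0]) / 2
  }
  list(overall = sum(diag(cm)) / n, sensitivity = sens, specificity = spec,
       balanced = bal)
}

# ---- random inputs for property tests ----------------------------------

random_categorical <- function(nr = 40, nc = 40, codes = 1:6, na_frac = 0.1) {
  g <- grid_spec(nr, nc, cell_size = 100)
  vals <- sample(codes, nr * nc, replace = TRUE)
  vals[runif(nr * nc) < na_frac] <- NA_integer_
  categorical_layer(g, matrix(vals, nr, nc), "synthetic")
}

random_test_stack <- function(nr, nc) {
  g <- grid_spec(nr, nc, cell_size = 100)
  n <- nr * nc
  cat1 <- sample(c(NA_integer_, 1:5), n, replace = TRUE)
  val1 <- round(runif(n, 0, 10), 2)
  val1[runif(n) < 0.1] <- NA_real_
  m1 <- runif(n) < 0.4
  layer_stack(cat1 = categorical_layer(g, matrix(cat1, nr, nc), "synthetic"),
              val1 = continuous_layer(g, matrix(val1, nr, nc)),
              m1 = binary_mask(g, matrix(m1, nr, nc)))
}

random_predicate <- function(depth = 2) {
  if (depth > 0 && runif(1) < 0.5) {
    kids <- replicate(sample(1:3, 1), random_predicate(depth - 1),
                      simplify = FALSE)
    switch(sample(3, 1),
           do.call(p_all, kids), do.call(p_any, kids),
           p_not(kids[[1]]))
  } else {
    switch(sample(3, 1),
           p_code_in("cat1", sample(1:5, sample(1:3, 1))),
           p_threshold("val1", sample(c("<", "<=", ">", ">="), 1),
                       round(runif(1, 0, 10), 1)),
           p_mask("m1"))
  }
}

random_ruleset <- function(n_rules = 4) {
  leg <- habitat_legend()
  pool <- leg$code[leg$minor != 0]
  targets <- sample(pool, n_rules)
  n_art <- sample(0:n_rules, 1)
  rules <- lapply(seq_len(n_rules), function(i)
    rule(targets[i], random_predicate(),
         group = if (i <= n_art) "artificial" else "natural"))
  ruleset(rules, name = "random")
}

# ---- record-filter fixture ---------------------------------------------
# 24 records on a 20x20 grid (100 m cells) with designed per-rule outcomes:
# 3 range rejections, 2 date, 3 uncertainty, 2 cell duplicates, 14 survivors.
build_filter_fixture <- function() {
  grid <- grid_spec(20, 20, cell_size = 100)
  # spA range: x in [0, 1000], y in [1000, 2000] (the upper-left 10x10 cells)
  range_a <- cbind(x = c(0, 1000, 1000, 0, 0), y = c(1000, 1000, 2000, 2000, 1000))
  cellxy <- function(row, col) cell_center(grid, row, col)
  mk <- function(id, row, col, date, unc, source, sp = "spA", x = NULL, y = NULL) {
    ctr <- cellxy(row, col)
    data.frame(record_id = id, species_id = sp,
               x = if (is.null(x)) ctr$x else x,
               y = if (is.null(y)) ctr$y else y,
               observed_date = date, coord_uncertainty_m = unc,
               source = source, expected_code = 106,
               sampling_extent_m = NA_real_)
  }
  rows <- list()
  keep_rc <- rbind(cbind(1:10, 1:10), c(1, 2), c(1, 3))
  for (i in 1:12)  # 12 clean GBIF records, distinct cells, in range
    rows[[i]] <- mk(sprintf("keep%02d", i), keep_rc[i, 1], keep_rc[i, 2],
                    "2010-06-01", 100, "gbif")
  rows[[13]] <- mk("range1", 3, 15, "2010-06-01", 100, "gbif")  # x = 1450: out of range
  rows[[14]] <- mk("range2", 15, 3, "2010-06-01", 100, "gbif")  # y = 550: out of range
  rows[[15]] <- mk("date1", 4, 4, "2003-05-01", 100, "gbif")
  rows[[16]] <- mk("date2", 5, 5, "2021-05-01", 100, "gbif")
  rows[[17]] <- mk("unc1", 6, 6, "2010-06-01", 400, "gbif")
  rows[[18]] <- mk("unc2", 7, 7, "2010-06-01", NA_real_, "gbif")
  rows[[19]] <- mk("unc3", 8, 8, "2010-06-01", 50, "ebird")
  rows[[20]] <- mk("keepEbird", 9, 2, "2010-06-01", 20, "ebird")
  rows[[21]] <- mk("dup1", 2, 2, "2011-06-01", 100, "gbif")   # same cell as keep02
  rows[[22]] <- mk("dup2", 2, 2, "2012-06-01", 100, "gbif")   # same cell again
  rows[[23]] <- mk("keepNoRange", 12, 12, "2010-06-01", 100, "gbif", sp = "spB")
  rows[[24]] <- mk("rangeAndDate", 15, 15, "2001-01-01", 100, "gbif") # out of range first
  d <- do.call(rbind, rows)
  recs <- occurrence_records(d$record_id, d$species_id, d$x, d$y,
                             d$observed_date, d$coord_uncertainty_m,
                             d$source, d$expected_code, d$sampling_extent_m)
  list(records = recs, ranges = list(spA = range_a), grid = grid,
       expected_survivors = c(sprintf("keep%02d", 1:12), "keepEbird",
                              "keepNoRange"),
       expected_tally = c(range = 3L, date = 2L, uncertainty = 3L,
                          duplicate = 2L))
}

roundtrip_exact <- function(world, map = classify(world$stack)) {
  identical(is.na(map$data), is.na(world$truth$data)) &&
    all(map$data[!is.na(world$truth$data)] ==
          world$truth$data[!is.na(world$truth$data)])
}
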