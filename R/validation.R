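#' Occurrence records for map validation
#'
#' Builds/validates the record table used by the validation stage. Each
#' record is an observation of a habitat-specialist species (a species coded
#' to occur in exactly one Level-2 class, whose code is the record's
#' `expected_code`).
#'
#' @param record_id unique identifiers.
#' @param species_id species identifiers.
#' @param x,y map coordinates.
#' @param observed_date observation dates (`Date` or parseable strings).
#' @param coord_uncertainty_m coordinate uncertainty in metres (`NA` if
#'   unknown).
#' @param source one of `"gbif"`, `"ebird"`, `"predicts"`, `"visual"`.
#' @param expected_code registered Level-2 habitat code.
#' @param sampling_extent_m sampling extent in metres (PREDICTS sites only;
#'   used as that record's match buffer).
#' @return A data frame of class `occurrence_records`.
#' @export
occurrence_records <- function(record_id, species_id, x, y, observed_date,
                               coord_uncertainty_m = NA_real_,
                               source, expected_code,
                               sampling_extent_m = NA_real_) {
  d <- data.frame(record_id = record_id, species_id = species_id,
                  x = as.numeric(x), y = as.numeric(y),
                  observed_date = as.Date(observed_date),
                  coord_uncertainty_m = as.numeric(coord_uncertainty_m),
                  source = source, expected_code = as.integer(expected_code),
                  sampling_extent_m = as.numeric(sampling_extent_m))
  bad_src <- !d$source %in% c("gbif", "ebird", "predicts", "visual")
  if (any(bad_src))
    stop("unknown record source(s): ", paste(unique(d$source[bad_src]),
                                             collapse = ", "))
  if (anyDuplicated(d$record_id)) stop("duplicate record_id values")
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("record coordinates must be finite")
  level1_of(d$expected_code)  # errors on unregistered codes
  class(d) <- c("occurrence_records", "data.frame")
  d
}

#' Validation filtering parameters
#'
#' Defaults follow the study design: records from 2005-2019; coordinate
#' uncertainty below 300 m (GBIF) or 30 m (eBird), records with missing
#' uncertainty rejected where a finite limit applies; a conservative 300 m
#' match buffer for positional error; and at least 10 independent records
#' per class for it to enter the confusion matrix.
#'
#' @param date_min,date_max retained observation window.
#' @param max_uncertainty_m named per-source uncertainty limits in metres
#'   (`Inf` disables the check for a source).
#' @param point_buffer_m match buffer radius for point records.
#' @param min_records_per_class minimum expected records per class.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(date_min = as.Date("2005-01-01"),
                          date_max = as.Date("2019-12-31"),
                          max_uncertainty_m = c(gbif = 300, ebird = 30,
                                                predicts = Inf, visual = Inf),
                          point_buffer_m = 300,
                          min_records_per_class = 10) {
  date_min <- as.Date(date_min); date_max <- as.Date(date_max)
  stopifnot(date_min <= date_max, all(max_uncertainty_m > 0),
            point_buffer_m >= 0, min_records_per_class >= 1)
  structure(list(date_min = date_min, date_max = date_max,
                 max_uncertainty_m = max_uncertainty_m,
                 point_buffer_m = point_buffer_m,
                 min_records_per_class = min_records_per_class),
            class = "filter_params")
}

# Ray-casting point-in-polygon (planar coordinates). `poly` is a two-column
# matrix of vertices (closed or open ring).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Filter occurrence records for validation
#'
#' Applies the retention rules in order: (a) inside the species' range
#' polygon (species without a supplied range are retained and flagged),
#' (b) observation date within the window, (c) coordinate uncertainty within
#' the per-source limit (missing uncertainty under a finite limit rejects),
#' (d) unique per (species, map cell). The returned tally counts rejections
#' per rule in that order — a record failing several rules is counted at the
#' first.
#'
#' @param records an [occurrence_records()] table.
#' @param ranges named list (by `species_id`) of two-column vertex matrices;
#'   `NULL` skips the range rule entirely.
#' @param grid the map `grid_spec` (defines the deduplication cell).
#' @param params a [filter_params()].
#' @return List with `records` (the survivors, with a logical
#'   `range_checked` column), and `tally` (named integer vector:
#'   `range`, `date`, `uncertainty`, `duplicate`).
#' @export
filter_records <- function(records, ranges = NULL, grid,
                           params = filter_params()) {
  stopifnot(inherits(records, "data.frame"), inherits(grid, "grid_spec"))
  n <- nrow(records)
  alive <- rep(TRUE, n)
  tally <- c(range = 0L, date = 0L, uncertainty = 0L, duplicate = 0L)
  records$range_checked <- FALSE

  if (!is.null(ranges)) {
    for (sp in unique(records$species_id)) {
      idx <- which(records$species_id == sp)
      if (!sp %in% names(ranges)) next       # no range: retained, flagged FALSE
      records$range_checked[idx] <- TRUE
      ok <- point_in_polygon(records$x[idx], records$y[idx], ranges[[sp]])
      alive[idx][!ok] <- FALSE
      tally["range"] <- tally["range"] + sum(!ok)
    }
  }

  d <- records$observed_date
  bad <- alive & (is.na(d) | d < params$date_min | d > params$date_max)
  tally["date"] <- sum(bad)
  alive[bad] <- FALSE

  lim <- params$max_uncertainty_m[records$source]
  lim[is.na(lim)] <- Inf
  u <- records$coord_uncertainty_m
  bad <- alive & is.finite(lim) & (is.na(u) | u > lim)
  tally["uncertainty"] <- sum(bad)
  alive[bad] <- FALSE

  cells <- cell_of(grid, records$x, records$y)
  key <- paste(records$species_id, cells$row, cells$col, sep = "|")
  key[is.na(cells$row)] <- paste0("offgrid|", seq_len(n)[is.na(cells$row)])
  key[!alive] <- paste0("dead|", which(!alive))   # dead records never collide
  dup <- alive & duplicated(key)
  tally["duplicate"] <- sum(dup)
  alive[dup] <- FALSE

  list(records = records[alive, , drop = FALSE], tally = tally)
}

modal_code <- function(codes) {
  vals <- sort(unique(codes))
  counts <- vapply(vals, function(v) sum(codes == v), integer(1))
  vals[which.max(counts)]  # which.max takes the first (= smallest) on ties
}

#' Match one buffered point record against the habitat map
#'
#' Collects the multiset S of non-nodata codes whose cell centers lie within
#' `buffer_m` of the record's cell center. Modes:
#' * `"lenient"` (default): predicted = `expected_code` when it occurs
#'   anywhere in S (presence-in-buffer, mirroring the polygon presence
#'   logic), else the modal code of S;
#' * `"strict"`: predicted = modal code of S regardless.
#' Ties break to the smallest code. An empty S (or a record whose cell is
#' off-grid) yields `dropped = TRUE`.
#'
#' @param map a `categorical_layer` habitat map.
#' @param x,y record coordinates.
#' @param expected_code the specialist's habitat code.
#' @param buffer_m buffer radius; below the cell size only the record's own
#'   cell is consulted.
#' @param mode `"lenient"` or `"strict"`.
#' @return List `(expected, predicted, dropped)`.
#' @export
match_point <- function(map, x, y, expected_code, buffer_m = 300,
                        mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  ctr <- cell_of(map$grid, x, y)
  if (is.na(ctr$row))
    return(list(expected = expected_code, predicted = NA_integer_,
                dropped = TRUE))
  cells <- disk_cells(map$grid, ctr$row, ctr$col, buffer_m)
  s <- map$data[cells]
  s <- s[!is.na(s)]
  if (length(s) == 0)
    return(list(expected = expected_code, predicted = NA_integer_,
                dropped = TRUE))
  predicted <- if (mode == "lenient" && expected_code %in% s) expected_code
               else modal_code(s)
  list(expected = as.integer(expected_code), predicted = as.integer(predicted),
       dropped = FALSE)
}

#' Match a whole record table against the map
#'
#' Applies [match_point()] to each record with the per-source buffer policy:
#' GBIF/eBird points use `params$point_buffer_m`, PREDICTS sites use their
#' own `sampling_extent_m`, and visually labelled points use a plain cell
#' lookup (buffer 0).
#'
#' @param map habitat map.
#' @param records filtered [occurrence_records()].
#' @param params a [filter_params()].
#' @param mode match mode, see [match_point()].
#' @return List with `pairs` (data frame `expected`, `predicted` for
#'   non-dropped records) and `n_dropped`.
#' @export
match_records <- function(map, records, params = filter_params(),
                          mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  n <- nrow(records)
  expected <- integer(n); predicted <- integer(n); dropped <- logical(n)
  for (i in seq_len(n)) {
    buf <- switch(records$source[i],
                  predicts = records$sampling_extent_m[i],
                  visual = 0,
                  params$point_buffer_m)
    if (is.na(buf)) buf <- params$point_buffer_m
    m <- match_point(map, records$x[i], records$y[i],
                     records$expected_code[i], buffer_m = buf, mode = mode)
    expected[i] <- m$expected; predicted[i] <- m$predicted
    dropped[i] <- m$dropped
  }
  list(pairs = data.frame(expected = expected[!dropped],
                          predicted = predicted[!dropped]),
       n_dropped = sum(dropped))
}

#' Test a validation polygon for habitat presence
#'
#' `TRUE` iff at least one map cell whose center lies inside the polygon
#' carries `expected_code` (the site-checklist presence test used for IBA
#' polygons).
#'
#' @param map habitat map.
#' @param geometry two-column vertex matrix in map coordinates.
#' @param expected_code habitat code to look for.
#' @return Logical scalar.
#' @export
match_polygon <- function(map, geometry, expected_code) {
  g <- map$grid
  xr <- range(geometry[, 1]); yr <- range(geometry[, 2])
  cmin <- max(1, floor((xr[1] - g$origin_x) / g$cell_size) + 1)
  cmax <- min(g$n_cols, floor((xr[2] - g$origin_x) / g$cell_size) + 1)
  rmin <- max(1, floor((g$origin_y - yr[2]) / g$cell_size) + 1)
  rmax <- min(g$n_rows, floor((g$origin_y - yr[1]) / g$cell_size) + 1)
  if (cmin > cmax || rmin > rmax)
    stop("validation polygon lies entirely outside the map grid")
  for (r in rmin:rmax) {
    cc <- cmin:cmax
    vals <- map$data[r, cc]
    cand <- cc[!is.na(vals) & vals == expected_code]
    if (length(cand) == 0) next
    ctr <- cell_center(g, rep(r, length(cand)), cand)
    if (any(point_in_polygon(ctr$x, ctr$y, geometry))) return(TRUE)
  }
  # polygon overlaps the grid but holds no expected-code cell center
  FALSE
}

#' Confusion matrix from expected/predicted pairs
#'
#' Classes with fewer than `min_records` *expected* records are dropped and
#' their pairs excluded entirely; the matrix then spans the union of the
#' remaining expected and predicted codes (rows = expected, columns =
#' predicted).
#'
#' @param pairs data frame with integer columns `expected`, `predicted`.
#' @param min_records minimum expected records per retained class.
#' @return Integer matrix of class `confusion_matrix` with code dimnames.
#' @export
confusion <- function(pairs, min_records = 10) {
  stopifnot(all(c("expected", "predicted") %in% names(pairs)))
  pairs <- pairs[!is.na(pairs$predicted), , drop = FALSE]
  tab <- table(pairs$expected)
  keep <- as.integer(names(tab)[tab >= min_records])
  pairs <- pairs[pairs$expected %in% keep, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("no habitat class has at least ", min_records, " validation records")
  classes <- sort(unique(c(pairs$expected, pairs$predicted)))
  m <- table(factor(pairs$expected, levels = classes),
             factor(pairs$predicted, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(expected = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy is trace/total. Per class (one-vs-rest):
#' sensitivity = TP / (row total), specificity = TN / (total - row total),
#' balanced accuracy = their mean; a metric whose denominator is zero is
#' `NA` and excluded from the macro average. The macro balanced accuracy is
#' the unweighted mean over classes, robust to imbalanced record counts.
#'
#' @param cm a square integer matrix (rows = expected, columns = predicted),
#'   e.g. from [confusion()].
#' @return List with `overall_accuracy`, `class_metrics` (data frame:
#'   `code`, `n_records`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`), and `macro_balanced_accuracy`.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix has no observations")
  codes <- if (!is.null(rownames(cm))) as.integer(rownames(cm))
           else seq_len(nrow(cm))
  rows <- rowSums(cm); cols <- colSums(cm); diagv <- diag(cm)
  sens <- ifelse(rows > 0, diagv / rows, NA_real_)
  spec_den <- total - rows
  spec <- ifelse(spec_den > 0, (total - rows - cols + diagv) / spec_den,
                 NA_real_)
  bal <- ifelse(!is.na(sens) & !is.na(spec), (sens + spec) / 2, NA_real_)
  list(overall_accuracy = sum(diagv) / total,
       class_metrics = data.frame(code = codes, n_records = as.integer(rows),
                                  sensitivity = sens, specificity = spec,
                                  balanced_accuracy = bal, row.names = NULL),
       macro_balanced_accuracy = mean(bal, na.rm = TRUE))
}

#' Cross-dataset validation summary
#'
#' Builds per-dataset confusion matrices and class metrics at Level 1 or
#' Level 2 and pools the per-(class, dataset) balanced accuracies into a
#' mean and sample standard deviation (n - 1 denominator; a single entry has
#' an undefined SD, reported as `NA`). Level-1 summaries project both
#' expected and predicted codes with [level1_of()] before counting, so
#' within-group confusions merge and never create new errors.
#'
#' @param pair_sets named list of pair data frames (`expected`,
#'   `predicted`), one per validation dataset.
#' @param level 1 or 2.
#' @param min_records minimum expected records per retained class, applied
#'   per (class, dataset).
#' @return List with `table` (data frame: `dataset`, `code`, `n_records`,
#'   `balanced_accuracy`), `overall_accuracy` (pooled over all retained
#'   pairs), `mean_balanced_accuracy`, `sd_balanced_accuracy`.
#' @export
summarize_validation <- function(pair_sets, level = 2, min_records = 10) {
  stopifnot(level %in% c(1, 2), length(pair_sets) >= 1)
  rows <- list(); pooled <- list()
  for (nm in names(pair_sets)) {
    p <- pair_sets[[nm]]
    if (level == 1)
      p <- data.frame(expected = level1_of(p$expected),
                      predicted = level1_of(p$predicted))
    cm <- confusion(p, min_records = min_records)
    m <- metrics(cm)
    k <- m$class_metrics
    k <- k[k$n_records > 0, , drop = FALSE]
    rows[[nm]] <- data.frame(dataset = nm, code = k$code,
                             n_records = k$n_records,
                             balanced_accuracy = k$balanced_accuracy)
    retained <- as.integer(rownames(cm))
    pooled[[nm]] <- p[p$expected %in% retained, , drop = FALSE]
  }
  tab <- do.call(rbind, rows)
  ba <- tab$balanced_accuracy[!is.na(tab$balanced_accuracy)]
  all_pairs <- do.call(rbind, pooled)
  list(table = tab,
       overall_accuracy = mean(all_pairs$expected == all_pairs$predicted),
       mean_balanced_accuracy = mean(ba),
       sd_balanced_accuracy = if (length(ba) >= 2) stats::sd(ba) else NA_real_)
}
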