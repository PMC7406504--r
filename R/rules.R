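#' Predicate constructors for habitat rules
#'
#' Predicates are finite boolean expression trees over named stack layers.
#' Atoms:
#' * `p_code_in(layer, codes)` — categorical layer value in a code set;
#' * `p_threshold(layer, op, value)` — continuous layer compared with one of
#'   `<`, `<=`, `>`, `>=`;
#' * `p_mask(layer)` — a binary mask is set;
#' and combinators `p_all(...)`, `p_any(...)`, `p_not(x)`. Nodata in an
#' atom's layer makes the atom `FALSE` (never `TRUE`), so classification is
#' biased toward leaving a cell unassigned rather than misassigning it.
#'
#' @param layer stack layer name.
#' @param codes integer code set.
#' @param op one of `"<"`, `"<="`, `">"`, `">="`.
#' @param value numeric comparison value.
#' @param ... sub-predicates.
#' @param x a sub-predicate.
#' @return A predicate (a tagged list).
#' @name predicates
NULL

#' @rdname predicates
#' @export
p_code_in <- function(layer, codes) {
  stopifnot(is.character(layer), length(codes) >= 1)
  list(atom = "code_in", layer = layer, codes = as.integer(codes))
}

#' @rdname predicates
#' @export
p_threshold <- function(layer, op, value) {
  op <- match.arg(op, c("<", "<=", ">", ">="))
  stopifnot(is.character(layer), is.numeric(value), length(value) == 1)
  list(atom = "threshold", layer = layer, op = op, value = as.numeric(value))
}

#' @rdname predicates
#' @export
p_mask <- function(layer) {
  stopifnot(is.character(layer))
  list(atom = "mask", layer = layer)
}

#' @rdname predicates
#' @export
p_all <- function(...) list(atom = "all", of = list(...))

#' @rdname predicates
#' @export
p_any <- function(...) list(atom = "any", of = list(...))

#' @rdname predicates
#' @export
p_not <- function(x) list(atom = "not", of = list(x))

#' Evaluate a predicate over a whole stack
#'
#' Returns a logical matrix; nodata in any referenced atom layer evaluates
#' that atom to `FALSE`.
#'
#' @param pred a predicate.
#' @param stack a `layer_stack`.
#' @param context optional string for error messages.
#' @return Logical matrix of the stack's grid dimensions.
#' @export
eval_predicate <- function(pred, stack, context = NULL) {
  a <- pred$atom
  if (a == "all") {
    out <- NULL
    for (p in pred$of) {
      m <- eval_predicate(p, stack, context)
      out <- if (is.null(out)) m else out & m
    }
    if (is.null(out)) stop("empty 'all' predicate")
    return(out)
  }
  if (a == "any") {
    out <- NULL
    for (p in pred$of) {
      m <- eval_predicate(p, stack, context)
      out <- if (is.null(out)) m else out | m
    }
    if (is.null(out)) stop("empty 'any' predicate")
    return(out)
  }
  if (a == "not") return(!eval_predicate(pred$of[[1]], stack, context))
  layer <- stack_layer(stack, pred$layer, context)
  if (a == "code_in") {
    d <- layer$data
    return(matrix(!is.na(d) & d %in% pred$codes, nrow(d), ncol(d)))
  }
  if (a == "threshold") {
    d <- layer$data
    cmp <- switch(pred$op,
                  "<"  = d <  pred$value, "<=" = d <= pred$value,
                  ">"  = d >  pred$value, ">=" = d >= pred$value)
    cmp[is.na(cmp)] <- FALSE
    return(cmp)
  }
  if (a == "mask") return(layer$data)
  stop("unknown predicate atom '", a, "'")
}

predicate_layers <- function(pred) {
  if (pred$atom %in% c("all", "any", "not"))
    unique(unlist(lapply(pred$of, predicate_layers)))
  else pred$layer
}

describe_atom <- function(pred) {
  switch(pred$atom,
         code_in  = sprintf("code_in(%s, {%s})", pred$layer,
                            paste(pred$codes, collapse = ",")),
         threshold = sprintf("threshold(%s %s %g)", pred$layer, pred$op,
                             pred$value),
         mask = sprintf("mask(%s)", pred$layer),
         pred$atom)
}

# Scalar evaluation at one cell, tracking the first failing atom.
eval_predicate_cell <- function(pred, stack, row, col) {
  a <- pred$atom
  if (a == "all") {
    for (p in pred$of) {
      r <- eval_predicate_cell(p, stack, row, col)
      if (!r$value) return(r)
    }
    return(list(value = TRUE, first_fail = NA_character_))
  }
  if (a == "any") {
    fail <- NA_character_
    for (p in pred$of) {
      r <- eval_predicate_cell(p, stack, row, col)
      if (r$value) return(list(value = TRUE, first_fail = NA_character_))
      if (is.na(fail)) fail <- r$first_fail
    }
    return(list(value = FALSE, first_fail = fail))
  }
  if (a == "not") {
    r <- eval_predicate_cell(pred$of[[1]], stack, row, col)
    return(list(value = !r$value,
                first_fail = if (r$value) paste0("not(", describe_atom(pred$of[[1]]), ")") else NA_character_))
  }
  layer <- stack_layer(stack, pred$layer)
  v <- layer$data[row, col]
  val <- switch(a,
                code_in = !is.na(v) && v %in% pred$codes,
                threshold = !is.na(v) && switch(pred$op,
                                                "<" = v < pred$value, "<=" = v <= pred$value,
                                                ">" = v > pred$value, ">=" = v >= pred$value),
                mask = isTRUE(v),
                stop("unknown predicate atom '", a, "'"))
  list(value = val, first_fail = if (val) NA_character_ else describe_atom(pred))
}

# ---- rules and rulesets -------------------------------------------------

#' Build a habitat rule
#'
#' @param target Level-2 habitat code (decade encoding), registered in the
#'   habitat legend.
#' @param when a predicate (see [predicates]).
#' @param group one of `"artificial"`, `"natural"`, `"default"`; default
#'   rules must target a minor-0 (Level-1 default) code.
#' @return An object of class `hm_rule`.
#' @export
rule <- function(target, when, group = c("natural", "artificial", "default")) {
  group <- match.arg(group)
  target <- as.integer(target)
  h <- habitat_legend()
  if (!target %in% h$code)
    stop("rule target ", target, " is not a registered habitat code")
  if (group == "default" && target %% 100 != 0)
    stop("default rule target must be a Level-1 default code (minor 0), got ",
         target)
  structure(list(target = target, when = when, group = group),
            class = "hm_rule")
}

#' Ordered first-match ruleset
#'
#' Validates the structural invariants at construction time: unique targets,
#' every artificial rule before every natural/default rule, and at most one
#' default rule per Level-1 block, placed last within the block.
#'
#' @param rules list of [rule()] objects.
#' @param name ruleset name.
#' @return An object of class `hm_ruleset`.
#' @export
ruleset <- function(rules, name = "unnamed") {
  for (r in rules) stopifnot(inherits(r, "hm_rule"))
  targets <- vapply(rules, function(r) r$target, integer(1))
  if (anyDuplicated(targets))
    stop("duplicate rule targets: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  groups <- vapply(rules, function(r) r$group, character(1))
  first_nat <- match(TRUE, groups != "artificial")
  if (!is.na(first_nat) && any(groups[seq_along(groups) >= first_nat] == "artificial")) {
    bad <- which(groups == "artificial" & seq_along(groups) >= first_nat)[1]
    stop("artificial rule at position ", bad,
         " follows a natural/default rule; anthropogenic classes must be mapped first")
  }
  l1 <- targets %/% 100L
  for (lev in unique(l1)) {
    in_block <- which(l1 == lev)
    defaults <- in_block[groups[in_block] == "default"]
    if (length(defaults) > 1)
      stop("Level-1 block ", lev, " has more than one default rule")
    if (length(defaults) == 1 && defaults != max(in_block))
      stop("default rule for Level-1 block ", lev,
           " must be the block's last rule (rule index ", defaults, ")")
  }
  structure(list(name = name, rules = rules), class = "hm_ruleset")
}

#' @export
print.hm_ruleset <- function(x, ...) {
  cat(sprintf("<ruleset '%s'> %d rules: %s\n", x$name, length(x$rules),
              paste(vapply(x$rules, function(r) r$target, integer(1)),
                    collapse = " > ")))
  invisible(x)
}

#' Length of a ruleset (number of rules)
#' @param x an `hm_ruleset`.
#' @export
length.hm_ruleset <- function(x) length(x$rules)

#' Classify a layer stack into Level-2 habitat codes
#'
#' Sequential first-match semantics: rules are evaluated in ruleset order and
#' each cell takes the target of the first rule whose predicate holds there;
#' a matched cell is never re-evaluated by later rules. Cells matching no
#' rule stay nodata. Because the ruleset orders anthropogenic rules first,
#' artificial classes mask all natural ones. Evaluation is vectorised
#' whole-grid boolean algebra, equivalent to a per-cell loop over the rules.
#'
#' @param stack a `layer_stack` containing every layer the ruleset references.
#' @param rs an `hm_ruleset` (default: the shipped default ruleset).
#' @return A `categorical_layer` of Level-2 habitat codes
#'   (legend `"iucn_habitat"`).
#' @export
classify <- function(stack, rs = default_ruleset()) {
  stopifnot(inherits(stack, "layer_stack"), inherits(rs, "hm_ruleset"))
  g <- stack[[1]]$grid
  out <- matrix(NA_integer_, g$n_rows, g$n_cols)
  unassigned <- matrix(TRUE, g$n_rows, g$n_cols)
  for (r in rs$rules) {
    if (!any(unassigned)) break
    hit <- eval_predicate(r$when, stack,
                          context = paste0("rule for class ", r$target))
    sel <- hit & unassigned
    out[sel] <- r$target
    unassigned[sel] <- FALSE
  }
  categorical_layer(g, out, "iucn_habitat")
}

#' Project a Level-2 habitat map to Level 1
#'
#' Cellwise [level1_of()]; nodata is preserved.
#'
#' @param map a `categorical_layer` of habitat codes.
#' @return A `categorical_layer` of Level-1 codes (legend
#'   `"iucn_habitat_level1"`).
#' @export
level1_map <- function(map) {
  stopifnot(inherits(map, "categorical_layer"))
  m <- matrix(level1_of(as.vector(map$data)),
              map$grid$n_rows, map$grid$n_cols)
  categorical_layer(map$grid, m, "iucn_habitat_level1")
}

#' Explain the classification of one cell
#'
#' Replays the ruleset at a single cell and reports, per rule up to and
#' including the first match, whether its predicate held and (if not) the
#' first failing atom. An audit/debugging aid; its final matched target
#' always equals [classify()]'s output for the cell.
#'
#' @param stack a `layer_stack`.
#' @param rs an `hm_ruleset`.
#' @param row,col 1-based cell indices.
#' @return A data frame with columns `target`, `matched`, `first_fail`; the
#'   attribute `matched_target` holds the assigned code (`NA` if none).
#' @export
explain <- function(stack, rs, row, col) {
  g <- stack[[1]]$grid
  if (row < 1 || row > g$n_rows || col < 1 || col > g$n_cols)
    stop("cell (", row, ", ", col, ") is outside the grid")
  targets <- integer(0); matched <- logical(0); fails <- character(0)
  final <- NA_integer_
  for (r in rs$rules) {
    res <- eval_predicate_cell(r$when, stack, row, col)
    targets <- c(targets, r$target)
    matched <- c(matched, res$value)
    fails <- c(fails, res$first_fail)
    if (res$value) { final <- r$target; break }
  }
  out <- data.frame(target = targets, matched = matched, first_fail = fails)
  attr(out, "matched_target") <- final
  out
}

# ---- ruleset (de)serialisation -----------------------------------------

predicate_from_list <- function(x, where) {
  if (is.null(x$atom)) stop("predicate without 'atom' in ", where)
  switch(x$atom,
         code_in = p_code_in(x$layer, unlist(x$codes)),
         threshold = p_threshold(x$layer, x$op, x$value),
         mask = p_mask(x$layer),
         all = do.call(p_all, lapply(x$of, predicate_from_list, where = where)),
         any = do.call(p_any, lapply(x$of, predicate_from_list, where = where)),
         not = p_not(predicate_from_list(x$of[[1]], where)),
         stop("unknown atom '", x$atom, "' in ", where))
}

predicate_to_list <- function(p) {
  if (p$atom %in% c("all", "any", "not"))
    list(atom = p$atom, of = lapply(p$of, predicate_to_list))
  else unclass(p)
}

#' Parse a ruleset from YAML (file or pre-parsed list)
#'
#' The document has a `name` and an ordered `rules` list; each rule gives a
#' `target` code, a `group` and a `when` predicate (see the shipped
#' `extdata/ruleset_default.yaml` for the schema). All structural invariants
#' are validated at parse time; violations report the offending rule index.
#'
#' @param x path to a YAML file, or an equivalent nested list.
#' @return An `hm_ruleset`.
#' @export
parse_ruleset <- function(x) {
  doc <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(doc$rules)) doc <- list(name = "unnamed", rules = doc)
  rules <- vector("list", length(doc$rules))
  for (i in seq_along(doc$rules)) {
    r <- doc$rules[[i]]
    where <- paste0("rule ", i)
    if (is.null(r$target)) stop("missing target in ", where)
    rules[[i]] <- tryCatch(
      rule(r$target, predicate_from_list(r$when, where),
           group = if (is.null(r$group)) "natural" else r$group),
      error = function(e) stop("in ", where, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  ruleset(rules, name = if (is.null(doc$name)) "unnamed" else doc$name)
}

#' @rdname parse_ruleset
#' @param rs an `hm_ruleset`.
#' @param path optional file to write YAML to.
#' @return `serialize_ruleset()`: the canonical nested list (invisibly if
#'   written to a file).
#' @export
serialize_ruleset <- function(rs, path = NULL) {
  doc <- list(name = rs$name,
              rules = lapply(rs$rules, function(r)
                list(target = r$target, group = r$group,
                     when = predicate_to_list(r$when))))
  if (!is.null(path)) {
    yaml::write_yaml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' The shipped default ruleset
#'
#' Parses and caches `extdata/ruleset_default.yaml`: the published sequential
#' class order with predicates reconstructed from the class definitions.
#' Users supply their own complete ruleset file for production use.
#'
#' @return An `hm_ruleset`.
#' @export
default_ruleset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- parse_ruleset(system.file("extdata", "ruleset_default.yaml",
                                          package = "habitatmapr"))
    cache
  }
})
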