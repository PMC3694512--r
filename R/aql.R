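#' @title AQL-subset parsing, translation and execution
#'
#' @description
#' A recursive-descent parser for a subset of the archetype query language:
#' `SELECT` with aliased paths, `FROM EHR [ehr_id=$p]`, chained `CONTAINS`
#' with archetype predicates, and `WHERE` with comparisons, `MATCHES` code
#' sets, `AND`/`OR` and parentheses, plus `$named` parameters. Parsed queries
#' are translated -- through a pluggable backend registry, of which only the
#' `"native"` in-memory backend ships -- into an executable plan with a
#' printable text form (returned verbatim by the query protocol's debug
#' mode), then run against a [version_store()]: only latest, non-deleted
#' compositions are visible to queries.
#'
#' @name aql_engine
NULL

# ---- tokenizer ---------------------------------------------------------------

aql_keywords <- c("SELECT", "AS", "FROM", "CONTAINS", "WHERE", "AND", "OR", "MATCHES")
aql_source_kinds <- c("EHR", "COMPOSITION", "OBSERVATION", "EVALUATION",
                      "INSTRUCTION", "ACTION", "SECTION", "ADMIN_ENTRY")

tokenize_aql <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  i <- 1L
  ident_start <- function(ch) grepl("[A-Za-z_]", ch)
  ident_char <- function(ch) grepl("[A-Za-z0-9_.-]", ch)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[ \t\r\n]", ch)) { i <- i + 1L; next }
    if (ch == "$") {
      j <- i + 1L
      while (j <= n && ident_char(chars[j])) j <- j + 1L
      if (j == i + 1L) stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: bare '$'", i))
      push("PARAM", paste(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      i <- j; next
    }
    if (grepl("[0-9]", ch) || (ch == "-" && i < n && grepl("[0-9]", chars[i + 1L]))) {
      j <- i + 1L
      while (j <= n && grepl("[0-9.]", chars[j])) j <- j + 1L
      push("NUMBER", as.numeric(paste(chars[i:(j - 1L)], collapse = "")), i)
      i <- j; next
    }
    if (ch == "'" || ch == '"') {
      q <- ch; j <- i + 1L; buf <- character(0)
      while (j <= n && chars[j] != q) { buf <- c(buf, chars[j]); j <- j + 1L }
      if (j > n) stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: unterminated string", i))
      push("STRING", paste(buf, collapse = ""), i)
      i <- j + 1L; next
    }
    if (ident_start(ch)) {
      j <- i + 1L
      while (j <= n && ident_char(chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      up <- toupper(word)
      if (up %in% aql_keywords) push("KW", up, i)
      else if (up %in% aql_source_kinds) push("KIND", up, i)
      else push("IDENT", word, i)
      i <- j; next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("<=", ">=", "!=")) { push("OP", two, i); i <- i + 2L; next }
    if (ch %in% c("=", "<", ">")) { push("OP", ch, i); i <- i + 1L; next }
    if (ch %in% c("/", "[", "]", "(", ")", "{", "}", ",")) { push(ch, ch, i); i <- i + 1L; next }
    stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: unexpected character '%s'", i, ch))
  }
  toks
}

# ---- parser ------------------------------------------------------------------

#' Parse an AQL query
#'
#' @param text Query text.
#' @return An `aql_ast` with `select` items, `sources` (the containment chain
#'   rooted at the EHR source), the `where` predicate tree, and the set of
#'   `$`-`parameters` used.
#' @examples
#' ast <- parse_aql(paste(
#'   "SELECT o/data/events/data/items[at0004]/value/magnitude AS systolic",
#'   "FROM EHR e [ehr_id=$current_ehr_uid]",
#'   "CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter.v1]",
#'   "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]",
#'   "WHERE o/data/events/data/items[at0004]/value/magnitude > 185"))
#' ast$parameters
#' @export
parse_aql <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) stop_ehrest("parse_error", "empty AQL query")
  toks <- tokenize_aql(text)
  pos <- 1L
  peek <- function(k = 0L) if (pos + k <= length(toks)) toks[[pos + k]] else NULL
  take <- function() { t <- peek(); if (is.null(t)) stop_ehrest("parse_error", "AQL syntax error: unexpected end of query"); pos <<- pos + 1L; t }
  expect <- function(type, value = NULL) {
    t <- take()
    if (t$type != type || (!is.null(value) && !identical(t$value, value))) {
      stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected %s%s, found '%s'",
                                         t$pos, type, if (!is.null(value)) paste0(" '", value, "'") else "", t$value))
    }
    t
  }
  params <- character(0)

  parse_path_after_alias <- function(alias) {
    segs <- list()
    while (!is.null(peek()) && peek()$type == "/") {
      take()
      nm <- expect("IDENT")$value
      pred <- NULL
      if (!is.null(peek()) && peek()$type == "[") {
        take()
        # predicate token: everything up to ']' -- idents, dots, numbers
        parts <- character(0)
        repeat {
          t <- take()
          if (t$type == "]") break
          parts <- c(parts, as.character(t$value))
        }
        pred <- paste(parts, collapse = "")
      }
      segs[[length(segs) + 1L]] <- list(attribute_name = nm, predicate = pred)
    }
    if (length(segs) == 0L) {
      stop_ehrest("parse_error", sprintf("AQL syntax error: alias '%s' must be followed by a path", alias))
    }
    list(alias = alias, path = rm_path(segs))
  }

  parse_operand <- function() {
    t <- take()
    if (t$type == "NUMBER") return(list(kind = "literal", value = t$value))
    if (t$type == "STRING") return(list(kind = "literal", value = t$value))
    if (t$type == "PARAM") { params <<- union(params, t$value); return(list(kind = "parameter", name = t$value)) }
    stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected literal or $parameter", t$pos))
  }

  parse_comparison <- function() {
    alias <- expect("IDENT")$value
    ap <- parse_path_after_alias(alias)
    t <- take()
    if (t$type == "KW" && t$value == "MATCHES") {
      expect("{")
      codes <- character(0)
      repeat {
        tt <- take()
        if (!tt$type %in% c("STRING", "IDENT", "NUMBER")) {
          stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected code in MATCHES set", tt$pos))
        }
        codes <- c(codes, as.character(tt$value))
        nx <- take()
        if (nx$type == "}") break
        if (nx$type != ",") stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected ',' or '}'", nx$pos))
      }
      return(list(node = "comparison", alias = ap$alias, path = ap$path,
                  operator = "matches", operand = list(kind = "codeset", codes = codes)))
    }
    if (t$type != "OP") stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected comparison operator", t$pos))
    list(node = "comparison", alias = ap$alias, path = ap$path,
         operator = t$value, operand = parse_operand())
  }

  parse_primary <- function() {
    if (!is.null(peek()) && peek()$type == "(") {
      take()
      e <- parse_or()
      expect(")")
      return(e)
    }
    parse_comparison()
  }
  parse_and <- function() {
    left <- parse_primary()
    while (!is.null(peek()) && peek()$type == "KW" && peek()$value == "AND") {
      take()
      left <- list(node = "and", left = left, right = parse_primary())
    }
    left
  }
  parse_or <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek()$type == "KW" && peek()$value == "OR") {
      take()
      left <- list(node = "or", left = left, right = parse_and())
    }
    left
  }

  # SELECT ...
  expect("KW", "SELECT")
  select <- list()
  repeat {
    alias <- expect("IDENT")$value
    ap <- parse_path_after_alias(alias)
    label <- NULL
    if (!is.null(peek()) && peek()$type == "KW" && peek()$value == "AS") {
      take()
      label <- expect("IDENT")$value
    }
    select[[length(select) + 1L]] <- list(alias = ap$alias, path = ap$path,
                                          label = label %||% paste0("col", length(select) + 1L))
    if (!is.null(peek()) && peek()$type == ",") take() else break
  }

  # FROM EHR e [ehr_id=$x]
  expect("KW", "FROM")
  expect("KIND", "EHR")
  ehr_alias <- expect("IDENT")$value
  ehr_predicate <- NULL
  if (!is.null(peek()) && peek()$type == "[") {
    take()
    key <- expect("IDENT")$value
    if (key != "ehr_id") stop_ehrest("parse_error", sprintf("AQL syntax error: unsupported EHR predicate '%s'", key))
    expect("OP", "=")
    ehr_predicate <- parse_operand()
    expect("]")
  }
  sources <- list(list(alias = ehr_alias, kind = "EHR", archetype_id = NULL, parent = NULL))

  # CONTAINS chain
  parent <- ehr_alias
  while (!is.null(peek()) && peek()$type == "KW" && peek()$value == "CONTAINS") {
    take()
    kind_tok <- take()
    if (kind_tok$type != "KIND") {
      stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: expected a class name after CONTAINS", kind_tok$pos))
    }
    alias <- expect("IDENT")$value
    archetype <- NULL
    if (!is.null(peek()) && peek()$type == "[") {
      take()
      parts <- character(0)
      repeat {
        t <- take()
        if (t$type == "]") break
        parts <- c(parts, as.character(t$value))
      }
      archetype <- paste(parts, collapse = "")
    }
    sources[[length(sources) + 1L]] <- list(alias = alias, kind = kind_tok$value,
                                            archetype_id = archetype, parent = parent)
    parent <- alias
  }

  where <- NULL
  if (!is.null(peek())) {
    expect("KW", "WHERE")
    where <- parse_or()
  }
  if (!is.null(peek())) {
    t <- peek()
    stop_ehrest("parse_error", sprintf("AQL syntax error at position %d: unexpected '%s' after query", t$pos, t$value))
  }

  declared <- vapply(sources, `[[`, character(1), "alias")
  used <- vapply(select, `[[`, character(1), "alias")
  walk_aliases <- function(p) {
    if (is.null(p)) return(character(0))
    if (p$node == "comparison") return(p$alias)
    c(walk_aliases(p$left), walk_aliases(p$right))
  }
  used <- c(used, walk_aliases(where))
  bad <- setdiff(used, declared)
  if (length(bad) > 0L) {
    stop_ehrest("parse_error", sprintf("AQL error: alias '%s' not declared in FROM/CONTAINS", bad[1]))
  }
  if (!is.null(ehr_predicate) && ehr_predicate$kind == "parameter") {
    params <- union(params, ehr_predicate$name)
  }
  structure(list(select = select, sources = sources, ehr_predicate = ehr_predicate,
                 where = where, parameters = sort(params), text = text),
            class = "aql_ast")
}

#' @export
print.aql_ast <- function(x, ...) {
  cat(sprintf("<aql_ast> %d select item(s), %d source(s), %d parameter(s)\n",
              length(x$select), length(x$sources), length(x$parameters)))
  invisible(x)
}

# ---- backend registry and translation ---------------------------------------

backend_registry <- new.env(parent = emptyenv())

#' Register a query-translation backend
#'
#' Translators turn an `aql_ast` into an executable plan for one storage
#' dialect. Only `"native"` (the in-memory store) ships; the registry exists
#' so translators for other storage engines can be plugged in.
#'
#' @param name Dialect id.
#' @param translator `function(aql_ast) -> query_plan`.
#' @export
register_backend <- function(name, translator) {
  assign(name, translator, envir = backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(backend_registry))

#' Translate a parsed query into an executable plan
#'
#' Translation is deterministic: the same AST always yields a byte-identical
#' printable form (`plan_text()`), which the query protocol returns verbatim
#' in debug mode.
#'
#' @param ast An `aql_ast`.
#' @param backend Dialect id (default `"native"`).
#' @return A `query_plan`.
#' @export
translate_aql <- function(ast, backend = "native") {
  if (!exists(backend, envir = backend_registry, inherits = FALSE)) {
    stop_ehrest("bad_request", sprintf("unknown query backend '%s'; available: %s",
                                       backend, paste(list_backends(), collapse = ", ")))
  }
  get(backend, envir = backend_registry)(ast)
}

native_translator <- function(ast) {
  containment <- ast$sources[-1]  # everything below the EHR source
  structure(list(
    backend = "native",
    containment = containment,
    select = ast$select,
    where = ast$where,
    ehr_predicate = ast$ehr_predicate,
    required_parameters = ast$parameters
  ), class = "query_plan")
}

#' Printable text form of a query plan
#' @param plan A `query_plan`.
#' @return A single string (deterministic for a given AST).
#' @export
plan_text <- function(plan) {
  pred_text <- function(p) {
    if (is.null(p)) return("true")
    if (p$node == "comparison") {
      op <- p$operand
      rhs <- switch(op$kind,
        literal   = if (is.numeric(op$value)) format_num(op$value) else paste0("'", op$value, "'"),
        parameter = paste0("$", op$name),
        codeset   = paste0("{", paste(op$codes, collapse = ","), "}"))
      return(sprintf("%s%s %s %s", p$alias, format(p$path), p$operator, rhs))
    }
    sprintf("(%s %s %s)", pred_text(p$left), toupper(p$node), pred_text(p$right))
  }
  lines <- c("NATIVE QUERY PLAN")
  scope <- if (is.null(plan$ehr_predicate)) "multi (all records)" else {
    ep <- plan$ehr_predicate
    if (ep$kind == "parameter") sprintf("single (ehr_id = $%s)", ep$name) else sprintf("single (ehr_id = '%s')", ep$value)
  }
  lines <- c(lines, paste0("scope: ", scope))
  for (s in plan$containment) {
    lines <- c(lines, sprintf("scan: %s %s%s", s$kind, s$alias,
                              if (!is.null(s$archetype_id)) paste0(" [", s$archetype_id, "]") else ""))
  }
  lines <- c(lines, paste0("filter: ", pred_text(plan$where)))
  for (s in plan$select) {
    lines <- c(lines, sprintf("project: %s%s AS %s", s$alias, format(s$path), s$label))
  }
  lines <- c(lines, paste0("parameters: ",
                           if (length(plan$required_parameters) == 0L) "(none)"
                           else paste(plan$required_parameters, collapse = ", ")))
  paste(lines, collapse = "\n")
}

#' @export
print.query_plan <- function(x, ...) {
  cat(plan_text(x), "\n")
  invisible(x)
}

# ---- execution ---------------------------------------------------------------

# Engine-side path matching, compiled into an iterative worklist walk
# (independent of rm_core::resolve_path, which the test oracle uses).
match_path_nodes <- function(node, segments) {
  frontier <- list(node)
  for (seg in segments) {
    nxt <- list()
    for (cur in frontier) {
      kids <- cur$children
      for (k in seq_along(kids)) {
        ch <- kids[[k]]
        if (identical(ch$name, seg$attribute_name) &&
            (is.null(seg$predicate) || identical(ch$node_id, seg$predicate))) {
          nxt[[length(nxt) + 1L]] <- ch
        }
      }
    }
    if (length(nxt) == 0L) return(list())
    frontier <- nxt
  }
  frontier
}

# First value addressed by a path from a bound node, or NULL.
plan_value_at <- function(node, path) {
  segs <- path$segments
  n <- length(segs)
  hits <- match_path_nodes(node, segs)
  for (h in hits) if (!is.null(h$value)) return(h$value)
  if (n >= 1L && is.null(segs[[n]]$predicate) && segs[[n]]$attribute_name %in% leaf_field_names) {
    for (h in match_path_nodes(node, segs[-n])) {
      v <- h$value
      if (!is.null(v) && !is.null(v[[segs[[n]]$attribute_name]])) return(v[[segs[[n]]$attribute_name]])
    }
  }
  NULL
}

value_as_number <- function(v) {
  if (is.null(v)) return(NULL)
  if (is.numeric(v)) return(v)
  if (is.list(v) && identical(v$type, "quantity")) return(v$magnitude)
  NULL
}

value_as_string <- function(v) {
  if (is.null(v)) return(NULL)
  if (is.character(v)) return(v)
  if (is.list(v)) {
    if (identical(v$type, "text") || identical(v$type, "timestamp")) return(v$value)
    if (identical(v$type, "coded_text")) return(v$code)
  }
  NULL
}

eval_predicate <- function(pred, bindings, params) {
  if (is.null(pred)) return(TRUE)
  if (pred$node == "and") return(eval_predicate(pred$left, bindings, params) &&
                                 eval_predicate(pred$right, bindings, params))
  if (pred$node == "or") return(eval_predicate(pred$left, bindings, params) ||
                                eval_predicate(pred$right, bindings, params))
  node <- bindings[[pred$alias]]
  v <- plan_value_at(node, pred$path)
  if (pred$operator == "matches") {
    s <- value_as_string(v)
    if (is.null(s)) return(FALSE)
    return(s %in% pred$operand$codes)
  }
  op <- pred$operand
  rhs <- switch(op$kind,
    literal = op$value,
    parameter = {
      if (is.null(params[[op$name]])) stop_ehrest("bad_request", sprintf("unbound query parameter '$%s'", op$name))
      params[[op$name]]
    })
  if (is.character(rhs)) {
    num <- suppressWarnings(as.numeric(rhs))
    if (!is.na(num) && op$kind == "parameter") rhs <- num
  }
  if (is.numeric(rhs)) {
    lhs <- value_as_number(v)
    if (is.null(lhs)) {
      if (!is.null(v) && !is.null(value_as_string(v))) {
        stop_ehrest("bad_request", sprintf("type mismatch: numeric comparison against a text value at %s", format(pred$path)))
      }
      return(FALSE)
    }
    return(switch(pred$operator,
      "="  = lhs == rhs, "!=" = lhs != rhs,
      "<"  = lhs < rhs,  "<=" = lhs <= rhs,
      ">"  = lhs > rhs,  ">=" = lhs >= rhs))
  }
  lhs <- value_as_string(v)
  if (is.null(lhs)) {
    if (!is.null(value_as_number(v))) {
      stop_ehrest("bad_request", sprintf("type mismatch: string comparison against a numeric value at %s", format(pred$path)))
    }
    return(FALSE)
  }
  switch(pred$operator,
    "="  = lhs == rhs, "!=" = lhs != rhs,
    stop_ehrest("bad_request", sprintf("operator '%s' is not defined for strings", pred$operator)))
}

# Find descendant nodes carrying a given archetype id, in document order.
archetype_subtrees <- function(node, archetype_id) {
  out <- list()
  walk <- function(nd) {
    if (identical(nd$node_id, archetype_id)) out[[length(out) + 1L]] <<- nd
    for (ch in nd$children) walk(ch)
  }
  for (ch in node$children) walk(ch)
  out
}

#' Execute a query plan against a store
#'
#' Visible data are exactly the latest, non-deleted versions of each object.
#' Rows are emitted in deterministic order: record id, then object commit
#' order, then document order of containment bindings. Single scope binds one
#' record (from the `ehr_id`/parameter binding); multi scope iterates all
#' records in the supplied store (a read replica, when so configured).
#'
#' @param plan A `query_plan`.
#' @param store A `VersionStore`.
#' @param params Named list binding every `$parameter` the plan requires.
#' @param scope_ehr Optional record id forced by the calling context (the
#'   single-record URI scope).
#' @return A `result_set` with columns, typed rows, and per-row provenance
#'   (the source version uid).
#' @export
execute_plan <- function(plan, store, params = list(), scope_ehr = NULL) {
  for (p in plan$required_parameters) {
    if (is.null(params[[p]])) stop_ehrest("bad_request", sprintf("unbound query parameter '$%s'", p))
  }
  ehr_ids <- if (!is.null(scope_ehr)) scope_ehr
  else if (!is.null(plan$ehr_predicate)) {
    ep <- plan$ehr_predicate
    if (ep$kind == "parameter") as.character(params[[ep$name]]) else as.character(ep$value)
  } else sort(store$ehr_ids())

  columns <- vapply(plan$select, `[[`, character(1), "label")
  rows <- list(); provenance <- character(0)

  for (eid in ehr_ids) {
    if (!store$has_ehr(eid)) next
    latest <- store$latest_versions(eid)
    for (v in latest) {
      if (identical(v$change_type, "deleted") || is.null(v$data)) next
      root <- v$data
      # containment chain: first non-EHR source binds the composition root
      bindings_list <- list(list())
      ok <- TRUE
      for (ci in seq_along(plan$containment)) {
        src <- plan$containment[[ci]]
        new_bindings <- list()
        for (b in bindings_list) {
          if (ci == 1L) {
            if (is.null(src$archetype_id) || identical(root$node_id, src$archetype_id)) {
              b[[src$alias]] <- root
              new_bindings[[length(new_bindings) + 1L]] <- b
            }
          } else {
            parent_node <- b[[plan$containment[[ci - 1L]]$alias]]
            cands <- if (is.null(src$archetype_id)) list(parent_node)
                     else archetype_subtrees(parent_node, src$archetype_id)
            for (cand in cands) {
              b2 <- b
              b2[[src$alias]] <- cand
              new_bindings[[length(new_bindings) + 1L]] <- b2
            }
          }
        }
        bindings_list <- new_bindings
        if (length(bindings_list) == 0L) { ok <- FALSE; break }
      }
      if (!ok) next
      for (b in bindings_list) {
        if (!eval_predicate(plan$where, b, params)) next
        row <- vector("list", length(plan$select))
        for (si in seq_along(plan$select)) {
          s <- plan$select[[si]]
          node <- b[[s$alias]]
          row[[si]] <- if (is.null(node)) NULL else plan_value_at(node, s$path)
        }
        names(row) <- columns
        rows[[length(rows) + 1L]] <- row
        provenance <- c(provenance, format(v$uid))
      }
    }
  }
  result_set(columns, rows, provenance)
}

#' Construct a result set
#' @param columns Ordered column labels.
#' @param rows List of rows; each row a named list of values (possibly NULL).
#' @param provenance Character vector of source version uids, one per row.
#' @return A `result_set`.
#' @export
result_set <- function(columns, rows = list(), provenance = character(0)) {
  stopifnot(length(rows) == length(provenance))
  structure(list(columns = columns, rows = rows, provenance = provenance),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d row(s) x %d column(s): %s\n",
              length(x$rows), length(x$columns), paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Convert a result set to a data.frame
#' @param x A `result_set`.
#' @param ... Unused.
#' @export
as.data.frame.result_set <- function(x, ...) {
  cols <- lapply(x$columns, function(cn) {
    vapply(x$rows, function(r) {
      v <- r[[cn]]
      n <- value_as_number(v)
      if (!is.null(n)) return(n)
      NA_real_
    }, numeric(1))
  })
  names(cols) <- x$columns
  df <- as.data.frame(cols, optional = TRUE)
  df$.uid <- x$provenance
  df
}

# ---- result-set serialization -----------------------------------------------

cell_value_to_xml <- function(cell_el, v) {
  if (is.null(v)) return(invisible(NULL))
  if (is.numeric(v)) {
    e <- xml2::xml_add_child(cell_el, "number"); xml2::xml_set_attr(e, "v", format_num(v))
  } else if (is.character(v)) {
    e <- xml2::xml_add_child(cell_el, "string"); xml2::xml_set_attr(e, "v", v)
  } else if (is.list(v) && !is.null(v$type)) {
    e <- xml2::xml_add_child(cell_el, v$type)
    if (v$type == "quantity") {
      xml2::xml_set_attr(e, "magnitude", format_num(v$magnitude)); xml2::xml_set_attr(e, "units", v$units)
    } else if (v$type == "coded_text") {
      xml2::xml_set_attr(e, "code", v$code); xml2::xml_set_attr(e, "terminology", v$terminology)
      xml2::xml_set_attr(e, "label", v$label)
    } else {
      xml2::xml_set_attr(e, "v", v$value)
    }
  } else stop_ehrest("internal", "unserializable cell value")
  invisible(NULL)
}

xml_to_cell_value <- function(el) {
  kids <- xml2::xml_children(el)
  if (length(kids) == 0L) return(NULL)
  e <- kids[[1]]
  a <- xml2::xml_attrs(e)
  switch(xml2::xml_name(e),
    number     = as.numeric(a[["v"]]),
    string     = unname(a[["v"]]),
    quantity   = leaf_quantity(as.numeric(a[["magnitude"]]), a[["units"]]),
    coded_text = leaf_coded_text(a[["code"]], a[["terminology"]], a[["label"]]),
    text       = leaf_text(a[["v"]]),
    timestamp  = leaf_timestamp(a[["v"]]),
    stop_ehrest("parse_error", sprintf("unknown cell payload '%s'", xml2::xml_name(e)))
  )
}

#' Serialize / parse a result set
#'
#' The XML form validates against the schema shipped at
#' `system.file("extdata", "resultset.xsd", package = "ehrest")`; the JSON
#' form is its mirror. Both round-trip losslessly; column order and per-row
#' provenance uids are preserved; absent values become empty cells.
#'
#' @param rs A `result_set`.
#' @param media `"xml"` or `"json"`.
#' @return `serialize_resultset()`: a single string.
#' @export
serialize_resultset <- function(rs, media = c("xml", "json")) {
  media <- match.arg(media)
  if (media == "json") {
    x <- list(
      columns = as.list(rs$columns),
      rows = lapply(seq_along(rs$rows), function(i) {
        cells <- lapply(rs$columns, function(cn) {
          v <- rs$rows[[i]][[cn]]
          if (is.null(v)) NULL
          else if (is.numeric(v)) list(kind = "number", v = v)
          else if (is.character(v)) list(kind = "string", v = v)
          else c(list(kind = "leaf"), v)
        })
        names(cells) <- NULL
        list(uid = rs$provenance[i], cells = cells)
      })
    )
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")))
  }
  doc <- xml2::xml_new_root("resultset")
  root <- xml2::xml_root(doc)
  cols <- xml2::xml_add_child(root, "columns")
  for (cn in rs$columns) {
    e <- xml2::xml_add_child(cols, "column"); xml2::xml_set_attr(e, "name", cn)
  }
  rows <- xml2::xml_add_child(root, "rows")
  for (i in seq_along(rs$rows)) {
    r <- xml2::xml_add_child(rows, "row")
    xml2::xml_set_attr(r, "uid", rs$provenance[i])
    for (cn in rs$columns) {
      cell <- xml2::xml_add_child(r, "cell")
      xml2::xml_set_attr(cell, "column", cn)
      cell_value_to_xml(cell, rs$rows[[i]][[cn]])
    }
  }
  as.character(doc)
}

#' @rdname serialize_resultset
#' @param text Serialized result set.
#' @return `parse_resultset()`: a `result_set`.
#' @export
parse_resultset <- function(text, media = c("xml", "json")) {
  media <- match.arg(media)
  if (media == "json") {
    x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    columns <- unlist(x$columns) %||% character(0)
    rows <- list(); prov <- character(0)
    for (r in x$rows) {
      row <- vector("list", length(columns)); names(row) <- columns
      for (i in seq_along(r$cells)) {
        cv <- r$cells[[i]]
        if (is.null(cv)) next
        row[[columns[i]]] <- switch(cv$kind,
          number = as.numeric(cv$v),
          string = as.character(cv$v),
          leaf   = { cv$kind <- NULL; cv })
      }
      rows[[length(rows) + 1L]] <- row
      prov <- c(prov, r$uid)
    }
    return(result_set(columns, rows, prov))
  }
  doc <- xml2::read_xml(text)
  columns <- xml2::xml_attr(xml2::xml_find_all(doc, "/resultset/columns/column"), "name")
  row_els <- xml2::xml_find_all(doc, "/resultset/rows/row")
  rows <- list(); prov <- character(0)
  for (re in row_els) {
    row <- vector("list", length(columns)); names(row) <- columns
    for (cell in xml2::xml_children(re)) {
      cn <- xml2::xml_attr(cell, "column")
      row[[cn]] <- xml_to_cell_value(cell)
    }
    rows[[length(rows) + 1L]] <- row
    prov <- c(prov, xml2::xml_attr(re, "uid"))
  }
  result_set(columns, rows, prov)
}
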