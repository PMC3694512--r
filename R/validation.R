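#' @title Instance validation against simplified constraint documents
#' @description
#' Validation runs on three levels: reference-model conformance (structure and
#' leaf typing), archetype-level constraints, and narrower template-level
#' constraints. Constraint documents are a deliberate simplification standing
#' in for full ADL archetypes: a flat list of constrained paths with
#' occurrence bounds, leaf kinds, magnitude ranges, code sets, units and
#' defaults, serialized as JSON files so fixtures ship as plain text.
#' @name validation
NULL

#' Construct a constraint document
#'
#' @param id Archetype or template id (e.g.
#'   `"openEHR-EHR-OBSERVATION.blood_pressure.v1"`).
#' @param kind `"archetype"` or `"template"`. A template narrows one or more
#'   base archetypes: it may tighten bounds but never remove mandatory fields
#'   or add new ones.
#' @param root List `list(name=, node_id=)` describing the instance root node.
#' @param nodes List of constraint nodes from [constraint_node()].
#' @param bases For templates, ids of the archetypes being narrowed.
#' @return A `constraint_doc`.
#' @export
constraint_doc <- function(id, kind = c("archetype", "template"), root, nodes = list(),
                           bases = character(0)) {
  kind <- match.arg(kind)
  for (nd in nodes) {
    if (nd$min > nd$max) stop_ehrest("bad_request", sprintf("constraint at '%s': min > max", nd$path))
    if (!is.null(nd$range) && nd$range[1] > nd$range[2]) {
      stop_ehrest("bad_request", sprintf("constraint at '%s': range lower > upper", nd$path))
    }
  }
  structure(list(id = id, kind = kind, root = root, nodes = nodes, bases = bases),
            class = "constraint_doc")
}

#' @rdname constraint_doc
#' @param path Path string addressing the constrained node, relative to the
#'   document root.
#' @param min,max Occurrence bounds; `max = Inf` means unbounded.
#' @param value_kind Optional leaf kind (`"quantity"`, `"coded_text"`,
#'   `"text"`, `"timestamp"`).
#' @param range Optional `c(lower, upper)` bound on quantity magnitudes.
#' @param allowed_codes Optional character vector of allowed codes.
#' @param default Optional default leaf value used by [build_skeleton()].
#' @param units Optional required units string for quantities.
#' @export
constraint_node <- function(path, min = 0L, max = 1L, value_kind = NULL,
                            range = NULL, allowed_codes = NULL,
                            default = NULL, units = NULL) {
  list(path = path, min = as.integer(min),
       max = if (is.infinite(max)) Inf else as.integer(max),
       value_kind = value_kind, range = range,
       allowed_codes = allowed_codes, default = default, units = units)
}

#' @export
print.constraint_doc <- function(x, ...) {
  cat(sprintf("<constraint_doc> %s (%s), %d constrained paths\n",
              x$id, x$kind, length(x$nodes)))
  invisible(x)
}

#' Read / write constraint documents as JSON files
#' @param path File path.
#' @return `read_constraint_doc()`: a `constraint_doc`.
#' @export
read_constraint_doc <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  constraint_doc(
    id = x$id, kind = x$kind, root = x$root,
    nodes = lapply(x$nodes, function(nd) {
      constraint_node(
        path = nd$path, min = nd$min,
        max = if (identical(nd$max, "unbounded")) Inf else nd$max,
        value_kind = nd$value_kind %||% NULL,
        range = if (!is.null(nd$range)) c(nd$range$lower, nd$range$upper) else NULL,
        allowed_codes = if (!is.null(nd$allowed_codes)) unlist(nd$allowed_codes) else NULL,
        default = nd$default %||% NULL,
        units = nd$units %||% NULL
      )
    }),
    bases = unlist(x$bases %||% list()) %||% character(0)
  )
}

#' @rdname read_constraint_doc
#' @param doc A `constraint_doc`.
#' @export
write_constraint_doc <- function(doc, path) {
  nodes <- lapply(doc$nodes, function(nd) {
    out <- list(path = nd$path, min = nd$min,
                max = if (is.infinite(nd$max)) "unbounded" else nd$max)
    if (!is.null(nd$value_kind)) out$value_kind <- nd$value_kind
    if (!is.null(nd$range)) out$range <- list(lower = nd$range[1], upper = nd$range[2])
    if (!is.null(nd$allowed_codes)) out$allowed_codes <- as.list(nd$allowed_codes)
    if (!is.null(nd$default)) out$default <- nd$default
    if (!is.null(nd$units)) out$units <- nd$units
    out
  })
  x <- list(id = doc$id, kind = doc$kind, root = doc$root, nodes = nodes,
            bases = as.list(doc$bases))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)), path)
  invisible(path)
}

# ---- reports ----------------------------------------------------------------

validation_report <- function(findings = list(), archetype_ids = character(0)) {
  structure(list(overall = if (length(findings) == 0L) "valid" else "invalid",
                 findings = findings, archetype_ids = archetype_ids),
            class = "validation_report")
}

finding <- function(path, level, message) list(path = path, level = level, message = message)

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%d finding%s)\n", x$overall,
              length(x$findings), if (length(x$findings) == 1L) "" else "s"))
  for (f in x$findings) cat(sprintf("  [%s] %s: %s\n", f$level, f$path, f$message))
  invisible(x)
}

#' Is a report valid?
#' @param report A `validation_report`.
#' @export
is_valid <- function(report) identical(report$overall, "valid")

# node ids that look like archetype ids (as opposed to local at-codes)
archetype_id_pattern <- "\\.v[0-9]+$"

collect_archetype_ids <- function(node) {
  ids <- character(0)
  walk <- function(nd) {
    if (!is.null(nd$node_id) && grepl(archetype_id_pattern, nd$node_id)) {
      ids <<- c(ids, nd$node_id)
    }
    for (ch in nd$children) walk(ch)
  }
  walk(node)
  unique(ids)
}

# ---- level 1: RM conformance ------------------------------------------------

#' Validate reference-model conformance of a document tree
#'
#' Checks structural well-formedness: non-empty attribute names, the
#' children-xor-leaf rule, and leaf typing (numeric finite magnitudes,
#' complete code phrases, parseable timestamps). Problems are reported as
#' findings, never thrown.
#'
#' @param doc An `rm_node` (or anything else, which yields a finding).
#' @return A `validation_report`; its `archetype_ids` field lists the
#'   archetype ids present in the document (forwarded to commit triggers).
#' @export
validate_rm <- function(doc) {
  findings <- list()
  add <- function(path, msg) findings[[length(findings) + 1L]] <<- finding(path, "rm", msg)
  if (!inherits(doc, "rm_node")) {
    return(validation_report(list(finding("", "rm", "document is not an rm_node tree"))))
  }
  walk <- function(nd, path) {
    here <- paste0(path, "/", nd$name, if (!is.null(nd$node_id)) paste0("[", nd$node_id, "]") else "")
    if (!is_string(nd$name) || !nzchar(nd$name)) add(here, "empty attribute name")
    if (length(nd$children) > 0L && !is.null(nd$value)) {
      add(here, "node has both children and a leaf value")
    }
    v <- nd$value
    if (!is.null(v)) {
      if (is.null(v$type) || !v$type %in% c("quantity", "coded_text", "text", "timestamp")) {
        add(here, sprintf("unknown leaf type '%s'", v$type %||% "<missing>"))
      } else if (v$type == "quantity") {
        if (!is.numeric(v$magnitude) || length(v$magnitude) != 1L || !is.finite(v$magnitude)) {
          add(here, "quantity magnitude is not a finite number")
        }
        if (!is_string(v$units)) add(here, "quantity lacks units")
      } else if (v$type == "coded_text") {
        if (!is_string(v$code) || !nzchar(v$code)) add(here, "coded_text lacks a code")
        if (!is_string(v$terminology) || !nzchar(v$terminology)) add(here, "coded_text lacks a terminology")
      } else if (v$type == "timestamp") {
        ok <- tryCatch({ parse_ehr_time(v$value); TRUE }, error = function(e) FALSE)
        if (!ok) add(here, sprintf("unparseable timestamp '%s'", v$value))
      }
    }
    for (ch in nd$children) {
      if (inherits(ch, "rm_node")) walk(ch, here) else add(here, "child is not an rm_node")
    }
  }
  walk(doc, "")
  validation_report(findings, archetype_ids = collect_archetype_ids(doc))
}

# ---- levels 2/3: constraint validation --------------------------------------

#' Validate a document against a constraint document
#'
#' Occurrence counts, leaf kinds, magnitude ranges, code sets and units are
#' checked for every constrained path. Findings are tagged with the
#' constraint document's level (`archetype` or `template`), so a document
#' valid under an archetype but violating a narrower template yields
#' template-level findings only.
#'
#' @param doc An `rm_node`.
#' @param constraints A `constraint_doc`.
#' @return A `validation_report`.
#' @export
validate_against <- function(doc, constraints) {
  findings <- list()
  level <- constraints$kind
  add <- function(path, msg) findings[[length(findings) + 1L]] <<- finding(path, level, msg)
  if (!is.null(constraints$root$node_id) &&
      !identical(doc$node_id, constraints$root$node_id)) {
    add("", sprintf("root node id '%s' does not match constrained root '%s'",
                    doc$node_id %||% "<none>", constraints$root$node_id))
  }
  for (cn in constraints$nodes) {
    nodes <- resolve_path(doc, cn$path)
    k <- length(nodes)
    if (k < cn$min) add(cn$path, sprintf("occurrences %d below minimum %d", k, cn$min))
    if (is.finite(cn$max) && k > cn$max) add(cn$path, sprintf("occurrences %d above maximum %s", k, cn$max))
    if (!is.null(cn$value_kind)) {
      for (nd in nodes) {
        v <- nd$value
        if (is.null(v)) { add(cn$path, sprintf("expected a %s leaf, found none", cn$value_kind)); next }
        if (!identical(v$type, cn$value_kind)) {
          add(cn$path, sprintf("leaf type '%s' where '%s' required", v$type, cn$value_kind)); next
        }
        if (!is.null(cn$range) && identical(v$type, "quantity")) {
          if (v$magnitude < cn$range[1] || v$magnitude > cn$range[2]) {
            add(cn$path, sprintf("magnitude %s outside range [%s, %s]",
                                 format_num(v$magnitude), format_num(cn$range[1]), format_num(cn$range[2])))
          }
        }
        if (!is.null(cn$units) && identical(v$type, "quantity") && !identical(v$units, cn$units)) {
          add(cn$path, sprintf("units '%s' where '%s' required", v$units, cn$units))
        }
        if (!is.null(cn$allowed_codes) && identical(v$type, "coded_text") &&
            !(v$code %in% cn$allowed_codes)) {
          add(cn$path, sprintf("code '%s' not in allowed set", v$code))
        }
      }
    }
  }
  validation_report(findings, archetype_ids = collect_archetype_ids(doc))
}

#' Verify that a template only narrows its base archetype
#'
#' Templates may tighten occurrence bounds, ranges and code sets but never
#' relax them, remove mandatory fields, or constrain paths absent from the
#' base.
#'
#' @param template,archetype `constraint_doc`s.
#' @return Character vector of violations (empty when the template narrows).
#' @export
verify_narrowing <- function(template, archetype) {
  problems <- character(0)
  base_by_path <- stats::setNames(archetype$nodes,
                                  vapply(archetype$nodes, `[[`, character(1), "path"))
  for (tn in template$nodes) {
    bn <- base_by_path[[tn$path]]
    if (is.null(bn)) { problems <- c(problems, sprintf("template adds new path '%s'", tn$path)); next }
    if (tn$min < bn$min) problems <- c(problems, sprintf("'%s': template relaxes min %d -> %d", tn$path, bn$min, tn$min))
    if (tn$max > bn$max) problems <- c(problems, sprintf("'%s': template relaxes max", tn$path))
    if (!is.null(bn$range)) {
      if (is.null(tn$range) || tn$range[1] < bn$range[1] || tn$range[2] > bn$range[2]) {
        problems <- c(problems, sprintf("'%s': template widens range", tn$path))
      }
    }
    if (!is.null(bn$allowed_codes) &&
        (!is.null(tn$allowed_codes) && !all(tn$allowed_codes %in% bn$allowed_codes))) {
      problems <- c(problems, sprintf("'%s': template widens code set", tn$path))
    }
  }
  mandatory_paths <- vapply(Filter(function(n) n$min >= 1L, archetype$nodes), `[[`, character(1), "path")
  t_paths <- vapply(template$nodes, `[[`, character(1), "path")
  missing <- setdiff(mandatory_paths, t_paths)
  if (length(missing) > 0L) {
    problems <- c(problems, sprintf("template drops mandatory path '%s'", missing))
  }
  problems
}

# ---- skeleton generation ----------------------------------------------------

#' Generate a valid instance skeleton from constraints
#'
#' The minimum strategy populates only nodes with `min >= 1`; the maximum
#' strategy populates every constrained node at its occurrence maximum
#' (unbounded maxima are taken as 1). Leaves take the constraint's default
#' when one exists; otherwise range-constrained quantities get the range
#' midpoint, coded leaves the first allowed code, text/timestamp leaves fixed
#' placeholder values. The result always validates against its own
#' constraint document.
#'
#' @param constraints A `constraint_doc`.
#' @param strategy `"min"` or `"max"`.
#' @return An `rm_node`.
#' @export
build_skeleton <- function(constraints, strategy = c("min", "max")) {
  strategy <- match.arg(strategy)
  root <- rm_node(constraints$root$name, node_id = constraints$root$node_id %||% NULL)
  # mutable tree under construction: use nested environments? Simpler:
  # rebuild functionally -- insert() returns the modified tree.
  insert_chain <- function(node, segs, count, leaf) {
    if (length(segs) == 0L) return(node)
    seg <- segs[[1]]
    idx <- which(vapply(node$children, function(ch) {
      ch$name == seg$attribute_name &&
        (is.null(seg$predicate) || identical(ch$node_id, seg$predicate))
    }, logical(1)))
    if (length(segs) == 1L) {
      have <- length(idx)
      for (i in seq_len(max(0L, count - have))) {
        node$children[[length(node$children) + 1L]] <-
          rm_node(seg$attribute_name, node_id = seg$predicate, value = leaf)
      }
      if (!is.null(leaf) && have > 0L) {
        for (j in idx) {
          if (is.null(node$children[[j]]$value) && length(node$children[[j]]$children) == 0L) {
            node$children[[j]]$value <- leaf
          }
        }
      }
      return(node)
    }
    if (length(idx) == 0L) {
      node$children[[length(node$children) + 1L]] <-
        rm_node(seg$attribute_name, node_id = seg$predicate)
      idx <- length(node$children)
    }
    node$children[[idx[1]]] <- insert_chain(node$children[[idx[1]]], segs[-1], count, leaf)
    node
  }
  leaf_for <- function(cn) {
    if (is.null(cn$value_kind)) return(NULL)
    if (!is.null(cn$default)) {
      d <- cn$default
      return(switch(cn$value_kind,
        quantity   = leaf_quantity(as.numeric(d), cn$units %||% ""),
        coded_text = leaf_coded_text(as.character(d), "local", as.character(d)),
        text       = leaf_text(d),
        timestamp  = leaf_timestamp(d)))
    }
    switch(cn$value_kind,
      quantity = {
        m <- if (!is.null(cn$range)) (cn$range[1] + cn$range[2]) / 2 else 0
        leaf_quantity(m, cn$units %||% "")
      },
      coded_text = {
        code <- if (!is.null(cn$allowed_codes)) cn$allowed_codes[1] else "at0000"
        leaf_coded_text(code, "local", code)
      },
      text      = leaf_text("text"),
      timestamp = leaf_timestamp("2005-01-01T00:00:00")
    )
  }
  # parents before children so container nodes exist when leaves arrive
  ord <- order(vapply(constraints$nodes, function(cn) length(parse_rm_path(cn$path)$segments), integer(1)))
  for (cn in constraints$nodes[ord]) {
    count <- if (strategy == "min") cn$min else if (is.finite(cn$max)) as.integer(cn$max) else max(1L, cn$min)
    if (count == 0L) next
    segs <- parse_rm_path(cn$path)$segments
    root <- insert_chain(root, segs, count, leaf_for(cn))
  }
  rep <- validate_against(root, constraints)
  if (!is_valid(rep)) {
    stop_ehrest("bad_request", paste("unsatisfiable constraints:",
                paste(vapply(rep$findings, `[[`, character(1), "message"), collapse = "; ")))
  }
  root
}

# ---- combined validator (used by the store and the builder) ------------------

#' Build a validator from a set of constraint documents
#'
#' Returns a function suitable for [version_store()]'s `validator` argument:
#' given a document it runs RM validation plus every shipped constraint
#' document whose id appears in the document (templates are matched via their
#' base archetypes). The report's `archetype_ids` is the list the commit
#' forwards to trigger messages.
#'
#' @param docs List of `constraint_doc`s.
#' @return `function(doc) -> validation_report`.
#' @export
make_validator <- function(docs = list()) {
  function(doc) {
    rep <- validate_rm(doc)
    findings <- rep$findings
    ids <- rep$archetype_ids
    used_templates <- character(0)
    if (length(findings) == 0L) {
      for (cd in docs) {
        applies <- if (cd$kind == "archetype") cd$id %in% ids else
          (cd$id %in% ids || any(cd$bases %in% ids))
        if (!applies) next
        r2 <- validate_against(doc, cd)
        findings <- c(findings, r2$findings)
        if (cd$kind == "template") used_templates <- c(used_templates, cd$id)
      }
    }
    out <- validation_report(findings, archetype_ids = ids)
    out$template_ids <- unique(used_templates)
    out
  }
}
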