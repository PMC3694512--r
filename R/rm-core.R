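#' @title Reference-model core: identifiers, document trees and paths
#' @description
#' The building blocks shared by every other component: version identifiers
#' (`object_id::creating_system_id::version_tree_id`), compositions as labelled
#' node trees, and path addressing over those trees. The dialect is a
#' deliberately small stand-in for the full openEHR reference model: a node has
#' an attribute name, an optional archetype/node id, and either ordered
#' children or one typed leaf value.
#' @name rm_core
NULL

# ---- version identifiers ----------------------------------------------------

#' Parse a version identifier
#'
#' A version uid has the canonical form
#' `object_id::creating_system_id::version_tree_id`, e.g.
#' `"56d03821-8e89-cca769b7d39e::test2.eee.mi.imt.liu.se::1"`. The version tree
#' id is a dotted sequence of positive integers; trunk versions are `"1"`,
#' `"2"`, ... and branch ids such as `"1.2.1"` parse but are never minted here.
#'
#' @param s A single string.
#' @return A `version_uid` object with fields `object_id`,
#'   `creating_system_id` and `version_tree_id`.
#' @examples
#' u <- parse_version_uid("56d03821-8e89-cca769b7d39e::test2.eee.mi.imt.liu.se::1")
#' u$version_tree_id
#' format(u)
#' @export
parse_version_uid <- function(s) {
  if (!is_string(s) || !nzchar(s)) stop_ehrest("parse_error", "version uid must be a non-empty string")
  parts <- strsplit(s, "::", fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts))) {
    stop_ehrest("parse_error", sprintf("malformed version uid '%s': need object_id::creating_system_id::version_tree_id", s))
  }
  if (!grepl("^[1-9][0-9]*(\\.[1-9][0-9]*)*$", parts[3])) {
    stop_ehrest("parse_error", sprintf("malformed version tree id '%s': segments must be positive integers", parts[3]))
  }
  version_uid(parts[1], parts[2], parts[3])
}

#' Construct a version uid from its components
#' @param object_id,creating_system_id,version_tree_id Component strings.
#' @return A `version_uid` object.
#' @export
version_uid <- function(object_id, creating_system_id, version_tree_id) {
  structure(
    list(object_id = object_id, creating_system_id = creating_system_id,
         version_tree_id = version_tree_id),
    class = "version_uid"
  )
}

#' @export
format.version_uid <- function(x, ...) {
  paste(x$object_id, x$creating_system_id, x$version_tree_id, sep = "::")
}

#' @export
print.version_uid <- function(x, ...) {
  cat("<version_uid> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.version_uid <- function(x, ...) format(x)

uid_chr <- function(u) if (inherits(u, "version_uid")) format(u) else u

# Compare dotted tree ids segment-by-segment (numeric within segment).
compare_tree_ids <- function(a, b) {
  sa <- as.integer(strsplit(a, ".", fixed = TRUE)[[1]])
  sb <- as.integer(strsplit(b, ".", fixed = TRUE)[[1]])
  n <- max(length(sa), length(sb))
  for (i in seq_len(n)) {
    va <- if (i <= length(sa)) sa[i] else 0L
    vb <- if (i <= length(sb)) sb[i] else 0L
    if (va != vb) return(sign(va - vb))
  }
  0L
}

# ---- paths ------------------------------------------------------------------

#' Parse a document path
#'
#' Paths address nodes inside a composition tree, in the form
#' `/attr[predicate]/attr/...`. Predicates are opaque tokens (archetype ids at
#' archetyped subtree roots, node ids elsewhere) matched by string equality.
#' The empty string is the root path; a trailing `/` is equivalent to none.
#'
#' @param s A string starting with `/`, or `""` for the root.
#' @return An `rm_path`: a list of segments, each with `attribute_name` and an
#'   optional `predicate`.
#' @examples
#' p <- parse_rm_path("/content[openEHR-EHR-SECTION.vital_signs.v1]/items/data/")
#' length(p$segments)
#' @export
parse_rm_path <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop_ehrest("parse_error", "path must be a single string")
  }
  if (s == "" || s == "/") return(rm_path(list()))
  if (!startsWith(s, "/")) stop_ehrest("parse_error", sprintf("path '%s' must start with '/'", s))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  segs <- list()
  i <- 2L  # skip leading '/'
  n <- length(chars)
  buf_name <- character(0); buf_pred <- NULL; in_pred <- FALSE
  flush_seg <- function() {
    name <- paste(buf_name, collapse = "")
    if (!nzchar(name)) stop_ehrest("parse_error", sprintf("empty attribute name in path '%s'", s))
    segs[[length(segs) + 1L]] <<- list(attribute_name = name, predicate = buf_pred)
    buf_name <<- character(0); buf_pred <<- NULL
  }
  while (i <= n) {
    ch <- chars[i]
    if (in_pred) {
      if (ch == "]") { in_pred <- FALSE }
      else if (ch == "[") stop_ehrest("parse_error", sprintf("nested '[' in path '%s'", s))
      else buf_pred <- paste0(buf_pred %||% "", ch)
    } else if (ch == "[") {
      if (!is.null(buf_pred)) stop_ehrest("parse_error", sprintf("two predicates on one segment in '%s'", s))
      in_pred <- TRUE; buf_pred <- ""
    } else if (ch == "]") {
      stop_ehrest("parse_error", sprintf("unbalanced ']' in path '%s'", s))
    } else if (ch == "/") {
      flush_seg()
    } else {
      buf_name <- c(buf_name, ch)
    }
    i <- i + 1L
  }
  if (in_pred) stop_ehrest("parse_error", sprintf("unbalanced '[' in path '%s'", s))
  if (length(buf_name) > 0L || !is.null(buf_pred)) flush_seg()
  rm_path(segs)
}

#' Construct a path from segments
#' @param segments List of `list(attribute_name=, predicate=)`.
#' @return An `rm_path` object.
#' @export
rm_path <- function(segments = list()) {
  structure(list(segments = segments), class = "rm_path")
}

#' @export
format.rm_path <- function(x, ...) {
  if (length(x$segments) == 0L) return("")
  paste0("/", paste(vapply(x$segments, function(sg) {
    if (is.null(sg$predicate)) sg$attribute_name
    else paste0(sg$attribute_name, "[", sg$predicate, "]")
  }, character(1)), collapse = "/"))
}

#' @export
print.rm_path <- function(x, ...) {
  cat("<rm_path> ", if (length(x$segments) == 0L) "(root)" else format(x), "\n", sep = "")
  invisible(x)
}

as_rm_path <- function(p) if (inherits(p, "rm_path")) p else parse_rm_path(p)

# ---- node trees -------------------------------------------------------------

#' Construct a document-tree node
#'
#' A node carries an attribute name, an optional archetype/node id, and either
#' ordered children or a single typed leaf value -- never both. Compositions
#' are simply the roots of such trees. Document order of children is
#' significant and preserved through all serializations.
#'
#' @param name Attribute name (non-empty string).
#' @param node_id Optional archetype id (at archetyped subtree roots) or node
#'   id; matched against path predicates by string equality.
#' @param children Ordered list of child `rm_node`s.
#' @param value Optional leaf value from [leaf_quantity()], [leaf_coded_text()],
#'   [leaf_text()] or [leaf_timestamp()].
#' @return An `rm_node`.
#' @examples
#' bp <- rm_node("value", children = list(), value = leaf_quantity(120, "mm[Hg]"))
#' bp$value$magnitude
#' @export
rm_node <- function(name, node_id = NULL, children = list(), value = NULL) {
  if (!is_string(name) || !nzchar(name)) stop_ehrest("bad_request", "node attribute name must be non-empty")
  if (length(children) > 0L && !is.null(value)) {
    stop_ehrest("bad_request", sprintf("node '%s' cannot have both children and a leaf value", name))
  }
  structure(list(name = name, node_id = node_id, children = children, value = value),
            class = "rm_node")
}

#' Leaf values for document-tree nodes
#'
#' Four leaf kinds are supported: physical quantities (magnitude + units),
#' coded text (code + terminology + human-readable label), plain text, and
#' ISO 8601 timestamps (zoneless values are read as UTC).
#'
#' @param magnitude Numeric magnitude.
#' @param units Units string (e.g. `"mm[Hg]"`).
#' @return A leaf value list with a `type` field.
#' @export
leaf_quantity <- function(magnitude, units) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L)
  list(type = "quantity", magnitude = as.numeric(magnitude), units = units)
}

#' @rdname leaf_quantity
#' @param code,terminology,label Code-phrase components.
#' @export
leaf_coded_text <- function(code, terminology, label = "") {
  list(type = "coded_text", code = code, terminology = terminology, label = label)
}

#' @rdname leaf_quantity
#' @param x Text or ISO 8601 timestamp string.
#' @export
leaf_text <- function(x) list(type = "text", value = as.character(x))

#' @rdname leaf_quantity
#' @export
leaf_timestamp <- function(x) list(type = "timestamp", value = as.character(x))

#' @export
print.rm_node <- function(x, ...) {
  show <- function(nd, depth) {
    pad <- strrep("  ", depth)
    id <- if (!is.null(nd$node_id)) paste0("[", nd$node_id, "]") else ""
    v <- if (!is.null(nd$value)) paste0(" = ", format_leaf(nd$value)) else ""
    cat(pad, nd$name, id, v, "\n", sep = "")
    for (ch in nd$children) show(ch, depth + 1L)
  }
  show(x, 0L)
  invisible(x)
}

format_leaf <- function(v) {
  switch(v$type,
    quantity   = sprintf("%s %s", format_num(v$magnitude), v$units),
    coded_text = sprintf("%s::%s (%s)", v$terminology, v$code, v$label),
    text       = v$value,
    timestamp  = v$value
  )
}

# Fixed-precision numeric formatting: 15 significant digits round-trips every
# value produced in this package and keeps serializations byte-deterministic.
format_num <- function(x) sprintf("%.15g", x)

n_nodes <- function(node) 1L + sum(vapply(node$children, n_nodes, integer(1)))

# ---- path resolution --------------------------------------------------------

#' Resolve a path against a document tree
#'
#' Walks the tree segment by segment: a segment matches a child whose
#' attribute name equals `attribute_name` and, when the segment carries a
#' predicate, whose node id equals it. Returns every matching node in
#' document order; the empty path resolves to the root. The input tree is
#' never mutated.
#'
#' @param root An `rm_node`.
#' @param path An `rm_path` or path string.
#' @return A list of `rm_node`s (possibly empty).
#' @export
resolve_path <- function(root, path) {
  path <- as_rm_path(path)
  current <- list(root)
  for (seg in path$segments) {
    nxt <- list()
    for (node in current) {
      for (ch in node$children) {
        if (ch$name == seg$attribute_name &&
            (is.null(seg$predicate) || identical(ch$node_id, seg$predicate))) {
          nxt[[length(nxt) + 1L]] <- ch
        }
      }
    }
    current <- nxt
    if (length(current) == 0L) break
  }
  current
}

# Leaf-field names addressable as a final path segment.
leaf_field_names <- c("magnitude", "units", "code", "terminology", "label", "value")

#' Extract scalar values addressed by a path
#'
#' Like [resolve_path()] but if the final segment names a field of a leaf
#' value (`magnitude`, `units`, `code`, `terminology`, `label`, `value`) the
#' matching leaves' field values are returned instead of nodes. Nodes whose
#' leaf lacks the field contribute nothing.
#'
#' @inheritParams resolve_path
#' @return A list of scalars (numeric or character) or leaf values.
#' @export
resolve_path_values <- function(root, path) {
  path <- as_rm_path(path)
  segs <- path$segments
  n <- length(segs)
  # First try: full path addresses nodes; their leaves are the values.
  nodes <- resolve_path(root, path)
  if (length(nodes) > 0L) {
    out <- list()
    for (nd in nodes) if (!is.null(nd$value)) out[[length(out) + 1L]] <- nd$value
    if (length(out) > 0L) return(out)
  }
  # Second try: last segment is a leaf field of the prefix nodes.
  if (n >= 1L && is.null(segs[[n]]$predicate) &&
      segs[[n]]$attribute_name %in% leaf_field_names) {
    prefix <- rm_path(segs[-n])
    field <- segs[[n]]$attribute_name
    out <- list()
    for (nd in resolve_path(root, prefix)) {
      if (!is.null(nd$value) && !is.null(nd$value[[field]])) {
        out[[length(out) + 1L]] <- nd$value[[field]]
      }
    }
    return(out)
  }
  list()
}

# ---- timestamps -------------------------------------------------------------

#' Parse an ISO 8601 timestamp (zoneless values read as UTC)
#' @param s Timestamp string, e.g. `"2005-08-02T04:30:00"`.
#' @return A `POSIXct` in UTC.
#' @export
parse_ehr_time <- function(s) {
  if (inherits(s, "POSIXct")) return(s)
  if (!is_string(s)) stop_ehrest("parse_error", "timestamp must be a string")
  s2 <- sub("Z$", "", s)
  s2 <- sub("T", " ", s2, fixed = TRUE)
  fmt <- if (grepl("\\.", s2)) "%Y-%m-%d %H:%M:%OS" else if (grepl(":", s2)) "%Y-%m-%d %H:%M:%S" else "%Y-%m-%d"
  t <- as.POSIXct(s2, tz = "UTC", format = fmt)
  if (is.na(t)) stop_ehrest("parse_error", sprintf("unparseable timestamp '%s'", s))
  t
}

format_ehr_time <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# ---- serialization: XML dialect --------------------------------------------

# Element name = attribute_name; node id and leaf payload are attributes:
#   vt  -- leaf type tag (quantity|coded_text|text|timestamp)
#   magnitude/units, code/terminology/label, v -- leaf fields
# This keeps every attribute name available as an element name and makes the
# round trip trivially lossless.

node_to_xml_node <- function(doc_parent, node) {
  el <- xml2::xml_add_child(doc_parent, node$name)
  if (!is.null(node$node_id)) xml2::xml_set_attr(el, "archetype_node_id", node$node_id)
  v <- node$value
  if (!is.null(v)) {
    xml2::xml_set_attr(el, "vt", v$type)
    if (v$type == "quantity") {
      xml2::xml_set_attr(el, "magnitude", format_num(v$magnitude))
      xml2::xml_set_attr(el, "units", v$units)
    } else if (v$type == "coded_text") {
      xml2::xml_set_attr(el, "code", v$code)
      xml2::xml_set_attr(el, "terminology", v$terminology)
      xml2::xml_set_attr(el, "label", v$label)
    } else {
      xml2::xml_set_attr(el, "v", v$value)
    }
  }
  for (ch in node$children) node_to_xml_node(el, ch)
  el
}

#' Serialize / parse a composition tree as XML
#'
#' Element names are attribute names; the node id and any leaf payload are
#' carried as XML attributes. `composition_from_xml()` accepts a string or an
#' `xml2` document. The round trip is lossless.
#'
#' @param node An `rm_node`.
#' @return `composition_to_xml()`: a single XML string.
#' @export
composition_to_xml <- function(node) {
  doc <- xml2::xml_new_root(node$name)
  root <- xml2::xml_root(doc)
  if (!is.null(node$node_id)) xml2::xml_set_attr(root, "archetype_node_id", node$node_id)
  v <- node$value
  if (!is.null(v)) {
    xml2::xml_set_attr(root, "vt", v$type)
    if (v$type == "quantity") {
      xml2::xml_set_attr(root, "magnitude", format_num(v$magnitude))
      xml2::xml_set_attr(root, "units", v$units)
    } else if (v$type == "coded_text") {
      xml2::xml_set_attr(root, "code", v$code)
      xml2::xml_set_attr(root, "terminology", v$terminology)
      xml2::xml_set_attr(root, "label", v$label)
    } else {
      xml2::xml_set_attr(root, "v", v$value)
    }
  }
  for (ch in node$children) node_to_xml_node(root, ch)
  as.character(doc)
}

xml_node_to_rm <- function(el) {
  attrs <- as.list(xml2::xml_attrs(el))
  vt <- attrs[["vt"]] %||% NULL
  value <- NULL
  if (!is.null(vt)) {
    value <- switch(vt,
      quantity   = leaf_quantity(as.numeric(attrs[["magnitude"]]), attrs[["units"]]),
      coded_text = leaf_coded_text(attrs[["code"]], attrs[["terminology"]], attrs[["label"]]),
      text       = leaf_text(attrs[["v"]]),
      timestamp  = leaf_timestamp(attrs[["v"]]),
      stop_ehrest("parse_error", sprintf("unknown leaf type '%s'", vt))
    )
  }
  kids <- xml2::xml_children(el)
  children <- lapply(seq_along(kids), function(i) xml_node_to_rm(kids[[i]]))
  rm_node(
    name = xml2::xml_name(el),
    node_id = if ("archetype_node_id" %in% names(attrs)) attrs[["archetype_node_id"]] else NULL,
    children = children,
    value = value
  )
}

#' @rdname composition_to_xml
#' @param x An XML string or `xml2` document.
#' @return `composition_from_xml()`: an `rm_node`.
#' @export
composition_from_xml <- function(x) {
  doc <- tryCatch(
    if (inherits(x, "xml_document")) x else xml2::read_xml(x),
    error = function(e) stop_ehrest("parse_error", paste("invalid XML:", conditionMessage(e)))
  )
  xml_node_to_rm(xml2::xml_root(doc))
}

# ---- serialization: JSON mirror ---------------------------------------------

node_to_list <- function(node) {
  out <- list(name = node$name)
  if (!is.null(node$node_id)) out$node_id <- node$node_id
  if (!is.null(node$value)) out$value <- node$value
  if (length(node$children) > 0L) out$children <- lapply(node$children, node_to_list)
  out
}

list_to_node <- function(x) {
  if (is.null(x$name)) stop_ehrest("parse_error", "JSON node lacks 'name'")
  value <- NULL
  if (!is.null(x$value)) {
    v <- x$value
    value <- switch(v$type %||% "",
      quantity   = leaf_quantity(as.numeric(v$magnitude), v$units),
      coded_text = leaf_coded_text(v$code, v$terminology, v$label %||% ""),
      text       = leaf_text(v$value),
      timestamp  = leaf_timestamp(v$value),
      stop_ehrest("parse_error", sprintf("unknown leaf type '%s'", v$type %||% "<missing>"))
    )
  }
  rm_node(
    name = x$name,
    node_id = x$node_id %||% NULL,
    children = lapply(x$children %||% list(), list_to_node),
    value = value
  )
}

#' Serialize / parse a composition tree as JSON
#'
#' JSON mirror of the XML dialect: objects with keys `name`, `node_id`,
#' `children` or `value`. The round trip is lossless.
#'
#' @param node An `rm_node`.
#' @return `composition_to_json()`: a single JSON string.
#' @export
composition_to_json <- function(node) {
  as.character(jsonlite::toJSON(node_to_list(node), auto_unbox = TRUE, digits = NA))
}

#' @rdname composition_to_json
#' @param x A JSON string.
#' @return `composition_from_json()`: an `rm_node`.
#' @export
composition_from_json <- function(x) {
  parsed <- tryCatch(jsonlite::fromJSON(x, simplifyVector = FALSE),
                     error = function(e) stop_ehrest("parse_error", paste("invalid JSON:", conditionMessage(e))))
  list_to_node(parsed)
}

# Sniff a document payload: XML if it starts with '<', else JSON.
parse_composition_payload <- function(text) {
  t <- sub("^\\s+", "", text)
  if (startsWith(t, "<")) composition_from_xml(text) else composition_from_json(text)
}

# ---- token minting ----------------------------------------------------------

hex_alphabet <- c(0:9, letters[1:6])

# Random hex token drawn from the session RNG, so callers control determinism
# with set.seed().
mint_hex <- function(n = 12L) {
  paste(sample(hex_alphabet, n, replace = TRUE), collapse = "")
}

mint_object_id <- function() {
  paste(mint_hex(8L), mint_hex(4L), mint_hex(12L), sep = "-")
}

valid_ehr_id <- function(x) {
  is_string(x) && nzchar(x) && !grepl("[/:@#]", x)
}
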