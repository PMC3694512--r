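#' @title Contribution builder: a temporary writing space
#'
#' @description
#' Writes never hit the shared store piecemeal: a committer assembles one or
#' more temporary versions in a private *contribution build* -- isolated per
#' committer and per record, the first build for each patient named
#' `"default"` -- validates them, and commits the whole build as a single
#' atomic contribution, after which the build is destroyed. Temporary
#' versions are created by six commands (`update-version`, `copy-version`,
#' `from-form`, `from-url`, `from-instance-template`, `from-ehr-path`); the
#' last three fetch a document over HTTP, are restricted to an allow-listed
#' host set, and send a fixed `Referer` of `{host}/static/restricted.txt` so
#' committer and record identifiers never leak to the fetched server.
#'
#' @name contribution_builder
NULL

builder_fetch_commands <- c("from-url", "from-instance-template", "from-ehr-path")
builder_commands <- c("update-version", "copy-version", "from-form", builder_fetch_commands)

# {{name}} placeholder substitution for from-instance-template. A tiny,
# engine-agnostic mechanism: every POSTed variable is in scope.
substitute_template <- function(text, vars) {
  for (nm in names(vars)) {
    text <- gsub(paste0("{{", nm, "}}"), as.character(vars[[nm]]), text, fixed = TRUE)
  }
  leftover <- regmatches(text, gregexpr("\\{\\{[^}]*\\}\\}", text))[[1]]
  if (length(leftover) > 0L) {
    stop_ehrest("bad_request", sprintf("unbound template variable(s): %s",
                                       paste(unique(leftover), collapse = ", ")))
  }
  text
}

# Replace leaf values addressed by path in a skeleton; returns the new tree.
# Unresolvable paths error, listing every offender.
replace_at_paths <- function(root, replacements) {
  missing <- character(0)
  for (pth in names(replacements)) {
    hits <- resolve_path(root, pth)
    if (length(hits) == 0L) missing <- c(missing, pth)
  }
  if (length(missing) > 0L) {
    stop_ehrest("bad_request", sprintf("substitution path(s) not found in skeleton: %s",
                                       paste(missing, collapse = ", ")))
  }
  apply_one <- function(node, segs, value) {
    if (length(segs) == 0L) {
      v <- node$value
      node$value <- if (!is.null(v) && identical(v$type, "quantity")) {
        leaf_quantity(as.numeric(value), v$units)
      } else if (!is.null(v) && identical(v$type, "coded_text")) {
        leaf_coded_text(as.character(value), v$terminology, as.character(value))
      } else if (!is.null(v) && identical(v$type, "timestamp")) {
        leaf_timestamp(as.character(value))
      } else {
        leaf_text(as.character(value))
      }
      return(node)
    }
    seg <- segs[[1]]
    for (k in seq_along(node$children)) {
      ch <- node$children[[k]]
      if (identical(ch$name, seg$attribute_name) &&
          (is.null(seg$predicate) || identical(ch$node_id, seg$predicate))) {
        node$children[[k]] <- apply_one(ch, segs[-1], value)
      }
    }
    node
  }
  for (pth in names(replacements)) {
    root <- apply_one(root, parse_rm_path(pth)$segments, replacements[[pth]])
  }
  root
}

#' Create a contribution-builder space
#'
#' @param store The deployment's `VersionStore`.
#' @param validator `function(rm_node) -> validation_report` used by
#'   `validate_build()` (see [make_validator()]); may be `NULL`.
#' @param fetcher `function(url, headers) -> character` performing outgoing
#'   GETs for the `from-url`-family commands. The default refuses everything;
#'   deployments supply a loopback fetcher for same-host URLs.
#' @param host Deployment hostname, used for the fixed `Referer` header and as
#'   the default allow-listed host.
#' @param allowed_hosts Hosts the fetch commands may contact.
#' @return A `BuilderSpace` R6 object.
#' @export
builder_space <- function(store, validator = NULL, fetcher = NULL,
                          host = "ehr.example.org", allowed_hosts = host) {
  BuilderSpace$new(store = store, validator = validator, fetcher = fetcher,
                   host = host, allowed_hosts = allowed_hosts)
}

#' @rdname builder_space
#' @export
BuilderSpace <- R6::R6Class("BuilderSpace",
  public = list(
    #' @description See [builder_space()].
    #' @param store,validator,fetcher,host,allowed_hosts See [builder_space()].
    initialize = function(store, validator = NULL, fetcher = NULL,
                          host = "ehr.example.org", allowed_hosts = host) {
      private$store <- store
      private$validator <- validator
      private$fetcher <- fetcher
      private$host <- host
      private$allowed_hosts <- allowed_hosts
      private$builds <- new.env(parent = emptyenv())
    },

    #' @description Create a new empty build. The first build for a
    #'   (committer, record) pair is named `"default"`; later ones take a name
    #'   derived from `description` or a generated one.
    #' @param committer_id Committer identity.
    #' @param ehr_id Record id (must exist).
    #' @param description Optional custom name.
    #' @return The build id (`cb_id`).
    create_build = function(committer_id, ehr_id, description = NULL) {
      if (!private$store$has_ehr(ehr_id)) {
        stop_ehrest("not_found", sprintf("no ehr '%s'", ehr_id))
      }
      existing <- self$list_builds(committer_id, ehr_id)
      cb_id <- if (length(existing) == 0L) "default"
      else if (!is.null(description) && nzchar(description)) {
        slug <- gsub("[^A-Za-z0-9]+", "-", trimws(description))
        base <- slug; k <- 1L
        while (base %in% existing) { k <- k + 1L; base <- paste0(slug, "-", k) }
        base
      } else paste0("cb-", length(existing) + 1L)
      key <- private$key(committer_id, ehr_id, cb_id)
      assign(key, list(committer_id = committer_id, ehr_id = ehr_id, cb_id = cb_id,
                       description = description %||% "", created = Sys.time(),
                       temp_versions = list(), counter = 0L),
             envir = private$builds)
      cb_id
    },

    #' @description Record ids with active builds for a committer, or build ids
    #'   for a (committer, record) pair. Builds are invisible to other
    #'   committers.
    #' @param committer_id Committer identity.
    #' @param ehr_id Optional record id.
    list_builds = function(committer_id, ehr_id = NULL) {
      keys <- ls(private$builds)
      out <- character(0)
      for (k in keys) {
        b <- get(k, envir = private$builds)
        if (!identical(b$committer_id, committer_id)) next
        if (is.null(ehr_id)) out <- c(out, b$ehr_id)
        else if (identical(b$ehr_id, ehr_id)) out <- c(out, b$cb_id)
      }
      sort(unique(out))
    },

    #' @description Fetch a build (error when absent -- also after commit,
    #'   which destroys the build).
    #' @param committer_id,ehr_id,cb_id Identifiers.
    get_build = function(committer_id, ehr_id, cb_id) {
      key <- private$key(committer_id, ehr_id, cb_id)
      if (!exists(key, envir = private$builds, inherits = FALSE)) {
        stop_ehrest("not_found", sprintf("no contribution build '%s' for %s on ehr '%s'",
                                         cb_id, committer_id, ehr_id))
      }
      get(key, envir = private$builds)
    },

    #' @description Create a temporary version in a build.
    #' @param committer_id,ehr_id,cb_id Build identifiers.
    #' @param command One of `update-version` (data copied from a live
    #'   version, committed as its amendment), `copy-version` (copied data,
    #'   committed as a new unrelated object), `from-form` (payload field
    #'   `data` holds the document), `from-url` (document fetched from payload
    #'   field `url`), `from-instance-template` (fetched document with
    #'   `{{name}}` placeholders bound from the payload), `from-ehr-path`
    #'   (fetched skeleton with payload fields named as paths replacing the
    #'   addressed leaves).
    #' @param payload Named list of command inputs / form fields.
    #' @return The new temp id.
    add_version = function(committer_id, ehr_id, cb_id, command, payload = list()) {
      if (!command %in% builder_commands) {
        stop_ehrest("bad_request", sprintf("unknown builder command '%s' (valid: %s)",
                                           command, paste(builder_commands, collapse = ", ")))
      }
      b <- self$get_build(committer_id, ehr_id, cb_id)
      lifecycle <- payload$lifecycle %||% "complete"
      intent <- list(kind = "new")
      data <- NULL
      if (command %in% c("update-version", "copy-version")) {
        uid <- payload$version_uid %||% stop_ehrest("bad_request", "payload field 'version_uid' required")
        uid <- if (inherits(uid, "version_uid")) uid else parse_version_uid(uid)
        v <- private$store$get_version(ehr_id, uid$object_id, uid)
        if (is.null(v$data)) stop_ehrest("bad_request", sprintf("version '%s' carries no data", format(uid)))
        data <- v$data
        if (command == "update-version") intent <- list(kind = "update_of", uid = v$uid)
      } else if (command == "from-form") {
        raw <- payload$data %||% stop_ehrest("bad_request", "form variable 'data' required")
        data <- if (inherits(raw, "rm_node")) raw else parse_composition_payload(raw)
      } else {
        url <- payload$url %||% stop_ehrest("bad_request", "form field 'url' required")
        text <- private$fetch(url)
        if (command == "from-instance-template") {
          vars <- payload[setdiff(names(payload), c("url", "lifecycle"))]
          text <- substitute_template(text, vars)
          data <- parse_composition_payload(text)
        } else if (command == "from-ehr-path") {
          skeleton <- parse_composition_payload(text)
          fields <- payload[startsWith(names(payload) %||% character(0), "/")]
          data <- replace_at_paths(skeleton, fields)
        } else {
          data <- parse_composition_payload(text)
        }
      }
      b$counter <- b$counter + 1L
      temp_id <- paste0("t", b$counter)
      b$temp_versions[[temp_id]] <- list(temp_id = temp_id, intent = intent,
                                         lifecycle = lifecycle, data = data)
      private$put(b)
      temp_id
    },

    #' @description Replace a temporary version's data wholesale. A malformed
    #'   document leaves the previous data intact.
    #' @param committer_id,ehr_id,cb_id,temp_id Identifiers.
    #' @param document An `rm_node`, or XML/JSON text.
    put_data = function(committer_id, ehr_id, cb_id, temp_id, document) {
      b <- self$get_build(committer_id, ehr_id, cb_id)
      tv <- b$temp_versions[[temp_id]]
      if (is.null(tv)) stop_ehrest("not_found", sprintf("no temp version '%s'", temp_id))
      data <- if (inherits(document, "rm_node")) document else parse_composition_payload(document)
      tv$data <- data
      b$temp_versions[[temp_id]] <- tv
      private$put(b)
      invisible(temp_id)
    },

    #' @description Serialize a temporary version's data.
    #' @param committer_id,ehr_id,cb_id,temp_id Identifiers.
    #' @param media `"xml"`, `"json"`, or `"html"` (a minimal editing view
    #'   embedding the XML in a form).
    get_data = function(committer_id, ehr_id, cb_id, temp_id, media = "xml") {
      b <- self$get_build(committer_id, ehr_id, cb_id)
      tv <- b$temp_versions[[temp_id]]
      if (is.null(tv)) stop_ehrest("not_found", sprintf("no temp version '%s'", temp_id))
      switch(media,
        xml  = composition_to_xml(tv$data),
        json = composition_to_json(tv$data),
        html = paste0(
          "<html><body><h1>Edit ", temp_id, "</h1>",
          "<form method=\"post\" action=\"data/\"><textarea name=\"data\">",
          xml_escape(composition_to_xml(tv$data)),
          "</textarea><input type=\"submit\" value=\"Save\"/></form></body></html>"),
        stop_ehrest("not_acceptable", sprintf("no representation '%s'", media)))
    },

    #' @description Delete a temporary version from a build.
    #' @param committer_id,ehr_id,cb_id,temp_id Identifiers.
    delete_version = function(committer_id, ehr_id, cb_id, temp_id) {
      b <- self$get_build(committer_id, ehr_id, cb_id)
      if (is.null(b$temp_versions[[temp_id]])) {
        stop_ehrest("not_found", sprintf("no temp version '%s'", temp_id))
      }
      b$temp_versions[[temp_id]] <- NULL
      private$put(b)
      invisible(NULL)
    },

    #' @description Validate every temporary version in a build (the build is
    #'   unchanged). The report's archetype-id list is what a later commit
    #'   forwards to trigger messages.
    #' @param committer_id,ehr_id,cb_id Identifiers.
    #' @return `list(overall=, by_temp_id=, archetype_ids=)`.
    validate_build = function(committer_id, ehr_id, cb_id) {
      b <- self$get_build(committer_id, ehr_id, cb_id)
      by_id <- list(); all_ids <- character(0); ok <- TRUE
      for (tid in names(b$temp_versions)) {
        tv <- b$temp_versions[[tid]]
        rep <- if (!is.null(private$validator)) private$validator(tv$data) else validate_rm(tv$data)
        by_id[[tid]] <- rep
        all_ids <- c(all_ids, rep$archetype_ids)
        if (!is_valid(rep)) ok <- FALSE
      }
      list(overall = if (ok) "valid" else "invalid", by_temp_id = by_id,
           archetype_ids = unique(all_ids))
    },

    #' @description Commit the entire build as one contribution, then destroy
    #'   the build. Validation failure or a stale update target leaves both the
    #'   build and the store untouched.
    #' @param committer_id,ehr_id,cb_id Identifiers.
    #' @param description Contribution description.
    #' @param commit_time Optional `POSIXct`.
    #' @return The committed `contribution`.
    commit_build = function(committer_id, ehr_id, cb_id, description = NULL,
                            commit_time = NULL) {
      b <- self$get_build(committer_id, ehr_id, cb_id)
      if (length(b$temp_versions) == 0L) {
        stop_ehrest("bad_request", "cannot commit an empty contribution build")
      }
      rep <- self$validate_build(committer_id, ehr_id, cb_id)
      if (!identical(rep$overall, "valid")) {
        bad <- names(Filter(function(r) !is_valid(r), rep$by_temp_id))
        stop_ehrest("validation_error", sprintf("build '%s' does not validate (temp versions: %s)",
                                                cb_id, paste(bad, collapse = ", ")))
      }
      specs <- lapply(b$temp_versions, function(tv) {
        if (identical(tv$intent$kind, "update_of")) {
          list(change_type = "amendment", preceding_uid = tv$intent$uid,
               lifecycle = tv$lifecycle, data = tv$data)
        } else {
          list(change_type = "creation", lifecycle = tv$lifecycle, data = tv$data)
        }
      })
      names(specs) <- NULL
      contribution <- private$store$commit_contribution(
        ehr_id, specs,
        audit = list(committer_id = committer_id,
                     description = description %||% b$description),
        commit_time = commit_time
      )
      rm(list = private$key(committer_id, ehr_id, cb_id), envir = private$builds)
      contribution
    },

    #' @description Print a summary.
    print = function() {
      cat(sprintf("<BuilderSpace> %d active build(s)\n", length(ls(private$builds))))
      invisible(self)
    }
  ),
  private = list(
    store = NULL, validator = NULL, fetcher = NULL, host = NULL,
    allowed_hosts = NULL, builds = NULL,
    key = function(committer_id, ehr_id, cb_id) paste(committer_id, ehr_id, cb_id, sep = "\r"),
    put = function(b) assign(private$key(b$committer_id, b$ehr_id, b$cb_id), b, envir = private$builds),
    fetch = function(url) {
      if (is.null(private$fetcher)) {
        stop_ehrest("bad_request", "no outgoing fetcher configured for from-url commands")
      }
      host <- if (grepl("^[a-z]+://", url)) {
        sub("^[a-z]+://([^/]+).*$", "\\1", url)
      } else private$host  # relative URLs are same-host
      if (!host %in% private$allowed_hosts) {
        stop_ehrest("bad_request", sprintf("host '%s' is not on the fetch allow list", host))
      }
      # fixed Referer: never the builder URI, which would leak committer and
      # record identifiers to the fetched server
      referer <- paste0(private$host, "/static/restricted.txt")
      private$fetcher(url, headers = list(Referer = referer))
    }
  )
)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
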