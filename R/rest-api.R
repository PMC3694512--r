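#' @title HTTP facade: routing, negotiation, caching, conditionals, logging
#'
#' @description
#' `EhrServer` wires every component behind the published URI grammar and
#' exposes a single pure entry point, `dispatch(method, uri, headers, body)`,
#' returning `list(status, headers, body)`. Routes cover direct version
#' access (`/ehr:{ehr_id}/{object_id}::{system}::{tree}` plus sub-paths),
#' version lookup commands (`@latest_version`, `@{timestamp}`), contribution
#' listing/commit, the query store-and-redirect protocol, the contribution
#' builder, bookmarks and static resources, each with the `/multi/` read
#' variant served from a configured replica. Cache headers follow three
#' resource classes: immutable versions (`Cache-Control: private` + high
#' max-age, no ETag), public statics (`Cache-Control: public` + high
#' max-age), and mutable record views (ETag = latest contribution id,
#' Last-Modified = its commit time), with `If-None-Match` answered 304
#' without touching the store and stale `If-Match` writes refused with 412.
#' Every request appends one NCSA-style access-log line carrying the
#' committer identity, so reads and query runs are reconstructible from the
#' log alone.
#'
#' @name rest_api
NULL

url_decode <- function(x) utils::URLdecode(chartr("+", " ", x))

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  out <- list()
  for (pair in strsplit(qs, "&", fixed = TRUE)[[1]]) {
    kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
    if (length(kv) == 0L || !nzchar(kv[1])) next
    out[[url_decode(kv[1])]] <- if (length(kv) > 1L) url_decode(paste(kv[-1], collapse = "=")) else ""
  }
  out
}

parse_form_body <- function(body, content_type = NULL) {
  if (is.null(body)) return(list())
  if (is.list(body)) return(body)
  ct <- content_type %||% ""
  if (grepl("json", ct, fixed = TRUE) || grepl("^\\s*[{\\[]", body)) {
    return(jsonlite::fromJSON(body, simplifyVector = FALSE))
  }
  parse_query_string(body)
}

http_date <- function(t) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  format(as.POSIXct(trunc(t, "secs")), "%a, %d %b %Y %H:%M:%S GMT", tz = "GMT")
}

#' Content negotiation
#'
#' Standard semantics over a small media set: the `Accept` header's types are
#' tried in listed order (with `*/*` and `type/*` wildcards); an absent header
#' yields the configured default (XML). No acceptable type is a 406.
#'
#' @param accept The `Accept` header value or `NULL`.
#' @param available Character vector of offered media types, first = default.
#' @return One element of `available`.
#' @export
negotiate_media <- function(accept, available = c("application/xml", "application/json")) {
  if (is.null(accept) || !nzchar(accept)) return(available[1])
  wanted <- trimws(vapply(strsplit(accept, ",", fixed = TRUE)[[1]],
                          function(p) strsplit(p, ";", fixed = TRUE)[[1]][1], character(1)))
  for (w in wanted) {
    if (w == "*/*") return(available[1])
    if (w %in% available) return(w)
    if (grepl("/\\*$", w)) {
      major <- sub("/\\*$", "", w)
      hit <- available[startsWith(available, paste0(major, "/"))]
      if (length(hit) > 0L) return(hit[1])
    }
  }
  stop_ehrest("not_acceptable", sprintf("no acceptable representation among: %s",
                                        paste(available, collapse = ", ")))
}

#' Cache headers for a resource class
#'
#' @param class `"immutable_version"` (private + high max-age, no ETag: a
#'   stored version never changes, so update checking is irrelevant),
#'   `"static_public"` (public + high max-age), or `"mutable_ehr_view"`
#'   (ETag = quoted latest contribution id for the whole record,
#'   Last-Modified = its commit time truncated to seconds).
#' @param metadata The record's metadata entry (required for mutable views).
#' @param config List with `max_age_immutable` and `max_age_static` seconds.
#' @return Named character vector of headers.
#' @export
cache_headers_for <- function(class, metadata = NULL,
                              config = list(max_age_immutable = 31536000L,
                                            max_age_static = 604800L)) {
  switch(class,
    immutable_version = c("Cache-Control" = sprintf("private, max-age=%d", config$max_age_immutable)),
    static_public = c("Cache-Control" = sprintf("public, max-age=%d", config$max_age_static)),
    mutable_ehr_view = {
      if (is.null(metadata)) stop_ehrest("internal", "mutable view requires record metadata")
      c("ETag" = paste0("\"", metadata$last_contribution_id, "\""),
        "Last-Modified" = http_date(metadata$last_modified),
        "Cache-Control" = "private")
    },
    stop_ehrest("internal", sprintf("unknown cache class '%s'", class))
  )
}

version_to_xml <- function(v, ehr_id) {
  doc <- xml2::xml_new_root("version")
  root <- xml2::xml_root(doc)
  xml2::xml_set_attr(root, "uid", format(v$uid))
  if (!is.null(v$preceding_uid)) xml2::xml_set_attr(root, "preceding_uid", format(v$preceding_uid))
  xml2::xml_set_attr(root, "change_type", v$change_type)
  xml2::xml_set_attr(root, "lifecycle", v$lifecycle)
  xml2::xml_set_attr(root, "commit_time", format_ehr_time(v$commit_time))
  xml2::xml_set_attr(root, "contribution_id", v$contribution_id)
  if (!is.null(v$data)) {
    data_doc <- xml2::read_xml(composition_to_xml(v$data))
    xml2::xml_add_child(root, data_doc)
  }
  as.character(doc)
}

version_to_json <- function(v) {
  out <- list(uid = format(v$uid), change_type = v$change_type,
              lifecycle = v$lifecycle, commit_time = format_ehr_time(v$commit_time),
              contribution_id = v$contribution_id)
  if (!is.null(v$preceding_uid)) out$preceding_uid <- format(v$preceding_uid)
  if (!is.null(v$data)) out$data <- node_to_list(v$data)
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}

contribution_to_json <- function(ctb) {
  as.character(jsonlite::toJSON(list(
    id = ctb$id, ehr_id = ctb$ehr_id, committer_id = ctb$committer_id,
    commit_time = format_ehr_time(ctb$commit_time), description = ctb$description,
    version_uids = lapply(ctb$version_uids, format),
    archetype_ids = as.list(ctb$archetype_ids),
    template_ids = as.list(ctb$template_ids)
  ), auto_unbox = TRUE, digits = NA))
}

#' Create a full server instance
#'
#' Wires a [version_store()], [query_registry()], [builder_space()],
#' [bookmark_service()] and [trigger_bus()] together: commits publish exactly
#' one trigger event, the metadata cache feeds ETags, and the builder's
#' outgoing fetches loop back through `dispatch()`.
#'
#' @param host Deployment hostname (also the `creating_system_id`).
#' @param validator_docs Constraint documents driving commit validation;
#'   defaults to the shipped blood-pressure archetype and template.
#' @param config Named list: `max_age_immutable`, `max_age_static` (seconds),
#'   `default_media`, `bookmark_policy`.
#' @param clock Time source for commits and logs.
#' @return An `EhrServer` R6 object.
#' @examples
#' srv <- ehr_server()
#' r <- srv$dispatch("POST", "/ehr/")
#' r$status
#' @export
ehr_server <- function(host = "ehr.example.org", validator_docs = shipped_constraint_docs(),
                       config = list(), clock = Sys.time) {
  EhrServer$new(host = host, validator_docs = validator_docs, config = config, clock = clock)
}

#' @rdname ehr_server
#' @export
EhrServer <- R6::R6Class("EhrServer",
  public = list(
    #' @field store The deployment's `VersionStore`.
    store = NULL,
    #' @field registry The `QueryRegistry`.
    registry = NULL,
    #' @field builders The `BuilderSpace`.
    builders = NULL,
    #' @field bookmarks The `BookmarkService`.
    bookmarks = NULL,
    #' @field bus The `TriggerBus`.
    bus = NULL,

    #' @description See [ehr_server()].
    #' @param host,validator_docs,config,clock See [ehr_server()].
    initialize = function(host = "ehr.example.org",
                          validator_docs = shipped_constraint_docs(),
                          config = list(), clock = Sys.time) {
      private$host <- host
      private$config <- utils::modifyList(
        list(max_age_immutable = 31536000L, max_age_static = 604800L,
             default_media = "application/xml",
             bookmark_policy = bookmark_policy_default),
        config)
      private$clock <- clock
      self$bus <- trigger_bus()
      validator <- if (length(validator_docs) > 0L) make_validator(validator_docs) else NULL
      self$store <- version_store(
        system_id = host, validator = validator, clock = clock,
        on_commit = function(ctb) self$bus$publish_commit(ctb)
      )
      self$registry <- query_registry()
      self$bookmarks <- bookmark_service(self$store, host = host,
                                         policy = private$config$bookmark_policy)
      loopback <- function(url, headers = list()) {
        path <- if (grepl("^[a-z]+://", url)) sub("^[a-z]+://[^/]+", "", url) else url
        resp <- self$dispatch("GET", path, headers = headers)
        if (resp$status >= 300L) {
          stop_ehrest("bad_request", sprintf("fetch of '%s' failed with status %d", url, resp$status))
        }
        resp$body
      }
      self$builders <- builder_space(self$store, validator = validator,
                                     fetcher = loopback, host = host,
                                     allowed_hosts = host)
      private$statics <- new.env(parent = emptyenv())
      self$add_static("restricted.txt", paste(
        "Requests carrying this Referer originate from the contribution builder's",
        "document-fetch commands. The Referer is fixed to this file so that",
        "committer and record identifiers never leak to fetched servers.", sep = "\n"))
    },

    #' @description Serve multi-record (population) reads from a replica store.
    #' @param store A `VersionStore` replica (see [replicate_to_multi()]).
    set_replica = function(store) {
      private$replica <- store
      invisible(self)
    },

    #' @description Register a static resource under `/static/{name}`.
    #' @param name File name.
    #' @param content Text content.
    #' @param media Media type.
    add_static = function(name, content, media = "text/plain") {
      assign(name, list(content = content, media = media), envir = private$statics)
      invisible(self)
    },

    #' @description The deployment hostname.
    hostname = function() private$host,

    #' @description Formatted access-log lines (NCSA combined + committer).
    log_lines = function() private$access_log,

    #' @description Handle one HTTP request.
    #' @param method HTTP method.
    #' @param uri Request URI (path, optional query string, optional fragment
    #'   -- fragments are client-side and stripped before routing).
    #' @param headers Named list (case as sent; `X-Committer` carries the
    #'   authenticated identity in this stub).
    #' @param body Request body: text, or a named list treated as a form.
    #' @return `list(status, headers, body)`.
    dispatch = function(method, uri, headers = list(), body = NULL) {
      resp <- tryCatch(
        private$route(method, uri, headers, body),
        ehrest_error = function(e) {
          list(status = ehrest_status(e), headers = c("Content-Type" = "text/plain"),
               body = conditionMessage(e))
        }
      )
      resp$headers <- c(resp$headers %||% character(0))
      private$log_request(method, uri, headers, resp)
      resp
    },

    #' @description Print a summary.
    print = function() {
      cat(sprintf("<EhrServer> host %s, %d ehr(s), %d stored quer%s, %d bookmark(s)\n",
                  private$host, length(self$store$ehr_ids()), self$registry$size(),
                  if (self$registry$size() == 1L) "y" else "ies", self$bookmarks$size()))
      invisible(self)
    }
  ),
  private = list(
    host = NULL, config = NULL, clock = NULL, statics = NULL, replica = NULL,
    access_log = character(0),

    log_request = function(method, uri, headers, resp) {
      committer <- headers[["X-Committer"]] %||% "-"
      size <- if (is.null(resp$body)) 0L else nchar(resp$body, type = "bytes")
      line <- sprintf('%s - %s [%s] "%s %s HTTP/1.1" %d %d "%s" "%s" %s',
                      private$host, committer,
                      format(private$clock(), "%d/%b/%Y:%H:%M:%S +0000", tz = "UTC"),
                      method, uri, resp$status, size,
                      headers[["Referer"]] %||% "-",
                      headers[["User-Agent"]] %||% "-",
                      committer)
      private$access_log <- c(private$access_log, line)
    },

    committer = function(headers) headers[["X-Committer"]] %||% "anonymous",

    read_store = function(multi) {
      if (multi && !is.null(private$replica)) private$replica else self$store
    },

    respond = function(status, body = NULL, headers = character(0), media = NULL) {
      if (!is.null(media)) headers <- c(headers, "Content-Type" = media)
      list(status = as.integer(status), headers = headers, body = body)
    },

    # Conditional GET: matching If-None-Match answers 304 from the metadata
    # cache alone -- the handler (and hence the store) is never reached.
    check_not_modified = function(headers, etag) {
      inm <- headers[["If-None-Match"]]
      !is.null(inm) && any(trimws(strsplit(inm, ",")[[1]]) %in% c(etag, "*"))
    },
    check_precondition = function(headers, etag) {
      im <- headers[["If-Match"]]
      if (is.null(im)) return(TRUE)
      any(trimws(strsplit(im, ",")[[1]]) %in% c(etag, "*"))
    },
    ehr_etag = function(store, ehr_id) {
      paste0("\"", store$metadata(ehr_id)$last_contribution_id, "\"")
    },

    route = function(method, uri, headers, body) {
      uri_full <- uri
      uri <- sub("#.*$", "", uri)   # fragments never reach the server's handlers
      qpos <- regexpr("?", uri, fixed = TRUE)
      path <- if (qpos > 0L) substr(uri, 1L, qpos - 1L) else uri
      query <- if (qpos > 0L) parse_query_string(substr(uri, qpos + 1L, nchar(uri))) else list()
      cfg <- private$config
      media_pair <- c(cfg$default_media, setdiff(c("application/xml", "application/json"), cfg$default_media))

      if (method == "OPTIONS") {
        return(private$respond(200L, headers = c("Allow" = "GET, POST, PUT, DELETE, OPTIONS")))
      }

      # -- root and statics ---------------------------------------------------
      if (grepl("^/$", path)) {
        if (method != "GET") stop_ehrest("method_not_allowed", "only GET on /")
        return(private$respond(200L, body = "ehrest: archetype-based EHR REST services",
                               media = "text/plain"))
      }
      m <- regmatches(path, regexec("^/static/(.+)$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "only GET on static resources")
        if (!exists(m[2], envir = private$statics, inherits = FALSE)) {
          stop_ehrest("not_found", sprintf("no static resource '%s'", m[2]))
        }
        st <- get(m[2], envir = private$statics)
        return(private$respond(200L, body = st$content, media = st$media,
                               headers = cache_headers_for("static_public", config = cfg)))
      }

      # -- record creation ----------------------------------------------------
      if (grepl("^/ehr/?$", path)) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST creates a record")
        form <- parse_form_body(body, headers[["Content-Type"]])
        id <- self$store$create_ehr(form$ehr_id %||% NULL, time = private$clock())
        return(private$respond(201L, body = id, media = "text/plain",
                               headers = c("Location" = sprintf("/ehr:%s/contributions/", id))))
      }

      # -- multi-scope query endpoints (no ehr id in path) ----------------------
      m <- regmatches(path, regexec("^/multi/ehr/q/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST registers a query")
        return(private$handle_register_query(list(kind = "multi"), m[2], headers, body))
      }
      m <- regmatches(path, regexec("^/multi/ehr/q/([^/]+)/([0-9a-f]{40})/(info/)?$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "stored queries are GET resources")
        if (identical(m[4], "info/")) return(private$handle_query_info(m[3], headers, media_pair))
        return(private$handle_run_query(list(kind = "multi"), m[3], query, headers, media_pair))
      }

      # -- single-record resources under /ehr:{id}/ (optionally /multi/ prefix) --
      m <- regmatches(path, regexec("^(/multi)?/ehr:([^/]+)(/.*)?$", path))[[1]]
      if (length(m) > 0L) {
        multi <- identical(m[2], "/multi")
        ehr_id <- m[3]
        rest <- if (length(m) >= 4L) m[4] else ""
        return(private$route_ehr(method, multi, ehr_id, rest, query, headers, body, media_pair))
      }

      # -- contribution builder -------------------------------------------------
      if (startsWith(path, "/cb")) {
        return(private$route_cb(method, path, query, headers, body, media_pair))
      }

      # -- bookmarks -------------------------------------------------------------
      if (grepl("^/bm/?$", path)) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST creates a bookmark")
        form <- parse_form_body(body, headers[["Content-Type"]])
        target <- form$url %||% form$target %||% stop_ehrest("bad_request", "form field 'url' required")
        bm <- self$bookmarks$create(target, created = private$clock())
        return(private$respond(201L, body = bm$short_url, media = "text/plain",
                               headers = c("Location" = bm$short_url)))
      }
      m <- regmatches(path, regexec("^/bm/([A-Za-z0-9]+)/?$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "bookmarks are GET resources")
        res <- self$bookmarks$resolve(m[2])
        if (identical(res$action, "block")) {
          return(private$respond(403L, body = sprintf(
            "bookmark resolution blocked by policy: target has %s information than at creation",
            res$change_status), media = "text/plain",
            headers = c("X-Bookmark-Change" = res$change_status)))
        }
        return(private$respond(303L, headers = c(
          "Location" = res$location,
          "X-Bookmark-Change" = res$change_status,
          "X-Bookmark-Action" = res$action)))
      }

      stop_ehrest("not_found", sprintf("no route for '%s'", uri_full))
    },

    route_ehr = function(method, multi, ehr_id, rest, query, headers, body, media_pair) {
      store <- private$read_store(multi)
      cfg <- private$config
      rest <- rest %||% ""

      # contributions collection
      if (grepl("^/contributions/?$", rest)) {
        if (method == "GET") {
          etag <- private$ehr_etag(store, ehr_id)
          if (private$check_not_modified(headers, etag)) {
            return(private$respond(304L, headers = c("ETag" = etag)))
          }
          ctbs <- store$list_contributions(
            ehr_id,
            start = as.integer(query$start %||% 1L),
            end = as.integer(query$end %||% 20L),
            descending = !identical(tolower(query$descending %||% "true"), "false"))
          media <- negotiate_media(headers[["Accept"]], media_pair)
          body_out <- if (media == "application/json") {
            as.character(jsonlite::toJSON(lapply(ctbs, function(c) jsonlite::fromJSON(contribution_to_json(c), simplifyVector = FALSE)),
                                          auto_unbox = TRUE, digits = NA))
          } else {
            paste0("<contributions>",
                   paste(vapply(ctbs, function(c) sprintf(
                     "<contribution id=\"%s\" committer_id=\"%s\" commit_time=\"%s\"/>",
                     c$id, c$committer_id, format_ehr_time(c$commit_time)), character(1)), collapse = ""),
                   "</contributions>")
          }
          meta <- store$metadata(ehr_id)
          return(private$respond(200L, body = body_out, media = media,
                                 headers = cache_headers_for("mutable_ehr_view", meta, cfg)))
        }
        if (method == "POST") {
          if (multi) stop_ehrest("method_not_allowed", "the multi replica is read-only")
          etag <- private$ehr_etag(store, ehr_id)
          if (!private$check_precondition(headers, etag)) {
            stop_ehrest("precondition", "If-Match does not match the record's current state")
          }
          payload <- parse_form_body(body, headers[["Content-Type"]])
          specs <- lapply(payload$versions %||% list(), function(v) {
            list(change_type = v$change_type, preceding_uid = v$preceding_uid %||% NULL,
                 lifecycle = v$lifecycle %||% "complete",
                 data = if (!is.null(v$data)) {
                   if (is.character(v$data)) parse_composition_payload(v$data) else list_to_node(v$data)
                 } else NULL,
                 attestation_proof = v$attestation_proof %||% NULL)
          })
          ctb <- self$store$commit_contribution(
            ehr_id, specs,
            audit = list(committer_id = private$committer(headers),
                         description = payload$description %||% ""),
            commit_time = private$clock())
          return(private$respond(201L, body = ctb$id, media = "text/plain",
                                 headers = c("Location" = sprintf("/ehr:%s/contributions/%s/", ehr_id, ctb$id))))
        }
        stop_ehrest("method_not_allowed", "contributions support GET and POST")
      }

      # one contribution
      m <- regmatches(rest, regexec("^/contributions/([^/]+)/?$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "contributions are immutable")
        ctb <- store$get_contribution(ehr_id, m[2])
        return(private$respond(200L, body = contribution_to_json(ctb),
                               media = "application/json",
                               headers = cache_headers_for("immutable_version", config = cfg)))
      }

      # query registration / run / info (single scope)
      m <- regmatches(rest, regexec("^/q/([^/]+)/$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST registers a query")
        if (!self$store$has_ehr(ehr_id)) stop_ehrest("not_found", sprintf("no ehr '%s'", ehr_id))
        return(private$handle_register_query(list(kind = "single", ehr_id = ehr_id), m[2], headers, body))
      }
      m <- regmatches(rest, regexec("^/q/([^/]+)/([0-9a-f]{40})/info/$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "query info is a GET resource")
        return(private$handle_query_info(m[3], headers, media_pair))
      }
      m <- regmatches(rest, regexec("^/q/([^/]+)/([0-9a-f]{40})/$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "stored queries run on GET")
        etag <- private$ehr_etag(store, ehr_id)
        if (private$check_not_modified(headers, etag)) {
          return(private$respond(304L, headers = c("ETag" = etag)))
        }
        return(private$handle_run_query(list(kind = "single", ehr_id = ehr_id, store = store),
                                        m[3], query, headers, media_pair,
                                        etag_headers = cache_headers_for(
                                          "mutable_ehr_view", store$metadata(ehr_id), private$config)))
      }

      # exact version, optionally with a sub-path
      m <- regmatches(rest, regexec("^/([^/@]+::[^/:]+::[0-9.]+)(/.*)?$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "versions are immutable")
        uid <- parse_version_uid(m[2])
        v <- store$get_version(ehr_id, uid$object_id, uid)
        subpath <- if (length(m) >= 3L && nzchar(m[3]) && m[3] != "/") sub("/$", "", m[3]) else NULL
        return(private$serve_version(v, ehr_id, subpath, headers, media_pair,
                                     cache_headers_for("immutable_version", config = private$config)))
      }

      # version lookup command: {object_id}@{selector}, optional sub-path
      m <- regmatches(rest, regexec("^/([^/@]+)@([^/]+)(/.*)?$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "version lookups are GET resources")
        etag <- private$ehr_etag(store, ehr_id)
        if (private$check_not_modified(headers, etag)) {
          return(private$respond(304L, headers = c("ETag" = etag)))
        }
        v <- store$get_version(ehr_id, m[2], m[3])
        subpath <- if (length(m) >= 4L && nzchar(m[4]) && m[4] != "/") sub("/$", "", m[4]) else NULL
        return(private$serve_version(v, ehr_id, subpath, headers, media_pair,
                                     cache_headers_for("mutable_ehr_view", store$metadata(ehr_id), private$config)))
      }

      # object command
      m <- regmatches(rest, regexec("^/([^/@]+)/all_version_ids/?$", rest))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "object commands are GET resources")
        etag <- private$ehr_etag(store, ehr_id)
        if (private$check_not_modified(headers, etag)) {
          return(private$respond(304L, headers = c("ETag" = etag)))
        }
        uids <- store$all_version_ids(ehr_id, m[2])
        return(private$respond(200L,
          body = as.character(jsonlite::toJSON(lapply(uids, format), auto_unbox = TRUE)),
          media = "application/json",
          headers = cache_headers_for("mutable_ehr_view", store$metadata(ehr_id), private$config)))
      }

      if (rest == "" || rest == "/") {
        if (method != "GET") stop_ehrest("method_not_allowed", "record overviews are GET resources")
        if (!store$has_ehr(ehr_id)) stop_ehrest("not_found", sprintf("no ehr '%s'", ehr_id))
        return(private$respond(200L, body = sprintf("ehr:%s", ehr_id), media = "text/plain"))
      }
      stop_ehrest("not_found", sprintf("no route for '%s' under ehr:%s", rest, ehr_id))
    },

    serve_version = function(v, ehr_id, subpath, headers, media_pair, cache_hdrs) {
      if (!is.null(subpath)) {
        if (is.null(v$data)) stop_ehrest("not_found", "version carries no data (deleted)")
        hits <- resolve_path(v$data, subpath)
        if (length(hits) == 0L) stop_ehrest("not_found", sprintf("no node at path '%s'", subpath))
        media <- negotiate_media(headers[["Accept"]], media_pair)
        body_out <- if (media == "application/json") {
          as.character(jsonlite::toJSON(lapply(hits, node_to_list), auto_unbox = TRUE, digits = NA))
        } else {
          frags <- vapply(hits, function(h) {
            sub("^<\\?xml[^>]*\\?>\\s*", "", composition_to_xml(h))
          }, character(1))
          paste0("<nodes>", paste(frags, collapse = ""), "</nodes>")
        }
        return(private$respond(200L, body = body_out, media = media, headers = cache_hdrs))
      }
      media <- negotiate_media(headers[["Accept"]], media_pair)
      body_out <- if (media == "application/json") version_to_json(v) else version_to_xml(v, ehr_id)
      private$respond(200L, body = body_out, media = media, headers = cache_hdrs)
    },

    handle_register_query = function(scope, language, headers, body) {
      form <- parse_form_body(body, headers[["Content-Type"]])
      text <- form$q %||% form$query %||% stop_ehrest("bad_request", "form field 'q' with the query text is required")
      params <- form[setdiff(names(form), c("q", "query"))]
      res <- self$registry$register(scope, language, text, posted_params = params,
                                    creator = private$committer(headers),
                                    created = private$clock())
      # Location drives the redirect; Content-Location repeats the sha URI for
      # script code that cannot see through automatic redirects.
      private$respond(303L, headers = c(
        "Location" = res$redirect_uri,
        "Content-Location" = sub("\\?.*$", "", res$redirect_uri)))
    },

    handle_query_info = function(sha, headers, media_pair) {
      info <- self$registry$info(sha)
      media <- negotiate_media(headers[["Accept"]], media_pair)
      body_out <- if (media == "application/json") {
        as.character(jsonlite::toJSON(list(
          sha = info$sha, language = info$language, text = info$text,
          static_params = info$static_params, creator = info$creator,
          created = format_ehr_time(info$created)), auto_unbox = TRUE, digits = NA))
      } else {
        doc <- xml2::xml_new_root("query_info")
        root <- xml2::xml_root(doc)
        xml2::xml_set_attr(root, "sha", info$sha)
        xml2::xml_set_attr(root, "language", info$language)
        xml2::xml_set_attr(root, "creator", info$creator)
        xml2::xml_set_attr(root, "created", format_ehr_time(info$created))
        xml2::xml_set_text(xml2::xml_add_child(root, "text"), info$text)
        sp <- xml2::xml_add_child(root, "static_params")
        for (nm in names(info$static_params)) {
          e <- xml2::xml_add_child(sp, "param")
          xml2::xml_set_attr(e, "name", nm)
          xml2::xml_set_attr(e, "value", as.character(info$static_params[[nm]]))
        }
        as.character(doc)
      }
      private$respond(200L, body = body_out, media = media)
    },

    handle_run_query = function(scope, sha, query, headers, media_pair, etag_headers = character(0)) {
      debug <- identical(tolower(query$debug %||% "false"), "true")
      uri_params <- query[setdiff(names(query), "debug")]
      if (identical(scope$kind, "multi")) {
        store <- private$read_store(TRUE)
        out <- self$registry$run_stored(sha, store, uri_params = uri_params, debug = debug)
      } else {
        out <- self$registry$run_stored(sha, scope$store %||% self$store, uri_params = uri_params,
                                        scope_ehr = scope$ehr_id, debug = debug)
      }
      if (debug) {
        return(private$respond(200L, body = out, media = "text/plain"))
      }
      media <- negotiate_media(headers[["Accept"]], media_pair)
      body_out <- serialize_resultset(out, if (media == "application/json") "json" else "xml")
      private$respond(200L, body = body_out, media = media, headers = etag_headers)
    },

    route_cb = function(method, path, query, headers, body, media_pair) {
      cb <- self$builders
      if (grepl("^/cb/?$", path)) {
        if (method != "GET") stop_ehrest("method_not_allowed", "only GET on /cb/")
        return(private$respond(200L, media = "text/plain", body = paste(
          "Contribution builder. Paths:",
          "/cb/{committer_id}/                         your records with active builds",
          "/cb/{committer_id}/{ehr_id}/                active builds",
          "/cb/{committer_id}/{ehr_id}/new-cb-id/      POST creates a build",
          "/cb/{committer_id}/{ehr_id}/{cb_id}/        build contents",
          sep = "\n")))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "listings are GET resources")
        return(private$respond(200L, body = as.character(jsonlite::toJSON(as.list(cb$list_builds(m[2])), auto_unbox = TRUE)),
                               media = "application/json"))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "listings are GET resources")
        return(private$respond(200L, body = as.character(jsonlite::toJSON(as.list(cb$list_builds(m[2], m[3])), auto_unbox = TRUE)),
                               media = "application/json"))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/new-cb-id/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST creates a build")
        cb_id <- cb$create_build(m[2], m[3], description = query$description %||% NULL)
        loc <- sprintf("/cb/%s/%s/%s/", m[2], m[3], cb_id)
        return(private$respond(303L, headers = c("Location" = loc), body = cb_id, media = "text/plain"))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/validate/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "validation reports are GET resources")
        rep <- cb$validate_build(m[2], m[3], m[4])
        out <- list(overall = rep$overall, archetype_ids = as.list(rep$archetype_ids),
                    versions = lapply(rep$by_temp_id, function(r) list(
                      overall = r$overall,
                      findings = lapply(r$findings, function(f) list(path = f$path, level = f$level, message = f$message)))))
        return(private$respond(200L, body = as.character(jsonlite::toJSON(out, auto_unbox = TRUE)),
                               media = "application/json"))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/commit/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST commits a build")
        ctb <- cb$commit_build(m[2], m[3], m[4], commit_time = private$clock())
        return(private$respond(201L, body = ctb$id, media = "text/plain",
                               headers = c("Location" = sprintf("/ehr:%s/contributions/%s/", m[3], ctb$id))))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/new/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "POST") stop_ehrest("method_not_allowed", "POST creates a temporary version")
        form <- parse_form_body(body, headers[["Content-Type"]])
        temp_id <- cb$add_version(m[2], m[3], m[4], command = m[5], payload = form)
        loc <- sprintf("/cb/%s/%s/%s/%s/", m[2], m[3], m[4], temp_id)
        return(private$respond(201L, body = temp_id, media = "text/plain",
                               headers = c("Location" = loc)))
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/([^/]+)/data/$", path))[[1]]
      if (length(m) > 0L) {
        if (method == "GET") {
          media <- negotiate_media(headers[["Accept"]],
                                   c("application/xml", "application/json", "text/html"))
          kind <- switch(media, "application/json" = "json", "text/html" = "html", "xml")
          return(private$respond(200L, body = cb$get_data(m[2], m[3], m[4], m[5], media = kind),
                                 media = media))
        }
        if (method %in% c("PUT", "POST")) {
          doc <- if (method == "POST") {
            form <- parse_form_body(body, headers[["Content-Type"]])
            form$data %||% stop_ehrest("bad_request", "form variable 'data' required")
          } else body
          cb$put_data(m[2], m[3], m[4], m[5], doc)
          return(private$respond(204L))
        }
        stop_ehrest("method_not_allowed", "data supports GET, PUT, POST")
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method == "DELETE") {
          cb$delete_version(m[2], m[3], m[4], m[5])
          return(private$respond(204L))
        }
        if (method == "GET") {
          b <- cb$get_build(m[2], m[3], m[4])
          tv <- b$temp_versions[[m[5]]]
          if (is.null(tv)) stop_ehrest("not_found", sprintf("no temp version '%s'", m[5]))
          out <- list(temp_id = tv$temp_id, lifecycle = tv$lifecycle,
                      intent = tv$intent$kind,
                      update_target = if (identical(tv$intent$kind, "update_of")) format(tv$intent$uid) else NULL)
          return(private$respond(200L, body = as.character(jsonlite::toJSON(out, auto_unbox = TRUE, null = "null")),
                                 media = "application/json"))
        }
        stop_ehrest("method_not_allowed", "temp versions support GET and DELETE")
      }
      m <- regmatches(path, regexec("^/cb/([^/]+)/([^/]+)/([^/]+)/$", path))[[1]]
      if (length(m) > 0L) {
        if (method != "GET") stop_ehrest("method_not_allowed", "build listings are GET resources")
        b <- cb$get_build(m[2], m[3], m[4])
        return(private$respond(200L,
          body = as.character(jsonlite::toJSON(as.list(names(b$temp_versions)), auto_unbox = TRUE)),
          media = "application/json"))
      }
      stop_ehrest("not_found", sprintf("no route for '%s'", path))
    }
  )
)
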