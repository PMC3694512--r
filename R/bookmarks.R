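#' @title Opaque bookmarks with change detection
#'
#' @description
#' Deep resource URIs expose record structure, so links meant to travel
#' outside a controlled environment are replaced by short opaque ones of the
#' form `/bm/{short_id}` (e.g. `/bm/ep7TtN`). Resolution is a 303 redirect to
#' the live target, so authentication and read logging still happen at the
#' target server -- the bookmark service itself never returns record content.
#' Because a bookmark points into a live record, the service snapshots the
#' target's version set at creation and reports on resolution whether the
#' target now holds *more*, the *same*, or *less* information, feeding a
#' configurable resolve/warn/block policy.
#'
#' @name bookmark_service
NULL

bm_alphabet <- c(LETTERS, letters, 0:9)

#' Default and strict bookmark resolution policies
#'
#' The default never resolves silently on change: more information warns, no
#' change resolves, less information warns (silent resolution on loss is the
#' dangerous cell of the policy matrix). The strict policy blocks resolution
#' on loss, for deployments where law or policy requires it.
#' @export
bookmark_policy_default <- list(more = "warn", none = "resolve", less = "warn")

#' @rdname bookmark_policy_default
#' @export
bookmark_policy_strict <- list(more = "warn", none = "resolve", less = "block")

#' Apply a resolution policy to a detected change status
#' @param change_status `"more"`, `"none"` or `"less"`.
#' @param policy Named list mapping each status to `"resolve"`, `"warn"` or
#'   `"block"`.
#' @return The action string.
#' @export
apply_bookmark_policy <- function(change_status, policy = bookmark_policy_default) {
  stopifnot(change_status %in% c("more", "none", "less"))
  action <- policy[[change_status]]
  if (is.null(action) || !action %in% c("resolve", "warn", "block")) {
    stop_ehrest("internal", sprintf("policy does not define an action for '%s'", change_status))
  }
  action
}

#' Create a bookmark service
#'
#' @param store The deployment's `VersionStore` (used for snapshots and change
#'   detection).
#' @param host Deployment hostname; absolute target URLs on other hosts are
#'   rejected.
#' @param id_length Length of minted short ids (default 6).
#' @param policy Resolution policy (see [bookmark_policy_default]).
#' @return A `BookmarkService` R6 object.
#' @export
bookmark_service <- function(store, host = "ehr.example.org", id_length = 6L,
                             policy = bookmark_policy_default) {
  BookmarkService$new(store = store, host = host, id_length = id_length, policy = policy)
}

#' @rdname bookmark_service
#' @export
BookmarkService <- R6::R6Class("BookmarkService",
  public = list(
    #' @description See [bookmark_service()].
    #' @param store,host,id_length,policy See [bookmark_service()].
    initialize = function(store, host = "ehr.example.org", id_length = 6L,
                          policy = bookmark_policy_default) {
      private$store <- store
      private$host <- host
      private$id_length <- as.integer(id_length)
      private$policy <- policy
      private$entries <- new.env(parent = emptyenv())
    },

    #' @description Create an opaque bookmark for a same-deployment URI.
    #' @param target_uri Relative URI (`/ehr:.../...`) or absolute URL on this
    #'   deployment's host. External hosts are rejected.
    #' @param created Creation time.
    #' @return `list(short_id=, short_url=, target_uri=)`.
    create = function(target_uri, created = Sys.time()) {
      path <- private$to_local_path(target_uri)
      snap <- private$snapshot(path)
      sensitive <- private$sensitive_tokens(path)
      repeat {
        short_id <- paste(sample(bm_alphabet, private$id_length, replace = TRUE), collapse = "")
        if (exists(short_id, envir = private$entries, inherits = FALSE)) next
        if (!private$leaks(short_id, sensitive)) break
      }
      assign(short_id, list(short_id = short_id, target_uri = path,
                            created = created, snapshot = snap),
             envir = private$entries)
      list(short_id = short_id,
           short_url = paste0("/bm/", short_id),
           target_uri = path)
    },

    #' @description Resolve a bookmark: a 303 redirect descriptor with the
    #'   detected change status and the policy action. The service returns the
    #'   target URI only -- never target content -- so target-side
    #'   authentication and logging are preserved by the client's re-request.
    #' @param short_id Bookmark id.
    #' @return `list(status = 303, location =, change_status =, action =)`;
    #'   `action == "block"` callers should deny resolution.
    resolve = function(short_id) {
      bm <- private$lookup(short_id)
      change <- self$detect_change(short_id)
      list(status = 303L, location = bm$target_uri, change_status = change,
           action = apply_bookmark_policy(change, private$policy))
    },

    #' @description Compare the bookmark target now against its creation
    #'   snapshot. Fast path: if the record's current ETag (latest
    #'   contribution id) equals the snapshot's, the answer is `"none"`
    #'   without re-resolving the target. Otherwise the target version set is
    #'   resolved afresh: any target object newly deleted means `"less"`; a
    #'   strict superset of version uids means `"more"`; an unchanged set
    #'   means `"none"`.
    #' @param short_id Bookmark id.
    #' @return `"more"`, `"none"` or `"less"`.
    detect_change = function(short_id) {
      bm <- private$lookup(short_id)
      snap <- bm$snapshot
      if (!is.null(snap$ehr_id)) {
        if (!private$store$has_ehr(snap$ehr_id)) return("less")
        meta <- private$store$metadata(snap$ehr_id)
        if (identical(meta$last_contribution_id, snap$etag)) return("none")
      }
      now <- private$snapshot(bm$target_uri)
      newly_deleted <- setdiff(now$deleted_objects, snap$deleted_objects)
      if (length(newly_deleted) > 0L) return("less")
      if (length(setdiff(snap$uids, now$uids)) > 0L) return("less")
      if (length(setdiff(now$uids, snap$uids)) > 0L) return("more")
      "none"
    },

    #' @description Retrieve a bookmark record.
    #' @param short_id Bookmark id.
    get = function(short_id) private$lookup(short_id),

    #' @description Number of bookmarks.
    size = function() length(ls(private$entries)),

    #' @description Print a summary.
    print = function() {
      cat(sprintf("<BookmarkService> %d bookmark(s) on host %s\n", self$size(), private$host))
      invisible(self)
    }
  ),
  private = list(
    store = NULL, host = NULL, id_length = 6L, policy = NULL, entries = NULL,
    lookup = function(short_id) {
      if (!exists(short_id, envir = private$entries, inherits = FALSE)) {
        stop_ehrest("not_found", sprintf("no bookmark '%s'", short_id))
      }
      get(short_id, envir = private$entries)
    },
    to_local_path = function(uri) {
      if (grepl("^[a-z]+://", uri)) {
        m <- regmatches(uri, regexec("^[a-z]+://([^/]+)(/.*)?$", uri))[[1]]
        if (m[2] != private$host) {
          stop_ehrest("bad_request", sprintf("bookmark target host '%s' is outside this deployment", m[2]))
        }
        uri <- if (nzchar(m[3])) m[3] else "/"
      }
      if (!startsWith(uri, "/")) stop_ehrest("bad_request", "bookmark target must be a deployment URI")
      uri <- sub("#.*$", "", uri)
      if (!grepl("^/(multi/)?ehr", uri)) {
        stop_ehrest("bad_request", sprintf("unbookmarkable target '%s': only record resources can be bookmarked", uri))
      }
      uri
    },
    # Version-set snapshot of what a target URI resolves to.
    snapshot = function(path) {
      p <- sub("^/multi", "", path)
      m <- regmatches(p, regexec("^/ehr:([^/]+)(/.*)?$", p))[[1]]
      if (length(m) == 0L) stop_ehrest("bad_request", sprintf("cannot snapshot target '%s'", path))
      ehr_id <- m[2]
      if (!private$store$has_ehr(ehr_id)) {
        stop_ehrest("not_found", sprintf("bookmark target record '%s' does not exist", ehr_id))
      }
      rest <- if (length(m) >= 3L) m[3] else ""
      etag <- private$store$metadata(ehr_id)$last_contribution_id
      object_id <- NULL
      mm <- regmatches(rest, regexec("^/([^/@:]+)(::|@|/|$)", rest))[[1]]
      if (length(mm) > 0L && !mm[2] %in% c("contributions", "q")) object_id <- mm[2]
      uids <- character(0); deleted <- character(0)
      collect <- function(oid) {
        vs <- private$store$all_version_ids(ehr_id, oid)
        uids <<- c(uids, vapply(vs, format, character(1)))
        latest <- private$store$get_version(ehr_id, oid, "latest_version")
        if (identical(latest$change_type, "deleted")) deleted <<- c(deleted, oid)
      }
      if (!is.null(object_id)) collect(object_id)
      else for (oid in private$store$object_ids(ehr_id)) collect(oid)
      list(ehr_id = ehr_id, etag = etag, uids = sort(uids), deleted_objects = sort(deleted))
    },
    sensitive_tokens = function(path) {
      segs <- strsplit(gsub("[:@?#]", "/", path), "/", fixed = TRUE)[[1]]
      segs <- unlist(strsplit(segs, "::", fixed = TRUE))
      unique(segs[nzchar(segs) & nchar(segs) >= 4L & !segs %in% c("multi", "contributions")])
    },
    leaks = function(short_id, sensitive) {
      for (tok in sensitive) {
        n <- nchar(tok)
        for (start in seq_len(max(0L, n - 4L + 1L))) {
          if (grepl(substr(tok, start, start + 3L), short_id, fixed = TRUE)) return(TRUE)
        }
      }
      FALSE
    }
  )
)
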