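#' @title Content-addressed query registry
#'
#' @description
#' Queries are POSTed once, parse-validated, and stored immutably under the
#' SHA-1 digest of the query text plus its canonicalized static parameters;
#' the caller is redirected (303) to
#' `/ehr:{ehr_id}/q/{language}/{sha}/?...` (or the `/multi/ehr/q/...` form)
#' and every subsequent run is an ordinary, cacheable, access-logged GET.
#' Parameters POSTed with a leading underscore are *dynamic*: the underscore
#' is stripped and they travel in the redirect URI, never entering the
#' digest. All other parameters are *static*: canonicalized, hashed and
#' stored with the query. A `debug=true` URI parameter returns the translated
#' plan as text instead of executing it.
#'
#' @name query_service
NULL

#' Canonicalize static query parameters
#'
#' Deterministic JSON object text: keys sorted ascending by code point, values
#' coerced to strings, no insignificant whitespace. This text -- not the raw
#' POST body -- enters the SHA-1 digest.
#'
#' @param params Named list or character vector (possibly empty).
#' @return A single JSON string, `"{}"` when empty.
#' @examples
#' canonical_static_params(list(b = "2", a = "1"))
#' @export
canonical_static_params <- function(params = list()) {
  if (length(params) == 0L) return("{}")
  nms <- names(params)
  if (is.null(nms) || any(!nzchar(nms))) stop_ehrest("bad_request", "static parameters must be named")
  if (any(startsWith(nms, "_"))) stop_ehrest("bad_request", "static parameter names must not start with '_'")
  ord <- order(nms, method = "radix")
  vals <- lapply(params[ord], function(v) as.character(v))
  names(vals) <- nms[ord]
  as.character(jsonlite::toJSON(vals, auto_unbox = TRUE))
}

#' Digest of a query plus its static parameters
#'
#' SHA-1 over the UTF-8 bytes of the query text, a single `0x0A` separator
#' byte, then the canonical static-parameter text. The byte layout is fixed
#' here because the protocol only prescribes the ingredients. The query
#' language is scoped by the URI (`/q/{language}/`), so it does not enter the
#' digest; dynamic parameters vary per call and never enter it.
#'
#' @param text Query text (hashed verbatim).
#' @param static_params Named list of static parameters.
#' @return 40-character lowercase hex digest.
#' @export
compute_query_sha <- function(text, static_params = list()) {
  payload <- c(charToRaw(enc2utf8(text)), as.raw(0x0A),
               charToRaw(enc2utf8(canonical_static_params(static_params))))
  digest::digest(payload, algo = "sha1", serialize = FALSE)
}

#' Create a query registry
#' @return A `QueryRegistry` R6 object.
#' @export
query_registry <- function() QueryRegistry$new()

#' Rebuild a query registry from its serialized log
#' @param lines Character vector from `$serialize_state()` (or read from a
#'   file written with [writeLines()]).
#' @return A `QueryRegistry` with every logged query re-registered.
#' @export
query_registry_from_log <- function(lines) {
  reg <- query_registry()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    reg$register(list(kind = "multi"), rec$language, rec$text,
                 posted_params = rec$static_params,
                 creator = rec$creator, created = parse_ehr_time(rec$created))
  }
  reg
}

#' @rdname query_registry
#' @export
QueryRegistry <- R6::R6Class("QueryRegistry",
  public = list(
    #' @description Create an empty registry.
    initialize = function() {
      private$entries <- new.env(parent = emptyenv())
    },

    #' @description Serialized registry state: one JSON line per registered
    #'   query, in registration order (commit-log style; the registry is
    #'   append-only, so earlier states are prefixes of later ones).
    serialize_state = function() {
      if (private$log_n == 0L) character(0)
      else unlist(private$log[seq_len(private$log_n)], use.names = FALSE)
    },

    #' @description Number of stored queries.
    size = function() length(ls(private$entries)),

    #' @description Register a query (idempotent).
    #'
    #' The text is parse-validated first -- a syntax error registers nothing.
    #' POSTed parameters with a leading `_` become dynamic URI parameters of
    #' the redirect; the rest are canonicalized, hashed and stored.
    #' @param scope `list(kind = "single", ehr_id = ...)` or
    #'   `list(kind = "multi")`.
    #' @param language Query language token (only `"AQL"` is supported).
    #' @param text Query text, stored verbatim.
    #' @param posted_params Named list of POSTed parameters.
    #' @param creator Committer identity for the audit record.
    #' @param created Registration time.
    #' @return `list(stored = <query record>, redirect_uri = <string>)`.
    register = function(scope, language, text, posted_params = list(),
                        creator = "anonymous", created = Sys.time()) {
      if (!identical(toupper(language), "AQL")) {
        stop_ehrest("bad_request", sprintf("unsupported query language '%s'", language))
      }
      posted_params <- posted_params %||% list()
      nms <- names(posted_params) %||% character(0)
      dynamic <- posted_params[startsWith(nms, "_")]
      static  <- posted_params[!startsWith(nms, "_")]
      ast <- parse_aql(text)  # 400 propagates; nothing stored
      sha <- compute_query_sha(text, static)
      if (!exists(sha, envir = private$entries, inherits = FALSE)) {
        rec <- list(sha = sha, language = toupper(language), text = text,
                    static_params = static, creator = creator,
                    created = created, ast = ast,
                    plan = translate_aql(ast, "native"))
        assign(sha, rec, envir = private$entries)
        private$log_n <- private$log_n + 1L
        private$log[[private$log_n]] <- as.character(jsonlite::toJSON(list(
          sha = sha, language = toupper(language), text = text,
          static_params = static, creator = creator,
          created = format_ehr_time(created)), auto_unbox = TRUE, digits = NA))
      }
      base <- if (identical(scope$kind, "multi")) {
        sprintf("/multi/ehr/q/%s/%s/", toupper(language), sha)
      } else {
        sprintf("/ehr:%s/q/%s/%s/", scope$ehr_id, toupper(language), sha)
      }
      qs <- ""
      if (length(dynamic) > 0L) {
        dn <- sub("^_", "", names(dynamic))
        ord <- order(dn, method = "radix")
        pairs <- vapply(seq_along(dn)[ord], function(i) {
          paste0(utils::URLencode(dn[i], reserved = TRUE), "=",
                 utils::URLencode(as.character(dynamic[[i]]), reserved = TRUE))
        }, character(1))
        qs <- paste0("?", paste(pairs, collapse = "&"))
      }
      list(stored = get(sha, envir = private$entries), redirect_uri = paste0(base, qs))
    },

    #' @description Run (or debug-print) a stored query.
    #' @param sha Stored query digest.
    #' @param store The `VersionStore` to execute against.
    #' @param uri_params Named list of dynamic parameters from the GET URI.
    #' @param scope_ehr Record id when running in single scope; `NULL` for
    #'   multi. Single scope binds the parameters `ehr_id` and (when the query
    #'   declares it) `current_ehr_uid` to this id -- the "calling program
    #'   context" binding.
    #' @param debug If `TRUE`, return the translated plan text without
    #'   executing (the store is never touched).
    #' @return A `result_set`, or a plan-text string when `debug`.
    run_stored = function(sha, store, uri_params = list(), scope_ehr = NULL, debug = FALSE) {
      rec <- private$lookup(sha)
      if (isTRUE(debug)) return(plan_text(rec$plan))
      params <- c(rec$static_params, uri_params)
      if (!is.null(scope_ehr)) {
        params[["ehr_id"]] <- scope_ehr
        if ("current_ehr_uid" %in% rec$plan$required_parameters &&
            is.null(params[["current_ehr_uid"]])) {
          params[["current_ehr_uid"]] <- scope_ehr
        }
      }
      execute_plan(rec$plan, store, params = params, scope_ehr = scope_ehr)
    },

    #' @description Audit record of a stored query: verbatim text, static
    #'   parameters, creator and creation time.
    #' @param sha Stored query digest.
    info = function(sha) {
      rec <- private$lookup(sha)
      list(sha = rec$sha, language = rec$language, text = rec$text,
           static_params = rec$static_params, creator = rec$creator,
           created = rec$created)
    },

    #' @description Is a digest registered?
    #' @param sha Digest.
    has = function(sha) exists(sha, envir = private$entries, inherits = FALSE),

    #' @description Print a summary.
    print = function() {
      cat(sprintf("<QueryRegistry> %d stored quer%s\n", self$size(),
                  if (self$size() == 1L) "y" else "ies"))
      invisible(self)
    }
  ),
  private = list(
    entries = NULL, log = list(), log_n = 0L,
    lookup = function(sha) {
      if (!exists(sha, envir = private$entries, inherits = FALSE)) {
        stop_ehrest("not_found", sprintf("no stored query '%s'", sha))
      }
      get(sha, envir = private$entries)
    }
  )
)
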